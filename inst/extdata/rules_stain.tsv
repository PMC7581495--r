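# pattern	target	priority
h&e	HE	1
hematoxylin	HE	2
eosin	HE	2
hestain	HE	1
ihc	IHC	1
ihcstain	IHC	1
immunohistochemistry	IHC	1
immunostain	IHC	2
pas	other	3
giemsa	other	3
trichrome	other	3
congo red	other	3
papanicolaou	other	3
gms	other	3
diff-quik	other	3
gram	other	3
specialstain	other	2
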