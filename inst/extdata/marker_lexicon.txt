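# marker-mention lexicon: one term per line, word-boundary and case-insensitive;
# prefix "re:" for a raw regex
ihc
immunohistochemistry
immunostain
fish
desmin
ki-67
ki67
her2
s100
vimentin
keratin
p53
p63
cdx2
ttf-1
synaptophysin
chromogranin
re:cd\d+
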