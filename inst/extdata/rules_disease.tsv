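# pattern	target	priority
carcinoma in situ	low_grade	1
low grade	low_grade	2
low-grade	low_grade	2
benign	low_grade	3
adenoma	low_grade	3
hyperplasia	low_grade	3
hyperplastic	low_grade	3
hamartoma	low_grade	3
leiomyoma	low_grade	3
fibroadenoma	low_grade	3
papilloma	low_grade	3
preneoplastic	low_grade	2
dysplasia	low_grade	3
lowgrade	low_grade	2
cancer	malignant	3
carcinoma	malignant	3
adenocarcinoma	malignant	2
sarcoma	malignant	3
malignant	malignant	2
malignancy	malignant	2
melanoma	malignant	3
lymphoma	malignant	3
leukemia	malignant	3
metastasis	malignant	2
metastatic	malignant	2
glioblastoma	malignant	3
high grade	malignant	2
normal	nontumor	3
artifact	nontumor	3
infection	nontumor	3
infectious	nontumor	3
injury	nontumor	3
inflammation	nontumor	3
inflammatory	nontumor	3
colitis	nontumor	3
gastritis	nontumor	3
esophagitis	nontumor	3
granulation tissue	nontumor	2
abscess	nontumor	3
fungal	nontumor	3
viral	nontumor	3
parasite	nontumor	3
pneumonia	nontumor	3
nontumor	nontumor	1
reactive	nontumor	4
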