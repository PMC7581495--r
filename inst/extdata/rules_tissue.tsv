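# pattern	target	priority   (lower = higher priority; lines starting with # ignored)
# patterns are matched case-insensitively on word boundaries; prefix "re:" for raw regex
bstpath	bone_soft_tissue	1
bonepath	bone_soft_tissue	1
bone	bone_soft_tissue	5
soft tissue	bone_soft_tissue	3
cardiac	bone_soft_tissue	4
skeletal muscle	bone_soft_tissue	3
breastpath	breast	1
breast	breast	4
mammary	breast	4
dermpath	dermatological	1
skin	dermatological	4
cutaneous	dermatological	4
melanocytic	dermatological	4
gipath	gastrointestinal	1
livpath	gastrointestinal	1
gastric	gastrointestinal	4
stomach	gastrointestinal	4
colon	gastrointestinal	4
colonic	gastrointestinal	4
esophagus	gastrointestinal	4
esophageal	gastrointestinal	4
appendix	gastrointestinal	4
bowel	gastrointestinal	4
pancreas	gastrointestinal	4
pancreatic	gastrointestinal	4
liver	gastrointestinal	4
hepatic	gastrointestinal	4
gupath	genitourinary	1
prostate	genitourinary	4
bladder	genitourinary	4
kidney	genitourinary	4
renal	genitourinary	4
testis	genitourinary	4
testicular	genitourinary	4
gynpath	gynecological	1
ovarian	gynecological	4
ovary	gynecological	4
uterus	gynecological	4
uterine	gynecological	4
cervix	gynecological	4
cervical	gynecological	4
endometrial	gynecological	4
endometrium	gynecological	4
fallopian	gynecological	4
entpath	head_neck	1
headneckpath	head_neck	1
head and neck	head_neck	3
thyroid	head_neck	4
salivary	head_neck	4
larynx	head_neck	4
oral	head_neck	5
sinonasal	head_neck	4
ocular	head_neck	4
hemepath	hematological	1
lymph node	hematological	3
spleen	hematological	4
bone marrow	hematological	3
neuropath	neurological	1
brain	neurological	4
cns	neurological	4
meninges	neurological	4
pulmpath	pulmonary	1
lung	pulmonary	4
pulmonary	pulmonary	4
pleura	pulmonary	4
bronchial	pulmonary	4
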