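tissue	organ
adrenal	adrenal
biceps	muscle
brainstem	brain
cerebellum	brain
cerebrum	brain
cortex	kidney
drg	drg
duodenum	intestine
stomach_glandular	stomach
heart	heart
hippocampus	brain
ileum	intestine
jejunum	intestine
kidney	kidney
liver	liver
medulla	kidney
stomach_nonglandular	stomach
ovary	ovary
pancreas	pancreas
soleus	muscle
testicle	testicle
uterus	uterus
whole_blood	whole_blood
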