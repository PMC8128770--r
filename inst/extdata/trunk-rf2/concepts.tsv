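id	primitive	semanticClass
12921003	0	clinical_region
22943007	0	structure
281902004	0	cavity
43799004	0	cavity
609617007	0	segment
67734004	0	segment
816092008	0	cross_section
816094009	0	cross_section
816991004	0	cavity
818981001	0	cross_section
818983003	1	clinical_region
818984009	1	clinical_region
818985005	0	segment
818987002	0	cavity
827003001	0	wall
X-abdomen-proper-cavity-E	1	entire
X-abdomen-proper-cavity-P	0	part
X-abdomen-proper-segment-E	1	entire
X-abdomen-proper-segment-P	0	part
X-abdominal-aorta-E	1	entire
X-abdominal-aorta-P	0	part
X-abdominal-aorta-S	0	content
X-abdominopelvic-cavity-E	1	entire
X-abdominopelvic-cavity-P	0	part
X-abdominopelvic-content-S	1	content
X-abdominopelvic-cross-section-E	1	entire
X-abdominopelvic-cross-section-P	0	part
X-abdominopelvic-cross-section-S	0	cross_section
X-abdominopelvic-segment-E	1	entire
X-abdominopelvic-segment-P	0	part
X-abdominopelvic-segment-S	0	segment
X-anal-canal-E	1	entire
X-anal-canal-P	0	part
X-anal-canal-S	0	content
X-anterior-abdominal-wall-E	1	entire
X-anterior-abdominal-wall-P	0	part
X-anterior-abdominal-wall-S	0	wall
X-aorta-E	1	entire
X-aorta-P	0	part
X-aorta-S	0	content
X-arch-of-aorta-E	1	entire
X-arch-of-aorta-P	0	part
X-arch-of-aorta-S	0	content
X-cavity-of-false-and-or-true-pelvis-S	1	cavity
X-cavity-of-false-pelvis-E	1	entire
X-cavity-of-false-pelvis-P	0	part
X-cavity-of-false-pelvis-S	0	cavity
X-cavity-of-true-pelvis-E	1	entire
X-cavity-of-true-pelvis-P	0	part
X-chest-wall-E	1	entire
X-chest-wall-P	0	part
X-chest-wall-S	0	wall
X-cross-sectional-abdomen-E	1	entire
X-cross-sectional-abdomen-P	0	part
X-cross-sectional-pelvis-E	1	entire
X-cross-sectional-pelvis-P	0	part
X-cross-sectional-thorax-E	1	entire
X-cross-sectional-thorax-P	0	part
X-descending-colon-E	1	entire
X-descending-colon-P	0	part
X-descending-colon-S	0	content
X-digestive-system-E	1	entire
X-digestive-system-P	0	part
X-digestive-system-S	0	content
X-disorder-abdomen-proper	0	disorder
X-disorder-abdominopelvic-segment	0	disorder
X-disorder-liver	0	disorder
X-disorder-root	1	disorder
X-disorder-uterus	0	disorder
X-entire-organ	1	entire
X-external-genitalia-E	1	entire
X-external-genitalia-P	0	part
X-external-genitalia-S	0	structure
X-fallopian-tube-E	1	entire
X-fallopian-tube-P	0	part
X-fallopian-tube-S	0	content
X-iliac-colon-E	1	entire
X-iliac-colon-P	0	part
X-iliac-colon-S	0	content
X-intra-abdomen-proper-region-E	1	entire
X-intra-abdomen-proper-region-P	0	part
X-intra-abdomen-proper-region-S	0	structure
X-intra-abdominopelvic-region-E	1	entire
X-intra-abdominopelvic-region-P	0	part
X-intra-abdominopelvic-region-S	0	structure
X-intra-thoracic-region-E	1	entire
X-intra-thoracic-region-P	0	part
X-intra-thoracic-region-S	0	structure
X-intra-true-pelvis-region-E	1	entire
X-intra-true-pelvis-region-P	0	part
X-intra-true-pelvis-region-S	0	structure
X-large-intestine-E	1	entire
X-large-intestine-P	0	part
X-large-intestine-S	0	content
X-liver-E	1	entire
X-liver-P	0	part
X-liver-S	0	content
X-lobe-of-liver-E	1	entire
X-lobe-of-liver-P	0	part
X-lobe-of-liver-S	0	content
X-lumbar-vertebral-column-E	1	entire
X-lumbar-vertebral-column-P	0	part
X-lumbar-vertebral-column-S	0	wall
X-ovary-E	1	entire
X-ovary-P	0	part
X-ovary-S	0	content
X-parenchyma-of-liver-S	1	content
X-pelvic-diaphragm-E	1	entire
X-pelvic-diaphragm-P	0	part
X-pelvic-diaphragm-S	0	wall
X-pelvic-portion-of-ureter-E	1	entire
X-pelvic-portion-of-ureter-P	0	part
X-pelvic-portion-of-ureter-S	0	content
X-pelvic-segment-E	1	entire
X-pelvic-segment-P	0	part
X-pelvic-wall-E	1	entire
X-pelvic-wall-P	0	part
X-pelvic-wall-S	0	wall
X-pelvis-E	1	entire
X-pelvis-P	0	part
X-perineum-E	1	entire
X-perineum-P	0	part
X-perineum-S	0	structure
X-posterior-wall-of-abdomen-proper-E	1	entire
X-posterior-wall-of-abdomen-proper-P	0	part
X-presacral-space-E	1	entire
X-presacral-space-P	0	part
X-presacral-space-S	0	content
X-procedure-cross-sectional-abdomen	0	procedure
X-procedure-root	1	procedure
X-procedure-trunk	0	procedure
X-prostate-E	1	entire
X-prostate-P	0	part
X-prostate-S	0	content
X-puboprostatic-ligament-E	1	entire
X-puboprostatic-ligament-P	0	part
X-puboprostatic-ligament-S	0	content
X-rectum-E	1	entire
X-rectum-P	0	part
X-rectum-S	0	content
X-retropubic-space-E	1	entire
X-retropubic-space-P	0	part
X-retropubic-space-S	0	content
X-seminal-vesicle-E	1	entire
X-seminal-vesicle-P	0	part
X-seminal-vesicle-S	0	content
X-sigmoid-colon-E	1	entire
X-sigmoid-colon-P	0	part
X-sigmoid-colon-S	0	content
X-t9-t12-band-of-trunk-E	1	entire
X-t9-t12-band-of-trunk-P	0	part
X-t9-t12-band-of-trunk-S	0	cross_section
X-thoracic-cavity-E	1	entire
X-thoracic-cavity-P	0	part
X-thoracic-diaphragm-E	1	entire
X-thoracic-diaphragm-P	0	part
X-thoracic-diaphragm-S	0	wall
X-thoracic-segment-E	1	entire
X-thoracic-segment-P	0	part
X-trunk-E	1	entire
X-trunk-P	0	part
X-urinary-bladder-E	1	entire
X-urinary-bladder-P	0	part
X-urinary-bladder-S	0	content
X-uterus-E	1	entire
X-uterus-P	0	part
X-uterus-S	0	content
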