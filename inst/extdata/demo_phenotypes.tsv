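id	yield
F01_L001	-2.3192
F01_L002	5.1169
F01_L003	1.5318
F02_L004	-0.8011
F02_L005	6.9740
F02_L006	3.8891
F03_L007	-3.3599
F03_L008	-3.7539
F03_L009	-1.4399
F04_L010	2.5746
F04_L011	-1.1368
F04_L012	0.0224
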