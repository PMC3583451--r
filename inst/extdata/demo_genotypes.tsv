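id	M0001	M0002	M0003	M0004	M0005	M0006	M0007	M0008	M0009	M0010	M0011	M0012
F01_L001	1	1	1	1	-1	-1	NA	-1	-1	1	1	-1
F01_L002	1	-1	-1	NA	-1	-1	-1	-1	-1	1	1	-1
F01_L003	-1	1	1	1	-1	1	1	-1	-1	-1	-1	-1
F02_L004	NA	1	-1	NA	-1	-1	1	-1	NA	-1	1	-1
F02_L005	NA	1	-1	1	1	1	1	-1	-1	-1	-1	1
F02_L006	-1	NA	-1	1	NA	-1	1	-1	-1	-1	1	1
F03_L007	1	1	NA	1	-1	-1	1	-1	1	1	1	-1
F03_L008	1	1	1	1	NA	-1	NA	1	-1	1	1	-1
F03_L009	1	1	-1	1	-1	-1	1	1	1	1	NA	-1
F04_L010	-1	-1	NA	-1	-1	-1	1	-1	-1	-1	1	-1
F04_L011	-1	NA	1	-1	-1	NA	-1	NA	-1	-1	1	-1
F04_L012	-1	1	-1	1	-1	1	1	-1	-1	-1	-1	-1
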