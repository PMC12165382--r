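chromosome	start	end	status	name
toy_chr1	9001	10000	Confirmed	ori_01
toy_chr1	97001	98000	Confirmed	ori_02
toy_chr1	103001	104000	Confirmed	ori_03
toy_chr1	126001	127000	Confirmed	ori_04
toy_chr1	181001	182000	Confirmed	ori_05
toy_chr1	269001	270000	Confirmed	ori_06
toy_chr2	5001	6000	Confirmed	ori_07
toy_chr2	27001	28000	Confirmed	ori_08
toy_chr2	58001	59000	Confirmed	ori_09
toy_chr2	117001	118000	Confirmed	ori_10
toy_chr2	217001	218000	Confirmed	ori_11
toy_chr2	299001	300000	Confirmed	ori_12
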