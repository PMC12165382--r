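origin_id	chrom	bin	rate
ori_01	toy_chr1	10	0.092926560303249708
ori_02	toy_chr1	98	0.091268748772160888
ori_03	toy_chr1	104	0.057883754116869079
ori_04	toy_chr1	127	0.062174447325860499
ori_05	toy_chr1	182	0.074851174334268536
ori_06	toy_chr1	270	0.077674177805189787
ori_07	toy_chr2	6	0.043651747169516371
ori_08	toy_chr2	28	0.044598548641801412
ori_09	toy_chr2	59	0.013537427502065127
ori_10	toy_chr2	118	0.068258558977592226
ori_11	toy_chr2	218	0.03944569137222631
ori_12	toy_chr2	300	0.022403125812138189
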