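ID	chrom	loc.start	loc.end	seg.mean
FA1	chr1	1	249250621	2
FA1	chr2	1	20000000	2
FA1	chr2	20000001	30000000	3
FA1	chr2	30000001	243199373	2
FA1	chr3	1	198022430	2
FA1	chr4	1	191154276	2
FA1	chr5	1	180915260	2
FA1	chr6	1	171115067	2
FA1	chr7	1	159138663	2
FA1	chr8	1	146364022	2
FA1	chr9	1	141213431	2
FA1	chr10	1	135534747	2
FA1	chr11	1	135006516	2
FA1	chr12	1	133851895	2
FA1	chr13	1	115169878	2
FA1	chr14	1	107349540	2
FA1	chr15	1	102531392	2
FA1	chr16	1	90354753	2
FA1	chr17	1	81195210	2
FA1	chr18	1	78077248	2
FA1	chr19	1	59128983	2
FA1	chr20	1	63025520	2
FA1	chr21	1	48129895	2
FA1	chr22	1	51304566	2
FA1	chrX	1	155270560	2
FA2	chr1	1	249250621	2
FA2	chr2	1	243199373	2
FA2	chr3	1	198022430	2
FA2	chr4	1	191154276	2
FA2	chr5	1	180915260	2
FA2	chr6	1	171115067	2
FA2	chr7	1	159138663	2
FA2	chr8	1	146364022	2
FA2	chr9	1	141213431	2
FA2	chr10	1	135534747	2
FA2	chr11	1	60000000	2
FA2	chr11	60000001	70000000	1
FA2	chr11	70000001	135006516	2
FA2	chr12	1	133851895	2
FA2	chr13	1	115169878	2
FA2	chr14	1	107349540	2
FA2	chr15	1	102531392	2
FA2	chr16	1	90354753	2
FA2	chr17	1	81195210	2
FA2	chr18	1	78077248	2
FA2	chr19	1	59128983	2
FA2	chr20	1	63025520	2
FA2	chr21	1	48129895	2
FA2	chr22	1	51304566	2
FA2	chrX	1	155270560	2
FA3	chr1	1	150000000	2
FA3	chr1	150000001	160000000	3
FA3	chr1	160000001	249250621	2
FA3	chr2	1	243199373	2
FA3	chr3	1	198022430	2
FA3	chr4	1	44000000	1
FA3	chr4	44000001	191154276	2
FA3	chr5	1	180915260	2
FA3	chr6	1	171115067	2
FA3	chr7	1	159138663	2
FA3	chr8	1	146364022	2
FA3	chr9	1	68000000	2
FA3	chr9	68000001	141213431	1
FA3	chr10	1	135534747	2
FA3	chr11	1	135006516	2
FA3	chr12	1	133851895	2
FA3	chr13	1	115169878	2
FA3	chr14	1	107349540	2
FA3	chr15	1	102531392	2
FA3	chr16	1	90354753	1
FA3	chr17	1	81195210	2
FA3	chr18	1	78077248	2
FA3	chr19	1	22000000	1
FA3	chr19	22000001	59128983	2
FA3	chr20	1	63025520	2
FA3	chr21	1	48129895	2
FA3	chr22	1	51304566	2
FA3	chrX	1	155270560	2
BenignPT	chr1	1	249250621	2
BenignPT	chr2	1	243199373	2
BenignPT	chr3	1	198022430	2
BenignPT	chr4	1	191154276	2
BenignPT	chr5	1	180915260	2
BenignPT	chr6	1	171115067	2
BenignPT	chr7	1	159138663	2
BenignPT	chr8	1	146364022	2
BenignPT	chr9	1	141213431	2
BenignPT	chr10	1	135534747	2
BenignPT	chr11	1	135006516	2
BenignPT	chr12	1	133851895	2
BenignPT	chr13	1	115169878	2
BenignPT	chr14	1	107349540	2
BenignPT	chr15	1	102531392	2
BenignPT	chr16	1	90354753	2
BenignPT	chr17	1	81195210	2
BenignPT	chr18	1	78077248	2
BenignPT	chr19	1	59128983	2
BenignPT	chr20	1	63025520	2
BenignPT	chr21	1	48129895	2
BenignPT	chr22	1	51304566	2
BenignPT	chrX	1	155270560	2
MalignantPT	chr1	1	249250621	2
MalignantPT	chr2	1	243199373	2
MalignantPT	chr3	1	198022430	2
MalignantPT	chr4	1	44180000	1
MalignantPT	chr4	44180001	191154276	2
MalignantPT	chr5	1	180915260	2
MalignantPT	chr6	1	171115067	2
MalignantPT	chr7	1	159138663	3
MalignantPT	chr8	1	146364022	2
MalignantPT	chr9	1	67750000	2
MalignantPT	chr9	67750001	141213431	1
MalignantPT	chr10	1	135534747	2
MalignantPT	chr11	1	135006516	2
MalignantPT	chr12	1	133851895	2
MalignantPT	chr13	1	40000000	2
MalignantPT	chr13	40000001	90000000	1
MalignantPT	chr13	90000001	115169878	2
MalignantPT	chr14	1	107349540	2
MalignantPT	chr15	1	102531392	2
MalignantPT	chr16	1	90354753	1
MalignantPT	chr17	1	81195210	2
MalignantPT	chr18	1	78077248	2
MalignantPT	chr19	1	22300000	1
MalignantPT	chr19	22300001	59128983	2
MalignantPT	chr20	1	63025520	2
MalignantPT	chr21	1	48129895	2
MalignantPT	chr22	1	51304566	2
MalignantPT	chrX	1	155270560	2
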