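region,axilla-I-anterior,axilla-I-central,axilla-I-lateral,axilla-I-posterior,axilla-I-interpectoral,axilla-II,axilla-III,internal-mammary,supraclavicular,mediastinal,interval,contralateral,region_total
0,87,37,1,9,5,14,1,37,1,1,13,1,111
1,66,19,3,6,3,9,0,19,1,0,4,0,85
2,164,59,2,22,5,13,1,28,1,0,16,0,199
3,69,29,1,12,2,7,1,14,0,0,11,0,94
4,44,18,0,7,1,3,0,16,0,0,4,0,56
5,31,11,0,7,2,3,0,16,0,0,10,0,41
6,20,10,1,5,0,0,0,16,0,1,5,0,31
7,21,5,0,1,0,2,0,17,0,0,4,0,24
8,19,7,0,2,0,3,0,15,0,0,1,0,23
9,19,6,0,0,0,1,0,11,0,1,1,0,23
10,42,16,1,3,0,5,0,28,1,0,3,1,56
11,41,14,1,7,1,4,0,29,1,1,6,0,60
12,48,22,1,4,2,8,1,18,0,0,5,0,66
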