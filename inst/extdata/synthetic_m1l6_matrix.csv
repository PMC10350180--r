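"neuron_id","ctxA","ctxB","ctxC","striatum","zona","thalA","thalB","thalC","thalD","thalE"
"L6N01",126,54,31,22,8,1,4,5,0,4
"L6N02",810,465,288,154,64,20,18,17,5,11
"L6N03",690,356,219,118,46,17,15,12,6,12
"L6N04",520,287,139,91,31,16,10,16,4,4
"L6N05",594,353,193,121,29,11,11,14,8,6
"L6N06",831,462,270,161,53,18,17,24,5,5
"L6N07",542,332,207,108,40,13,8,15,5,5
"L6N08",572,286,161,103,31,14,10,9,7,4
"L6N09",173,92,61,25,11,3,2,7,0,3
"L6N10",1360,772,426,235,83,26,22,26,16,13
"L6N11",1455,731,446,265,84,28,37,42,17,10
"L6N12",398,218,130,67,22,9,8,7,3,4
"L6N13",824,408,220,150,66,13,14,17,13,5
"L6N14",290,167,84,59,16,6,3,7,2,2
"L6N15",458,192,152,82,27,8,8,8,4,6
"L6N16",204,117,81,31,11,5,5,5,4,4
"L6N17",867,494,283,151,66,13,18,13,10,9
"L6N18",1139,675,373,206,78,22,22,19,15,13
"L6N19",541,304,164,69,34,11,11,12,1,7
"L6N20",841,477,301,175,57,21,14,18,5,13
"L6N21",418,233,142,77,18,16,9,7,4,2
"L6N22",27,26,17,17,50,339,305,240,138,65
"L6N23",7,13,2,5,19,162,130,79,49,26
"L6N24",30,23,19,16,60,389,332,270,146,72
"L6N25",26,20,11,13,57,338,272,203,123,57
"L6N26",6,6,3,3,22,113,95,79,38,22
"L6N27",9,16,9,3,19,199,129,132,57,29
"L6N28",20,15,13,11,34,266,241,190,90,43
"L6N29",11,5,4,7,19,158,146,100,44,23
"L6N30",15,21,8,13,35,244,211,161,71,33
"L6N31",8,19,2,10,30,248,241,191,87,41
"L6N32",37,35,21,12,91,543,449,357,182,90
"L6N33",7,5,4,2,11,127,97,93,52,27
"L6N34",10,13,9,5,29,178,157,127,69,38
"L6N35",15,11,5,5,13,140,123,99,48,40
"L6N36",22,17,10,5,40,300,241,192,91,45
"L6N37",13,9,10,4,17,134,149,116,46,18
"L6N38",15,14,7,11,34,192,178,149,79,40
"L6N39",10,8,7,2,24,180,130,118,58,23
"L6N40",44,29,14,14,70,571,451,328,147,87
"L6N41",5,7,5,6,16,102,100,62,36,14
"L6N42",40,37,13,16,67,534,432,371,168,95
"L6N43",37,43,16,17,78,593,453,398,191,86
"L6N44",10,18,7,4,23,277,191,164,79,39
"L6N45",12,4,6,6,30,165,136,107,47,24
"L6N46",48,48,17,23,79,705,566,453,223,108
"L6N47",19,25,10,9,40,295,261,217,104,53
"L6N48",13,9,7,7,20,149,132,105,51,26
"L6N49",51,57,27,27,109,776,630,544,267,123
"L6N50",19,11,5,7,28,180,163,123,72,31
"L6N51",48,49,16,20,88,635,524,413,216,117
"L6N52",29,21,12,13,65,438,336,294,137,63
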