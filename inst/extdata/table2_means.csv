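# Digitized condition-level trait means of the best 26 and worst single-cross
# hybrids (plus the open-pollinated check) ranked by the drought base index.
# Means-level dialect: one pseudo-environment per condition, replicate 1,
# block 1. Yield kg/ha; da days; asi days; pasp/easp 1-5 scores; epp count;
# sgc 1-9 score (drought only). The source table prints nine "worst" hybrids
# but one row was lost in text extraction, so 35 entries (70 rows) are stored.
environment,condition,replicate,block,genotype,line,tester,yield,da,asi,pasp,easp,epp,sgc
drought,drought,1,1,,TZEEI 102,TZEEI 95,2707,50.8,2.5,2.0,2.5,0.9,3.0
rainfed,rainfed,1,1,,TZEEI 102,TZEEI 95,3774,48.4,0.3,2.5,3.0,0.97,
drought,drought,1,1,,TZEEI 97,TZEEI 79,2471,49.7,2.0,2.4,2.5,0.9,3.5
rainfed,rainfed,1,1,,TZEEI 97,TZEEI 79,4292,48.4,1.1,2.9,2.7,0.93,
drought,drought,1,1,,TZEEI 71,TZEEI 79,2253,51.3,2.5,2.3,2.9,0.8,3.8
rainfed,rainfed,1,1,,TZEEI 71,TZEEI 79,4241,49.0,0.4,2.3,2.9,0.93,
drought,drought,1,1,,TZEEI 80,TZEEI 95,1992,51.3,2.7,2.5,2.8,0.9,3.7
rainfed,rainfed,1,1,,TZEEI 80,TZEEI 95,3755,49.8,-0.1,2.7,3.1,0.95,
drought,drought,1,1,,TZEEI 76,TZEEI 79,1960,51.2,2.3,2.4,3.0,0.9,3.5
rainfed,rainfed,1,1,,TZEEI 76,TZEEI 79,4368,49.0,0.4,1.9,2.5,0.96,
drought,drought,1,1,,TZEEI 74,TZEEI 79,2055,49.7,2.7,2.5,2.7,0.8,3.5
rainfed,rainfed,1,1,,TZEEI 74,TZEEI 79,3733,48.5,0.2,2.5,2.9,0.92,
drought,drought,1,1,,TZEEI 61,TZEEI 95,2434,52.8,4.5,2.5,2.5,0.8,4.0
rainfed,rainfed,1,1,,TZEEI 61,TZEEI 95,4150,48.3,0.5,2.9,2.9,0.99,
drought,drought,1,1,,TZEEI 82,TZEEI 79,2060,50.5,2.2,2.4,2.6,0.7,3.7
rainfed,rainfed,1,1,,TZEEI 82,TZEEI 79,4479,49.4,0.3,2.2,2.6,1.00,
drought,drought,1,1,,TZEEI 86,TZEEI 79,2020,51.0,3.7,2.6,2.4,0.8,3.7
rainfed,rainfed,1,1,,TZEEI 86,TZEEI 79,4538,48.8,0.6,2.2,2.5,0.98,
drought,drought,1,1,,TZEEI 100,TZEEI 63,1913,52.2,2.3,2.3,2.7,0.8,3.8
rainfed,rainfed,1,1,,TZEEI 100,TZEEI 63,4937,50.7,0.0,2.3,2.5,0.98,
drought,drought,1,1,,TZEEI 67,TZEEI 79,1906,52.5,2.2,2.4,2.5,0.8,4.2
rainfed,rainfed,1,1,,TZEEI 67,TZEEI 79,4441,50.9,-0.2,1.9,2.4,0.92,
drought,drought,1,1,,TZEEI 98,TZEEI 63,1982,51.8,2.7,2.8,2.6,0.9,3.8
rainfed,rainfed,1,1,,TZEEI 98,TZEEI 63,4888,48.6,0.6,2.1,2.7,0.98,
drought,drought,1,1,,TZEEI 94,TZEEI 95,1908,52.3,2.7,2.8,2.5,0.8,3.8
rainfed,rainfed,1,1,,TZEEI 94,TZEEI 95,3453,47.9,0.4,2.7,3.1,0.98,
drought,drought,1,1,,TZEEI 83,TZEEI 79,1961,50.2,2.8,2.4,2.7,0.8,4.0
rainfed,rainfed,1,1,,TZEEI 83,TZEEI 79,4709,49.3,0.1,2.1,2.6,1.00,
drought,drought,1,1,,TZEEI 73,TZEEI 79,1878,50.7,2.8,2.3,2.8,0.9,4.2
rainfed,rainfed,1,1,,TZEEI 73,TZEEI 79,4491,49.1,1.5,2.1,2.9,0.99,
drought,drought,1,1,,TZEEI 64,TZEEI 79,1994,50.7,2.5,2.6,2.8,0.8,4.2
rainfed,rainfed,1,1,,TZEEI 64,TZEEI 79,4690,48.5,0.2,2.8,2.6,1.01,
drought,drought,1,1,,TZEEI 108,TZEEI 79,1917,51.0,3.5,2.4,2.5,0.8,4.3
rainfed,rainfed,1,1,,TZEEI 108,TZEEI 79,4435,50.3,1.0,2.1,2.8,1.01,
drought,drought,1,1,,TZEEI 71,TZEEI 95,1981,50.7,3.0,2.8,2.8,0.8,3.5
rainfed,rainfed,1,1,,TZEEI 71,TZEEI 95,4388,48.7,0.4,2.2,2.5,0.98,
drought,drought,1,1,,TZEEI 80,TZEEI 79,1886,51.7,3.2,2.6,2.8,0.8,3.7
rainfed,rainfed,1,1,,TZEEI 80,TZEEI 79,4682,49.1,0.6,2.2,2.9,1.04,
drought,drought,1,1,,TZEEI 76,TZEEI 95,1853,51.8,2.7,2.8,2.8,0.7,3.3
rainfed,rainfed,1,1,,TZEEI 76,TZEEI 95,3987,48.3,0.1,2.1,3.0,0.99,
drought,drought,1,1,,TZEEI 59,TZEEI 79,1922,51.5,3.5,2.6,2.7,0.8,4.0
rainfed,rainfed,1,1,,TZEEI 59,TZEEI 79,3513,49.6,1.0,2.3,2.9,0.90,
drought,drought,1,1,,TZEEI 72,TZEEI 79,1948,51.2,3.0,2.6,2.8,0.8,4.2
rainfed,rainfed,1,1,,TZEEI 72,TZEEI 79,4669,48.9,0.2,2.2,2.5,0.99,
drought,drought,1,1,,TZEEI 9,TZEEI 79,1928,49.2,3.0,2.5,2.6,0.8,4.3
rainfed,rainfed,1,1,,TZEEI 9,TZEEI 79,3382,48.9,0.3,2.4,3.1,0.89,
drought,drought,1,1,,TZEEI 98,TZEEI 95,1665,52.5,2.3,2.8,2.8,0.8,3.7
rainfed,rainfed,1,1,,TZEEI 98,TZEEI 95,3626,50.0,0.1,2.5,2.7,0.96,
drought,drought,1,1,,TZEEI 100,TZEEI 79,1837,53.0,2.0,2.6,2.9,0.8,4.0
rainfed,rainfed,1,1,,TZEEI 100,TZEEI 79,4084,51.3,1.3,2.7,2.9,1.03,
drought,drought,1,1,,TZEEI 81,TZEEI 79,2060,52.2,4.2,3.0,2.8,0.7,4.3
rainfed,rainfed,1,1,,TZEEI 81,TZEEI 79,5382,49.8,0.2,1.8,2.3,0.99,
drought,drought,1,1,2008 SYN EE-Y DT STR,,,1525,51.8,3.2,2.6,3.0,0.7,4.2
rainfed,rainfed,1,1,2008 SYN EE-Y DT STR,,,3652,50.7,0.7,2.5,3.1,0.89,
drought,drought,1,1,,TZEEI 61,TZEEI 63,1111,53.2,7.0,3.3,3.3,0.7,5.0
rainfed,rainfed,1,1,,TZEEI 61,TZEEI 63,2551,52.2,1.3,3.0,3.2,0.91,
drought,drought,1,1,,TZEEI 58,TZEEI 63,753,53.2,6.3,3.2,3.7,0.6,4.0
rainfed,rainfed,1,1,,TZEEI 58,TZEEI 63,2743,50.8,0.7,2.7,3.3,0.95,
drought,drought,1,1,,TZEEI 115,TZEEI 63,728,53.5,4.8,3.5,3.6,0.5,4.5
rainfed,rainfed,1,1,,TZEEI 115,TZEEI 63,2148,51.2,1.1,3.2,3.5,0.88,
drought,drought,1,1,,TZEEI 75,TZEEI 63,901,55.8,5.5,3.8,3.7,0.5,4.3
rainfed,rainfed,1,1,,TZEEI 75,TZEEI 63,1834,50.8,2.5,3.2,3.8,0.90,
drought,drought,1,1,,TZEEI 76,TZEEI 63,761,53.2,7.0,3.7,3.7,0.5,4.8
rainfed,rainfed,1,1,,TZEEI 76,TZEEI 63,2527,50.5,1.5,3.3,3.1,0.95,
drought,drought,1,1,,TZEEI 102,TZEEI 63,462,55.2,5.5,3.8,3.8,0.5,4.3
rainfed,rainfed,1,1,,TZEEI 102,TZEEI 63,1203,51.7,1.9,3.2,4.1,0.71,
drought,drought,1,1,,TZEEI 74,TZEEI 63,728,52.2,6.3,3.8,3.8,0.6,5.5
rainfed,rainfed,1,1,,TZEEI 74,TZEEI 63,2178,50.0,0.8,3.0,3.5,0.89,
drought,drought,1,1,,TZEEI 62,TZEEI 63,503,54.3,8.8,3.8,4.1,0.5,5.3
rainfed,rainfed,1,1,,TZEEI 62,TZEEI 63,1632,51.9,1.9,2.8,3.8,0.75,
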