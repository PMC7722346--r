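# Digitized testcross summary: grain yield means (kg/ha) and SCA effects of 18
# of 39 extra-early maize inbred lines crossed to three testers under drought.
# sig: ns / p05 / p01 as printed. Rows line=="Mean" carry tester grand means
# (over all 39 testcrosses) with sca fixed at 0; rows line=="SE" carry the
# standard error of a tester mean (mean_yield column) and of an SCA effect
# (sca column).
# note: the TZEEI 71 x TZEEI 63 SCA of -4188 is magnitudes out of line with
# every other entry (plausibly -418.8); stored as printed.
line,tester,mean_yield,sca,sig
TZEEI 60,TZEEI 63,1066,-48,ns
TZEEI 60,TZEEI 79,1373,-319,ns
TZEEI 60,TZEEI 95,3987,2316,p01
TZEEI 61,TZEEI 63,1111,-168,ns
TZEEI 61,TZEEI 79,1686,-170,ns
TZEEI 61,TZEEI 95,2434,598,p01
TZEEI 62,TZEEI 63,503,-446,ns
TZEEI 62,TZEEI 79,1486,-40,ns
TZEEI 62,TZEEI 95,1993,488,p01
TZEEI 69,TZEEI 63,1616,335,p05
TZEEI 69,TZEEI 79,1729,-130,ns
TZEEI 69,TZEEI 95,1636,-203,ns
TZEEI 71,TZEEI 63,922,-4188,p01
TZEEI 71,TZEEI 79,2253,336,p05
TZEEI 71,TZEEI 95,1981,84,ns
TZEEI 72,TZEEI 63,935,-93,ns
TZEEI 72,TZEEI 79,1948,342,p05
TZEEI 72,TZEEI 95,1338,-247,ns
TZEEI 74,TZEEI 63,728,-300,ns
TZEEI 74,TZEEI 79,2055,449,p01
TZEEI 74,TZEEI 95,1438,-148,ns
TZEEI 76,TZEEI 63,761,-385,p05
TZEEI 76,TZEEI 79,1960,236,ns
TZEEI 76,TZEEI 95,1853,151,ns
TZEEI 77,TZEEI 63,1337,418,p05
TZEEI 77,TZEEI 79,1311,-185,ns
TZEEI 77,TZEEI 95,1245,-231,ns
TZEEI 78,TZEEI 63,1446,357,p05
TZEEI 78,TZEEI 79,1501,-166,ns
TZEEI 78,TZEEI 95,1457,-189,ns
TZEEI 87,TZEEI 63,1652,506,p01
TZEEI 87,TZEEI 79,1419,-304,ns
TZEEI 87,TZEEI 95,1503,-200,ns
TZEEI 96,TZEEI 63,1664,473,p01
TZEEI 96,TZEEI 79,1037,-732,p01
TZEEI 96,TZEEI 95,2009,260,ns
TZEEI 97,TZEEI 63,1551,44,ns
TZEEI 97,TZEEI 79,2471,386,p05
TZEEI 97,TZEEI 95,1637,-428,p01
TZEEI 98,TZEEI 63,1982,561,p01
TZEEI 98,TZEEI 79,1756,-244,ns
TZEEI 98,TZEEI 95,1665,-315,ns
TZEEI 99,TZEEI 63,1826,632,p01
TZEEI 99,TZEEI 79,1512,-260,ns
TZEEI 99,TZEEI 95,1382,-370,p05
TZEEI 101,TZEEI 63,1743,409,p01
TZEEI 101,TZEEI 79,1908,-3,ns
TZEEI 101,TZEEI 95,1487,-404,p05
TZEEI 102,TZEEI 63,462,-578,p01
TZEEI 102,TZEEI 79,1516,-101,ns
TZEEI 102,TZEEI 95,2707,1110,p01
TZEEI 115,TZEEI 63,728,-375,p05
TZEEI 115,TZEEI 79,1833,152,ns
TZEEI 115,TZEEI 95,1885,225,ns
Mean,TZEEI 63,1199,0,ns
Mean,TZEEI 79,1776,0,ns
Mean,TZEEI 95,1756,0,ns
SE,TZEEI 63,101.0,174.5,ns
SE,TZEEI 79,103.0,174.5,ns
SE,TZEEI 95,104.0,174.5,ns
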