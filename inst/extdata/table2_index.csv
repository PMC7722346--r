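# Printed drought base-index values for the 35 digitized entries. These were
# standardized over all 121 trial entries (whose full data are unpublished),
# so they are a sign/ordering plausibility reference, never an exact target.
genotype,printed_index
TZEEI 102xTZEEI 95,15.66
TZEEI 97xTZEEI 79,12.53
TZEEI 71xTZEEI 79,8.26
TZEEI 80xTZEEI 95,8.17
TZEEI 76xTZEEI 79,8.11
TZEEI 74xTZEEI 79,8.08
TZEEI 61xTZEEI 95,7.75
TZEEI 82xTZEEI 79,7.75
TZEEI 86xTZEEI 79,7.50
TZEEI 100xTZEEI 63,7.41
TZEEI 67xTZEEI 79,6.82
TZEEI 98xTZEEI 63,6.60
TZEEI 94xTZEEI 95,6.42
TZEEI 83xTZEEI 79,6.08
TZEEI 73xTZEEI 79,5.95
TZEEI 64xTZEEI 79,5.80
TZEEI 108xTZEEI 79,5.72
TZEEI 71xTZEEI 95,5.64
TZEEI 80xTZEEI 79,5.56
TZEEI 76xTZEEI 95,5.29
TZEEI 59xTZEEI 79,5.26
TZEEI 72xTZEEI 79,5.19
TZEEI 9xTZEEI 79,5.05
TZEEI 98xTZEEI 95,4.79
TZEEI 100xTZEEI 79,4.64
TZEEI 81xTZEEI 79,1.72
2008 SYN EE-Y DT STR,0.96
TZEEI 61xTZEEI 63,-10.19
TZEEI 58xTZEEI 63,-10.38
TZEEI 115xTZEEI 63,-11.83
TZEEI 75xTZEEI 63,-12.92
TZEEI 76xTZEEI 63,-14.99
TZEEI 102xTZEEI 63,-15.09
TZEEI 74xTZEEI 63,-17.10
TZEEI 62xTZEEI 63,-21.25
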