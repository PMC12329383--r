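participant_id,dropout_status,measure,d,p
01,dropped_fully,ECBI_INTENSITY,3.59,0.84
02,completer,ECBI_INTENSITY,0.80,0.20
03,completer,ECBI_INTENSITY,0.394,0.68
04,completer,ECBI_INTENSITY,0.002,0.50
05,completer,ECBI_INTENSITY,-0.925,0.92
06,completer,ECBI_INTENSITY,1.44,0.24
09,completer,ECBI_INTENSITY,1.36,0.001
10,dropped_fully,ECBI_INTENSITY,-2.17,0.10
11,dropped_fully,ECBI_INTENSITY,1.74,0.18
12,dropped_intervention,ECBI_INTENSITY,0.86,0.25
13,dropped_fully,ECBI_INTENSITY,0.20,0.48
15,completer,ECBI_INTENSITY,2.04,0.27
16,completer,ECBI_INTENSITY,0.49,0.28
01,dropped_fully,OBVL_K,3.59,0.82
02,completer,OBVL_K,0.69,0.15
03,completer,OBVL_K,0.48,0.49
04,completer,OBVL_K,0.06,0.46
05,completer,OBVL_K,-0.47,0.81
06,completer,OBVL_K,1.60,0.14
09,completer,OBVL_K,1.39,0.001
10,dropped_fully,OBVL_K,-1.77,0.10
11,dropped_fully,OBVL_K,1.76,0.07
12,dropped_intervention,OBVL_K,0.88,0.13
13,dropped_fully,OBVL_K,0.217,0.43
15,completer,OBVL_K,2.04,0.20
16,completer,OBVL_K,0.32,0.32
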