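participant_id,measure,interval,rci
03,ECBI_INTENSITY,T0T1,-0.14
03,ECBI_INTENSITY,T0T2,0.37
03,ECBI_INTENSITY,T1T2,0.50
03,ECBI_PROBLEM,T0T1,-0.64
03,ECBI_PROBLEM,T0T2,-0.85
03,ECBI_PROBLEM,T1T2,-0.21
03,OBVL_K,T0T1,2.44
03,OBVL_K,T0T2,3.66
03,OBVL_K,T1T2,1.22
05,ECBI_INTENSITY,T0T1,-0.09
05,ECBI_INTENSITY,T0T2,1.29
05,ECBI_INTENSITY,T1T2,1.38
05,ECBI_PROBLEM,T0T1,-0.85
05,ECBI_PROBLEM,T0T2,2.77
05,ECBI_PROBLEM,T1T2,3.62
05,OBVL_K,T0T1,0.00
05,OBVL_K,T0T2,2.38
05,OBVL_K,T1T2,2.38
06,ECBI_INTENSITY,T0T1,2.11
06,ECBI_INTENSITY,T0T2,0.23
06,ECBI_INTENSITY,T1T2,-1.88
06,ECBI_PROBLEM,T0T1,3.20
06,ECBI_PROBLEM,T0T2,0.43
06,ECBI_PROBLEM,T1T2,-2.77
06,OBVL_K,T0T1,11.90
06,OBVL_K,T0T2,5.36
06,OBVL_K,T1T2,-6.55
15,ECBI_INTENSITY,T0T1,2.29
15,ECBI_INTENSITY,T0T2,7.57
15,ECBI_INTENSITY,T1T2,5.28
15,ECBI_PROBLEM,T0T1,4.26
15,ECBI_PROBLEM,T0T2,4.26
15,ECBI_PROBLEM,T1T2,0.00
15,OBVL_K,T0T1,5.95
15,OBVL_K,T0T2,8.93
15,OBVL_K,T1T2,2.98
16,ECBI_INTENSITY,T0T1,0.60
16,ECBI_INTENSITY,T0T2,0.09
16,ECBI_INTENSITY,T1T2,-0.50
16,ECBI_PROBLEM,T0T1,-0.43
16,ECBI_PROBLEM,T0T2,-25.57
16,ECBI_PROBLEM,T1T2,-25.14
16,OBVL_K,T0T1,0.60
16,OBVL_K,T0T2,2.98
16,OBVL_K,T1T2,2.38
02,ECBI_INTENSITY,T0T1,2.48
02,ECBI_INTENSITY,T0T2,2.52
02,ECBI_INTENSITY,T1T2,0.05
02,ECBI_PROBLEM,T0T1,1.92
02,ECBI_PROBLEM,T0T2,6.18
02,ECBI_PROBLEM,T1T2,4.26
02,OBVL_K,T0T1,1.22
02,OBVL_K,T0T2,4.88
02,OBVL_K,T1T2,3.66
04,ECBI_INTENSITY,T0T1,0.18
04,ECBI_INTENSITY,T0T2,-0.37
04,ECBI_INTENSITY,T1T2,-0.55
04,ECBI_PROBLEM,T0T1,-0.85
04,ECBI_PROBLEM,T0T2,-1.07
04,ECBI_PROBLEM,T1T2,-0.21
04,OBVL_K,T0T1,0.00
04,OBVL_K,T0T2,-2.44
04,OBVL_K,T1T2,-2.44
09,ECBI_INTENSITY,T0T1,0.78
09,ECBI_INTENSITY,T0T2,0.78
09,ECBI_INTENSITY,T1T2,0.00
09,ECBI_PROBLEM,T0T1,2.98
09,ECBI_PROBLEM,T0T2,4.05
09,ECBI_PROBLEM,T1T2,1.07
09,OBVL_K,T0T1,1.22
09,OBVL_K,T0T2,2.44
09,OBVL_K,T1T2,1.22
12,ECBI_INTENSITY,T0T1,3.49
12,ECBI_INTENSITY,T0T2,3.53
12,ECBI_INTENSITY,T1T2,0.05
12,ECBI_PROBLEM,T0T1,2.77
12,ECBI_PROBLEM,T0T2,2.56
12,ECBI_PROBLEM,T1T2,-0.21
12,OBVL_K,T0T1,11.59
12,OBVL_K,T0T2,12.80
12,OBVL_K,T1T2,1.22
17,ECBI_INTENSITY,T1T2,0.05
17,ECBI_PROBLEM,T1T2,0.00
17,OBVL_K,T1T2,4.88
18,ECBI_INTENSITY,T1T2,-1.06
18,ECBI_PROBLEM,T1T2,0.43
18,OBVL_K,T1T2,-6.10
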