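participant_id,dropout_status,vr_total,measure,timepoint,value
03,completer,4,DPICS_PF,T0,3
03,completer,4,DPICS_PF,T1,89
03,completer,4,DPICS_NL,T0,14
03,completer,4,DPICS_NL,T1,0
03,completer,4,ECBI_INTENSITY,T0,140
03,completer,4,ECBI_INTENSITY,T1,143
03,completer,4,ECBI_INTENSITY,T2,132
03,completer,4,ECBI_PROBLEM,T0,17
03,completer,4,ECBI_PROBLEM,T1,20
03,completer,4,ECBI_PROBLEM,T2,21
03,completer,4,OBVL_K,T0,72
03,completer,4,OBVL_K,T1,68
03,completer,4,OBVL_K,T2,66
05,completer,3,DPICS_PF,T0,10
05,completer,3,DPICS_PF,T1,23
05,completer,3,DPICS_NL,T0,41
05,completer,3,DPICS_NL,T1,57
05,completer,3,ECBI_INTENSITY,T0,159
05,completer,3,ECBI_INTENSITY,T1,161
05,completer,3,ECBI_INTENSITY,T2,131
05,completer,3,ECBI_PROBLEM,T0,18
05,completer,3,ECBI_PROBLEM,T1,22
05,completer,3,ECBI_PROBLEM,T2,5
05,completer,3,OBVL_K,T0,79
05,completer,3,OBVL_K,T1,79
05,completer,3,OBVL_K,T2,75
06,completer,3,DPICS_PF,T0,6
06,completer,3,DPICS_PF,T1,28
06,completer,3,DPICS_NL,T0,36
06,completer,3,DPICS_NL,T1,19
06,completer,3,ECBI_INTENSITY,T0,155
06,completer,3,ECBI_INTENSITY,T1,109
06,completer,3,ECBI_INTENSITY,T2,150
06,completer,3,ECBI_PROBLEM,T0,16
06,completer,3,ECBI_PROBLEM,T1,1
06,completer,3,ECBI_PROBLEM,T2,14
06,completer,3,OBVL_K,T0,75
06,completer,3,OBVL_K,T1,55
06,completer,3,OBVL_K,T2,66
15,completer,4,DPICS_PF,T0,0
15,completer,4,DPICS_PF,T1,11
15,completer,4,DPICS_PF,T2,36
15,completer,4,DPICS_NL,T0,32
15,completer,4,DPICS_NL,T1,12
15,completer,4,DPICS_NL,T2,8
15,completer,4,ECBI_INTENSITY,T0,165
15,completer,4,ECBI_INTENSITY,T1,115
15,completer,4,ECBI_INTENSITY,T2,129
15,completer,4,ECBI_PROBLEM,T0,20
15,completer,4,ECBI_PROBLEM,T1,0
15,completer,4,ECBI_PROBLEM,T2,0
15,completer,4,OBVL_K,T0,63
15,completer,4,OBVL_K,T1,53
15,completer,4,OBVL_K,T2,48
16,completer,5,DPICS_PF,T0,18
16,completer,5,DPICS_PF,T1,51
16,completer,5,DPICS_PF,T2,37
16,completer,5,DPICS_NL,T0,56
16,completer,5,DPICS_NL,T1,10
16,completer,5,DPICS_NL,T2,1
16,completer,5,ECBI_INTENSITY,T0,137
16,completer,5,ECBI_INTENSITY,T1,124
16,completer,5,ECBI_INTENSITY,T2,135
16,completer,5,ECBI_PROBLEM,T0,15
16,completer,5,ECBI_PROBLEM,T1,1
16,completer,5,ECBI_PROBLEM,T2,20
16,completer,5,OBVL_K,T0,77
16,completer,5,OBVL_K,T1,76
16,completer,5,OBVL_K,T2,72
02,completer,7,DPICS_PF,T0,2
02,completer,7,DPICS_PF,T1,24
02,completer,7,DPICS_PF,T2,51
02,completer,7,DPICS_NL,T0,5
02,completer,7,DPICS_NL,T1,3
02,completer,7,DPICS_NL,T2,3
02,completer,7,ECBI_INTENSITY,T0,117
02,completer,7,ECBI_INTENSITY,T1,63
02,completer,7,ECBI_INTENSITY,T2,62
02,completer,7,ECBI_PROBLEM,T0,29
02,completer,7,ECBI_PROBLEM,T1,20
02,completer,7,ECBI_PROBLEM,T2,0
02,completer,7,OBVL_K,T0,56
02,completer,7,OBVL_K,T1,54
02,completer,7,OBVL_K,T2,48
04,completer,24,DPICS_PF,T0,2
04,completer,24,DPICS_PF,T1,17
04,completer,24,DPICS_PF,T2,24
04,completer,24,DPICS_NL,T0,30
04,completer,24,DPICS_NL,T1,8
04,completer,24,DPICS_NL,T2,10
04,completer,24,ECBI_INTENSITY,T0,123
04,completer,24,ECBI_INTENSITY,T1,119
04,completer,24,ECBI_INTENSITY,T2,131
04,completer,24,ECBI_PROBLEM,T0,13
04,completer,24,ECBI_PROBLEM,T1,17
04,completer,24,ECBI_PROBLEM,T2,18
04,completer,24,OBVL_K,T0,72
04,completer,24,OBVL_K,T1,72
04,completer,24,OBVL_K,T2,76
09,completer,14,DPICS_PF,T0,2
09,completer,14,DPICS_PF,T1,35
09,completer,14,DPICS_PF,T2,43
09,completer,14,DPICS_NL,T0,37
09,completer,14,DPICS_NL,T1,22
09,completer,14,DPICS_NL,T2,15
09,completer,14,ECBI_INTENSITY,T0,145
09,completer,14,ECBI_INTENSITY,T1,128
09,completer,14,ECBI_INTENSITY,T2,128
09,completer,14,ECBI_PROBLEM,T0,21
09,completer,14,ECBI_PROBLEM,T1,7
09,completer,14,ECBI_PROBLEM,T2,2
09,completer,14,OBVL_K,T0,70
09,completer,14,OBVL_K,T1,68
09,completer,14,OBVL_K,T2,66
12,dropped_intervention,7,DPICS_PF,T0,3
12,dropped_intervention,7,DPICS_PF,T1,3
12,dropped_intervention,7,DPICS_PF,T2,1
12,dropped_intervention,7,DPICS_NL,T0,51
12,dropped_intervention,7,DPICS_NL,T1,18
12,dropped_intervention,7,DPICS_NL,T2,18
12,dropped_intervention,7,ECBI_INTENSITY,T0,164
12,dropped_intervention,7,ECBI_INTENSITY,T1,88
12,dropped_intervention,7,ECBI_INTENSITY,T2,87
12,dropped_intervention,7,ECBI_PROBLEM,T0,19
12,dropped_intervention,7,ECBI_PROBLEM,T1,6
12,dropped_intervention,7,ECBI_PROBLEM,T2,7
12,dropped_intervention,7,OBVL_K,T0,72
12,dropped_intervention,7,OBVL_K,T1,53
12,dropped_intervention,7,OBVL_K,T2,51
17,completer,24,DPICS_PF,T1,26
17,completer,24,DPICS_PF,T2,13
17,completer,24,DPICS_NL,T1,6
17,completer,24,DPICS_NL,T2,4
17,completer,24,ECBI_INTENSITY,T1,52
17,completer,24,ECBI_INTENSITY,T2,51
17,completer,24,ECBI_PROBLEM,T1,0
17,completer,24,ECBI_PROBLEM,T2,0
17,completer,24,OBVL_K,T1,58
17,completer,24,OBVL_K,T2,50
18,completer,8,DPICS_PF,T1,17
18,completer,8,DPICS_PF,T2,20
18,completer,8,DPICS_NL,T1,7
18,completer,8,DPICS_NL,T2,4
18,completer,8,ECBI_INTENSITY,T1,78
18,completer,8,ECBI_INTENSITY,T2,101
18,completer,8,ECBI_PROBLEM,T1,0
18,completer,8,ECBI_PROBLEM,T2,2
18,completer,8,OBVL_K,T1,49
18,completer,8,OBVL_K,T2,59
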