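day	methane_umol_per_L	mn2_dissolved	mn2_adsorbed	mn2_carbonate
0	2005.81342644892	9.95534332334468	273.771941391979	214.039881451911
7	1685.57037767053	35.9149606122375	987.661416836531	772.171653163106
14	1385.92732501658	61.4270282385586	1689.24327656036	1320.68110712901
21	1058.83703144757	87.4870981656673	2405.89519955585	1880.97261056185
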