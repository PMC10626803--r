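table,row,col,count
depression,CM,yes,13
depression,CM,no,10
depression,EM,yes,4
depression,EM,no,21
sex_3group,male,HC,16
sex_3group,male,EM,9
sex_3group,male,CM,9
sex_3group,female,HC,25
sex_3group,female,EM,23
sex_3group,female,CM,15
sex_em_cm,EM,male,9
sex_em_cm,EM,female,23
sex_em_cm,CM,male,9
sex_em_cm,CM,female,15
anxiety,CM,yes,11
anxiety,CM,no,12
anxiety,EM,yes,6
anxiety,EM,no,19
poor_sleep,CM,yes,14
poor_sleep,CM,no,9
poor_sleep,EM,yes,13
poor_sleep,EM,no,12
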