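participant,probe,session,outcome,attribution,skill_report,path_length,prop_nonup,prop_correct_keys,prop_pauses,time_limit,difficulty
demo,1,1,1,Internal,0.52,9,0.25,0.81,0.05,27,-0.5
demo,2,1,1,NA,0.61,11,0.32,0.77,0.1,26,-0.25
demo,3,2,0,Luck,0.55,12,0.41,0.69,0.08,25,0
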