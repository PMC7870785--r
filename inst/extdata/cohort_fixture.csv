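subject_id,group,age,weight,gestational_week,afp,free_bhcg,ue3,shla_g
F001,control,28.1,54.5,15,30,20,4,106.3
F002,control,25.3,60.2,16,36.1,17.5,5.1,98.4
F003,control,31,52,17,41.2,15.9,6.2,111
F004,T21,33.2,55,16,24.9,48.2,3.9,125.7
F005,T18,29.4,49.8,15,16.5,4.4,3.3,47.8
F006,T18,24.8,63.1,18,25.1,3.5,5.6,52.2
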