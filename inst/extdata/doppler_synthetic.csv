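subject_id,group,site,psv,edv
S01,control,main_renal,98.5,41.4
S02,control,interlobar,82.0,35.3
S03,A,main_renal,104.2,33.9
S04,A,interlobar,96.8,30.0
S05,B,main_renal,101.5,37.6
S06,B,interlobar,91.3,33.8
S07,B,intrarenal,88.0,123.0
S08,A,intrarenal,93.4,28.9
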