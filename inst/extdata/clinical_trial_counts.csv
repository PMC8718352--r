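patient,hemisphere,trials,state
P1,Right,66,Sedated
P2,Right,281,Awake
P3,Left,164,Sedated
P4,Left,80,Sedated
P5,Left,95,Sedated
P6,Left,200,Awake
P7,Left,101,Sedated
P8,Right,105,Sedated
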