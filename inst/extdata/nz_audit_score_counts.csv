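service,score,n
Uber Eats,-2,2361
Uber Eats,-1,2277
Uber Eats,0,1114
Uber Eats,1,1568
Uber Eats,2,138
Menulog,-2,2197
Menulog,-1,2681
Menulog,0,1680
Menulog,1,1340
Menulog,2,178
delivereasy,-2,1609
delivereasy,-1,1632
delivereasy,0,646
delivereasy,1,1134
delivereasy,2,316
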