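model,intercept,ATM,ACC,DONN,ARO
mono,4.2566,0.1111,,,
bi,5.9493,0.0948,-0.3329,,
tri,6.0749,0.0849,-0.3338,0.3495,
tetra,6.1250,0.0907,-0.3721,0.3766,-0.0674
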