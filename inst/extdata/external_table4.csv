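id,role,observed,mono,d_mono,bi,d_bi,tri,d_tri,tetra,d_tetra
26,external_validation,9.7447,9.3672,0.3775,9.3114,0.4333,9.6779,0.0668,9.6645,0.0802
27,external_validation,9.2676,8.8117,0.4559,8.8374,0.4302,9.2534,0.0142,9.2110,0.0566
28,external_validation,8.8508,8.9228,-0.0720,9.2651,-0.4143,9.3226,-0.4718,9.2972,-0.4464
29,external_validation,8.6198,9.7005,-1.0807,8.2642,0.3556,8.2479,0.3719,8.1390,0.4808
30,external_validation,8.2757,8.3673,-0.0916,8.1253,0.1504,8.2305,0.0452,8.1669,0.1088
31,external_validation,8.1549,7.8118,0.3431,8.3171,-0.1622,8.4736,-0.3187,8.5250,-0.3701
Celecoxib,external_validation,9.2839,8.7006,0.5833,8.4097,0.8742,8.4852,0.7987,8.4390,0.8449
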