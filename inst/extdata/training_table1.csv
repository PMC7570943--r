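id,name,role,ATM,ARO,DONN,ACC,pic50,ic50_nM
1,Rofecoxib(BDBM22369),pivot,36,2,0,4,7.9208,12.00
2,BDBM50272105,training,45,4,1,2,10.0457,0.09
3,BDBM50272097,training,48,4,1,2,9.7695,0.17
4,BDBM50365267,training,50,2,1,3,9.6989,0.20
5,BDBM50272130,training,45,4,1,2,9.5528,0.28
6,BDBM50272111,training,42,4,1,2,9.4436,0.36
7,BDBM50272124,training,42,4,1,2,9.4317,0.37
8,BDBM50272106,training,42,4,1,2,9.2218,0.60
9,BDBM50272092,training,42,4,1,2,9.0969,0.80
10,BDBM50049011,training,42,3,1,3,9.0000,1.00
11,BDBM50189988,training,37,2,3,5,8.7447,1.80
12,BDBM50057618,training,44,3,1,5,8.4317,3.70
13,BDBM50151689,training,40,3,1,3,8.3979,4.00
14,BDBM50103310,training,42,3,0,4,8.3767,4.20
15,BDBM13066,training,29,2,1,2,8.3000,5.00
16,BDBM50297680,training,41,3,1,4,8.2518,5.60
17,BDBM50026234,training,40,1,0,4,8.2218,6.00
18,BDBM50332773,training,36,1,0,4,8.0969,8.00
19,BDBM50332765,training,36,1,0,4,7.7212,19.00
20,BDBM50336012,training,33,2,0,3,7.6777,21.00
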