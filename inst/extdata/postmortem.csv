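animal_id,wound_tracts,pellets_head,pellets_neck,pellets_thorax,pellets_abdomen,pellets_limbs,pellets_expected,body_mass_kg,mass_censored,exam
D0001,4,1,0,2,1,0,18,55.5,false,EX_SITU
D0005,4,0,0,4,0,0,18,47.0,false,EX_SITU
D0006,8,0,0,6,0,2,18,48.5,false,EX_SITU
D0018,4,0,0,4,0,0,27,56.5,false,EX_SITU
D0022,2,0,0,0,0,0,0,41.5,false,EX_SITU
D0024,2,0,0,0,0,0,0,60.5,false,EX_SITU
D0025,2,,,,,,0,,,IN_SITU_ONLY
D0028,3,,,,,,0,,,IN_SITU_ONLY
D0030,4,,,,,,0,,,IN_SITU_ONLY
D0031,2,0,0,0,0,0,0,77.5,false,EX_SITU
D0032,2,0,0,0,0,0,0,83.0,false,EX_SITU
D0037,2,0,0,0,0,0,0,70.5,false,EX_SITU
D0042,2,0,0,0,0,0,0,53.0,false,EX_SITU
D0043,2,,,,,,0,,,IN_SITU_ONLY
D0044,2,0,0,0,0,0,0,93.0,false,EX_SITU
D0046,5,0,1,4,0,0,54,34.5,false,EX_SITU
D0048,19,1,1,9,2,6,81,69.0,false,EX_SITU
D0055,14,0,1,10,2,1,54,38.5,false,EX_SITU
D0057,9,,,,,,54,,,IN_SITU_ONLY
D0063,27,1,2,19,4,1,108,56.0,false,EX_SITU
D0064,22,0,3,16,1,2,81,62.0,false,EX_SITU
D0070,8,0,2,5,0,1,32,50.5,false,EX_SITU
D0083,8,0,1,6,0,1,32,100.0,true,EX_SITU
D0088,7,0,1,4,2,0,32,32.5,false,EX_SITU
D0102,5,0,1,3,1,0,32,65.5,false,EX_SITU
D0109,18,2,1,10,3,2,48,96.5,false,EX_SITU
D0111,11,,,,,,32,,,IN_SITU_ONLY
D0112,8,0,1,7,0,0,32,100.0,false,EX_SITU
D0118,15,,,,,,48,,,IN_SITU_ONLY
D0125,2,,,,,,0,,,IN_SITU_ONLY
D0145,6,0,0,5,0,1,27,85.0,false,EX_SITU
D0153,5,0,2,2,1,0,27,96.0,false,EX_SITU
D0158,2,,,,,,18,,,IN_SITU_ONLY
D0161,4,1,1,2,0,0,18,58.0,false,EX_SITU
D0163,1,0,0,1,0,0,18,63.0,false,EX_SITU
D0166,20,,,,,,81,,,IN_SITU_ONLY
D0208,2,0,0,0,0,0,0,100.0,true,EX_SITU
D0214,5,,,,,,18,,,IN_SITU_ONLY
D0217,7,0,1,3,1,2,18,62.0,false,EX_SITU
D0220,2,0,0,1,0,1,18,76.5,false,EX_SITU
D0230,7,1,1,5,0,0,27,68.0,false,EX_SITU
D0235,9,0,1,6,0,2,32,65.0,false,EX_SITU
D0240,7,0,0,7,0,0,48,60.5,false,EX_SITU
D0243,14,,,,,,48,,,IN_SITU_ONLY
D0244,11,1,1,7,0,2,48,33.5,false,EX_SITU
D0248,4,,,,,,32,,,IN_SITU_ONLY
D0249,3,,,,,,32,,,IN_SITU_ONLY
D0253,10,1,0,9,0,0,48,36.0,false,EX_SITU
D0255,7,0,0,6,1,0,32,96.0,false,EX_SITU
D0266,14,0,2,10,2,0,54,100.0,true,EX_SITU
D0268,10,1,2,5,1,1,54,60.0,false,EX_SITU
D0270,5,0,1,4,0,0,54,36.0,false,EX_SITU
D0271,16,1,1,11,2,1,54,59.5,false,EX_SITU
D0274,24,,,,,,108,,,IN_SITU_ONLY
D0275,14,2,0,6,4,2,54,45.0,false,EX_SITU
D0278,11,2,0,8,0,1,54,60.0,false,EX_SITU
D0285,3,0,0,3,0,0,18,74.5,false,EX_SITU
D0286,2,,,,,,18,,,IN_SITU_ONLY
D0293,4,0,2,2,0,0,18,48.5,false,EX_SITU
D0304,4,0,0,0,0,0,0,35.5,false,EX_SITU
D0306,2,0,0,0,0,0,0,67.5,false,EX_SITU
D0309,3,0,0,0,0,0,0,43.0,false,EX_SITU
D0313,3,0,0,0,0,0,0,45.0,false,EX_SITU
D0314,2,0,0,0,0,0,0,45.5,false,EX_SITU
D0316,3,0,0,0,0,0,0,75.0,false,EX_SITU
D0321,2,0,0,0,0,0,0,60.5,false,EX_SITU
D0322,2,,,,,,0,,,IN_SITU_ONLY
D0324,2,0,0,0,0,0,0,77.5,false,EX_SITU
D0325,12,1,2,7,1,1,54,89.0,false,EX_SITU
D0329,12,2,1,8,1,0,54,69.0,false,EX_SITU
D0334,19,3,2,10,2,2,81,87.5,false,EX_SITU
D0340,9,,,,,,54,,,IN_SITU_ONLY
D0342,16,,,,,,81,,,IN_SITU_ONLY
D0343,8,1,1,6,0,0,54,49.0,false,EX_SITU
D0346,8,,,,,,54,,,IN_SITU_ONLY
D0351,6,0,0,5,1,0,32,77.0,false,EX_SITU
D0360,7,0,0,7,0,0,32,49.0,false,EX_SITU
D0364,5,0,1,2,1,1,32,76.5,false,EX_SITU
D0368,7,0,1,6,0,0,32,26.5,false,EX_SITU
D0371,8,2,1,5,0,0,32,36.5,false,EX_SITU
D0372,5,,,,,,18,,,IN_SITU_ONLY
D0376,5,,,,,,18,,,IN_SITU_ONLY
D0390,4,1,0,2,0,1,27,41.5,false,EX_SITU
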