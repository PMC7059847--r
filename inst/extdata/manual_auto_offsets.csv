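file_id,target_id,group,rater_1,rater_2,rater_3,rater_4,auto
Study2.wav,synctune.wav,study2,7.921,7.920,7.913,7.917,7.916
s01_w.wav,bigbunny.wav,study3,5.870,5.834,5.816,5.808,5.807
s02_w.wav,bigbunny.wav,study3,5.401,5.377,5.399,5.387,5.387
s03_w.wav,bigbunny.wav,study3,6.381,6.315,6.363,6.377,6.372
s04_w.wav,bigbunny.wav,study3,5.500,5.515,5.500,5.511,5.516
s05_w.wav,bigbunny.wav,study3,11.834,11.906,11.833,11.832,11.833
s02_d.wav,s01_d.wav,study4,4.840,4.864,4.900,4.901,4.897
s02_d.wav,s01_d.wav,study4,5.930,5.973,5.983,5.959,5.978
s04_w.wav,s01_d.wav,study4,5.600,5.675,5.658,5.665,5.660
s05_w.wav,s01_d.wav,study4,4.502,4.507,4.508,4.511,4.504
01.wav,clap.wav,supplementary,18.922,18.924,18.924,18.920,18.924
02.wav,clap.wav,supplementary,16.216,16.218,16.218,16.217,16.218
03.wav,synctune.wav,supplementary,12.001,12.011,12.006,12.003,12.003
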