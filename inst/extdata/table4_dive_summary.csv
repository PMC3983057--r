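lme,sex,day_mean,day_sd,mostly_day_mean,mostly_day_sd,mostly_night_mean,mostly_night_sd,night_mean,night_sd,day_n,mostly_day_n,mostly_night_n,night_n,total_dives
BB,F,NA,NA,NA,NA,NA,NA,NA,NA,0,0,0,0,0
BB,M,117.4,54.0,115.7,24.1,NA,NA,39.6,40.8,966,84,0,503,1553
BS,F,42.4,20.6,24.6,15.8,NA,NA,27.1,23.4,205,378,8,1679,2270
BS,M,78,45.0,74.8,50.0,NA,NA,62.4,36.7,1240,583,0,4874,6697
NP,F,40.3,26.0,27.5,22.2,22.1,17.3,23.5,23.0,584,4749,8254,12101,25688
NP,M,90,40.2,64.6,32.6,46.7,30.7,24.8,18.3,24436,4781,5179,4696,39092
AS,F,21.1,16.4,18.9,8.5,NA,NA,15.6,6.6,170,697,0,3205,4072
AS,M,158.7,72.0,169.3,58.2,NA,NA,31.9,33.7,711,450,0,231,1392
CC,F,37.1,19.5,28.5,13.1,25.3,13.4,22.7,10.6,1323,1857,391,437,4008
CC,M,NA,NA,NA,NA,NA,NA,NA,NA,0,0,0,0,0
GA,F,33.1,41.8,31.4,15.4,39.6,22.9,29.7,22.5,31,3115,7460,7559,18165
GA,M,NA,NA,NA,NA,NA,NA,NA,NA,0,0,0,0,0
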