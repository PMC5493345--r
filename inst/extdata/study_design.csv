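site,year,regime,ma_id,n_grounds,n_loco,n_limpet
Las Cruces,2013,NT,NA,1,282,352
Las Cruces,2013,OAA,NA,1,136,203
Algarrobo,2013,OAA,NA,5,422,724
Algarrobo,1999,MA,A,NA,1062,2266
Algarrobo,2000,MA,A,NA,972,1127
Algarrobo,2001,MA,A,NA,595,281
Algarrobo,2002,MA,A,NA,640,843
Algarrobo,2003,MA,A,NA,210,211
Algarrobo,2004,MA,A,NA,198,158
Algarrobo,2005,MA,A,NA,143,156
Algarrobo,2006,MA,A,NA,430,879
Algarrobo,2007,MA,A,NA,995,1044
Algarrobo,2008,MA,A,NA,248,561
Algarrobo,2009,MA,A,NA,252,196
Algarrobo,2010,MA,A,NA,225,278
Algarrobo,2013,MA,A,4,220,656
Algarrobo,1999,MA,B,NA,1531,1556
Algarrobo,2000,MA,B,NA,991,1590
Algarrobo,2001,MA,B,NA,560,980
Algarrobo,2002,MA,B,NA,656,1350
Algarrobo,2003,MA,B,NA,272,715
Algarrobo,2004,MA,B,NA,325,499
Algarrobo,2005,MA,B,NA,251,390
Algarrobo,2006,MA,B,NA,635,728
Algarrobo,2007,MA,B,NA,754,1212
Algarrobo,2011,MA,B,NA,349,363
Algarrobo,2013,MA,B,5,296,424
Algarrobo,1999,MA,C,NA,1207,1182
Algarrobo,2000,MA,C,NA,956,1398
Algarrobo,2001,MA,C,NA,1075,1294
Algarrobo,2002,MA,C,NA,1090,1103
Algarrobo,2003,MA,C,NA,1289,589
Algarrobo,2004,MA,C,NA,499,467
Algarrobo,2005,MA,C,NA,209,169
Algarrobo,2006,MA,C,NA,1077,587
Algarrobo,2007,MA,C,NA,878,467
Algarrobo,2008,MA,C,NA,520,1010
Algarrobo,2010,MA,C,NA,175,73
Algarrobo,2011,MA,C,NA,450,449
Algarrobo,2013,MA,C,3,325,498
Quintay,2013,OAA,NA,13,1352,2699
Quintay,2001,MA,A,NA,6753,6561
Quintay,2002,MA,A,NA,1920,2614
Quintay,2004,MA,A,NA,443,1040
Quintay,2006,MA,A,NA,595,1052
Quintay,2007,MA,A,NA,1083,1602
Quintay,2011,MA,A,NA,803,1603
Quintay,2013,MA,A,4,208,438
Quintay,1999,MA,B,NA,586,1254
Quintay,2000,MA,B,NA,4906,1775
Quintay,2001,MA,B,NA,2735,NA
Quintay,2002,MA,B,NA,2506,2486
Quintay,2004,MA,B,NA,508,1042
Quintay,2006,MA,B,NA,446,1593
Quintay,2008,MA,B,NA,1672,756
Quintay,2009,MA,B,NA,478,1378
Quintay,2011,MA,B,NA,1039,1586
Quintay,2013,MA,B,7,462,718
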