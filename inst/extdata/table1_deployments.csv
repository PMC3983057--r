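id,sex,capture_site,transmitter,dive_data,mass_kg,capture_date,departure_date,last_transmission_date,days_to_migration,migrating_days,passes
662,F,Polovina Cliffs,SPLASH,yes,33.6,2009-10-02,2009-11-11,2010-03-13,40.5,122.0,Unimak Pass
665,F,Polovina Cliffs,KiwiSat 202,no,37.8,2009-10-05,2009-11-23,2010-01-23,49.5,60.5,Unimak Pass
670,F,Polovina Cliffs,SPLASH,yes,35.6,2009-10-02,2009-11-05,2010-02-23,34.5,110.0,Unimak Pass
671,F,Polovina Cliffs,SPLASH,yes,44.0,2009-10-03,2009-11-12,2009-12-22,40.3,40.0,Unimak Pass
672,F,Polovina Cliffs,SPLASH,yes,28.4,2009-10-03,2009-11-14,2009-12-28,42.0,44.3,Unimak Pass
673,F,Polovina Cliffs,SPLASH,yes,32.4,2009-10-03,2009-10-30,2009-12-12,27.8,42.5,Unimak Pass
674,F,Polovina Cliffs,SPLASH,yes,45.4,2009-10-03,2009-11-13,2010-03-04,41.5,110.5,Unimak Pass
675,F,Polovina Cliffs,KiwiSat 202,no,27.0,2009-10-05,2009-11-14,2009-11-15,40.0,1.0,n/a
676,F,Polovina Cliffs,KiwiSat 202,no,38.0,2009-10-05,2009-11-12,2010-03-11,38.0,119.0,Akutan Pass
677,F,Polovina Cliffs,KiwiSat 202,no,37.6,2009-10-07,2009-10-15,2010-03-03,8.0,139.0,Unimak Pass
678,M,Zapadni Sands,SRDL,yes,149.1,2009-10-22,2009-10-25,2010-01-31,3.5,98.0,Unimak Pass
679,M,Zapadni Sands,SRDL,yes,152.9,2009-10-22,2009-11-08,2010-05-22,17.5,194.9,Buldir-Kiska Pass; Amukta Pass; Tanaga Pass
680,M,Zapadni Sands,SRDL,yes,114.2,2009-10-23,2009-10-25,2010-04-09,2.8,166.0,Amchitka Pass
681,M,Reef,SRDL,yes,118.7,2009-10-23,2009-11-06,2009-12-25,14.3,49.0,Yunaska Is. Pass
682,M,Zapadni Sands,SRDL,yes,221.8,2009-10-24,2009-11-11,2010-05-19,18.5,189.4,Samalga Pass
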