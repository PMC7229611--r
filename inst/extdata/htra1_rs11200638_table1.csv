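author,year,country,ethnicity,amd_type,soc,method,case_AA,case_AG,case_GG,ctrl_AA,ctrl_AG,ctrl_GG,hwe_p_printed
Tian,2012,China,Asian,AMD,HB,Typer 4.0 software,255,193,84,104,224,140,0.423
Ruamviboonsuk,2017,Thailand,Asian,wet,PB,InfiniumOmniExpressExome-8 v1.3 platform,125,164,88,146,490,437,0.643
Chu,2008,China,Asian,wet,HB,PCR-RFLP,76,52,16,31,69,26,0.276
Losonczy,2011,Hungary,Caucasian,AMD,HB,PCR-RFLP,23,50,30,3,49,43,0.133
Tuo,2008,USA,Caucasian,AMD,PB,PCR-RFLP,33,60,49,7,51,74,0.638
Tuo,2008,USA,Caucasian,AMD,PB,PCR-RFLP,63,164,103,12,73,106,0.904
Tuo,2008,USA,Caucasian,AMD,PB,PCR-RFLP,15,122,135,20,186,349,0.431
Tuo,2008,USA,Caucasian,AMD,PB,PCR-RFLP,2,15,29,1,6,15,0.696
Chan,2007,USA,Caucasian,AMD,HB,RT-PCR,14,27,11,0,8,5,0.109
Kanda,2007,USA,Caucasian,AMD,HB,RT-PCR,102,183,172,11,90,179,0.94
Cheng,2013,China,Asian,wet,HB,Sequencing,52,30,11,21,42,30,0.395
Liang,2012,China,Asian,wet,HB,Sequencing,61,83,17,30,72,48,0.751
Jiang,2008,China,Asian,wet,HB,Sequencing,99,47,13,31,67,42,0.662
Lee,2010,Korea,Asian,wet,HB,Sequencing,57,59,21,35,100,52,0.283
Lin,2008,China-Taiwan,Asian,AMD,HB,Sequencing,53,33,9,19,47,24,0.651
Kaur,2008,India,Asian,AMD,HB,Sequencing,90,89,50,21,85,78,0.765
Xu,2007,China,Asian,wet,HB,Sequencing,56,52,13,24,64,44,0.931
Tam,2008,China-Hong Kong,Asian,wet,HB,Sequencing,94,51,18,38,90,55,0.916
Mori,2007,Japan,Asian,AMD,HB,Sequencing,45,52,26,22,57,54,0.298
Askari,2015,Iran,Asian,AMD,HB,Sequencing,58,42,20,12,66,42,0.057
Lana,2018,Brazil,Caucasian,AMD,HB,Sequencing,73,89,42,22,77,67,0.987
Kaur,2013,India,Asian,AMD,PB,Sequencing,84,70,44,17,67,61,0.829
Ng,2016,Hong Kong,Asian,wet,PB,Sequencing,109,63,22,38,90,55,0.916
Kaur,2013,India,Caucasian,AMD,PB,Sequencing,130,292,194,17,138,271,0.913
Chen,2013,China,Asian,AMD,HB,TaqMan,28,74,56,21,77,59,0.599
Kondo,2007,Japan,Asian,AMD,HB,TaqMan,29,39,5,16,40,38,0.334
Leveziel,2007,France,Caucasian,wet,HB,TaqMan,32,57,29,5,41,70,0.743
Weger,2007,Austria,Caucasian,wet,PB,TaqMan,67,108,67,8,50,99,0.609
Lu,2007,China,Asian,wet,HB,PCR-RFLP,53,34,3,15,63,28,lt_0.05
Cruz-Gonzalez,2013,Spain,Caucasian,AMD,HB,PCR-RFLP,29,60,32,61,21,9,lt_0.05
Mohamad,2019,Malaysia,Asian,wet,HB,PCR-RFLP,79,47,19,48,82,15,lt_0.05
Yang,2010,China,Asian,wet,HB,PCR-RFLP,31,45,33,30,50,70,lt_0.05
Chen,2008,USA,Caucasian,AMD,HB,Sequencing,131,400,245,10,128,156,lt_0.05
Zeng,2011,China,Caucasian,AMD,PB,SNaPshot,244,641,450,21,181,307,0.374
Li,2015,China,Asian,AMD,HB,MassARRAY MALDI-TOF,73,54,19,44,74,27,0.674
Yang,2018,China,Asian,AMD,HB,MassARRAY MALDI-TOF,103,74,24,42,100,59,0.975
Matuskova,2020,Czech Republic,Caucasian,wet,HB,SNaPshot Multiplex-System,69,148,90,9,66,116,0.921
Fritsche,2008,Germany,Caucasian,AMD,PB,Multiplex PCR,152,344,264,22,174,353,0.923
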