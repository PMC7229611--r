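author,year,country,ethnicity,amd_type,soc,method,case_AA,case_AG,case_GG,ctrl_AA,ctrl_AG,ctrl_GG,hwe_p_printed
Lin,2008,China-Taiwan,Asian,dry,HB,Sequencing,28,19,5,19,47,24,0.651
Chan,2007,USA,Caucasian,dry,HB,RT-PCR,4,10,4,0,8,5,0.109
Mori,2007,Japan,Asian,dry,HB,Sequencing,4,7,8,5,41,70,0.743
Askari,2015,Iran,Asian,dry,HB,Sequencing,11,12,9,12,66,42,0.576
Ruamviboonsuk,2017,Thailand,Asian,wet,PB,InfiniumOmniExpressExome-8 v1.3 platform,125,164,88,146,490,437,0.643
Cheng,2013,China,Asian,wet,HB,Sequencing,52,30,11,21,42,30,0.395
Ng,2016,Hong Kong,Asian,wet,PB,Sequencing,109,63,22,38,90,55,0.915
Liang,2012,China,Asian,wet,HB,Sequencing,61,83,17,30,72,48,0.75
Chu,2008,China,Asian,wet,HB,PCR-RFLP,76,52,16,31,69,26,0.276
Jiang,2008,China,Asian,wet,HB,Sequencing,99,47,13,31,67,42,0.662
Lee,2010,Korea,Asian,wet,HB,Sequencing,57,59,21,35,100,52,0.283
Lin,2008,China-Taiwan,Asian,wet,HB,Sequencing,25,14,4,19,47,24,0.651
Xu,2007,China,Asian,wet,HB,Sequencing,56,52,13,24,64,44,0.931
Tam,2008,China-Hong Kong,Asian,wet,HB,Sequencing,94,51,18,38,90,55,0.916
Chan,2007,USA,Caucasian,wet,HB,RT-PCR,8,16,7,0,8,5,0.109
Leveziel,2007,France,Caucasian,wet,HB,TaqMan,32,57,29,5,41,70,0.743
Mori,2007,Japan,Asian,wet,HB,Sequencing,41,45,18,5,41,70,0.743
Askari,2015,Iran,Asian,wet,HB,Sequencing,47,30,11,12,66,42,0.576
Weger,2007,Austria,Caucasian,wet,PB,TaqMan,67,108,67,8,50,99,0.609
Lu,2007,China,Asian,wet,HB,PCR-RFLP,53,34,3,15,63,28,lt_0.05
Mohamad,2019,Malaysia,Asian,wet,HB,PCR-RFLP,79,47,19,48,82,15,lt_0.05
Yang,2010,China,Asian,wet,HB,PCR-RFLP,31,45,33,30,50,70,lt_0.05
Chen,2008,USA,Caucasian,wet,HB,Sequencing,76,245,149,10,128,156,lt_0.05
Chen,2008,USA,Caucasian,dry,HB,Sequencing,55,155,96,10,128,156,lt_0.05
Zeng,2011,China,Caucasian,dry,PB,SNaPshot,60,166,115,21,181,307,0.374
Zeng,2011,China,Caucasian,wet,PB,SNaPshot,184,475,335,21,181,307,0.374
Matuskova,2020,Czech Republic,Caucasian,wet,HB,SNaPshot Multiplex-System,69,148,90,9,66,116,0.921
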