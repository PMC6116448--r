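study_id,source,treatment,n_subjects,relapses,person_years,edss
Lanzillo 2012,RWE,Natalizumab,42,10,42,3.5
Lanzillo 2012,RWE,Rebif 44,42,23,42,NA
Limmroth 2007,RWE,Avonex,1094,1116,2188,2.62
Limmroth 2007,RWE,Betaferon,1034,1075,2068,NA
Limmroth 2007,RWE,Rebif 22,555,588,1110,NA
Limmroth 2007,RWE,Rebif 44,185,233,370,NA
Halpern 2011,RWE,Natalizumab,288,21,72,NA
Halpern 2011,RWE,Avonex,151,7,38,NA
Halpern 2011,RWE,Rebif 22,329,22,82,NA
Halpern 2011,RWE,Betaferon,144,11,36,NA
Halpern 2011,RWE,Glatiramer acetate,469,25,117,NA
Patti 2006,RWE,Betaferon,114,137,570,2.2
Patti 2006,RWE,Avonex,37,50,185,NA
Patti 2006,RWE,Rebif 22,17,35,85,NA
Rio 2005,RWE,Placebo,107,288,356,2.73
Rio 2005,RWE,Glatiramer acetate,101,204,334,NA
Haas and Firzlaff 2005,RWE,Avonex,79,109,158,2.2
Haas and Firzlaff 2005,RWE,Betaferon,77,123,154,2.28
Haas and Firzlaff 2005,RWE,Glatiramer acetate,127,115,254,2.12
Khan 2001,RWE,Placebo,15,23,23,2.63
Khan 2001,RWE,Avonex,34,41,51,2.71
Khan 2001,RWE,Betaferon,34,28,51,2.6
Khan 2001,RWE,Glatiramer acetate,39,29,59,2.64
Trojano 2003,RWE,Betaferon,209,136,418,2.5
Trojano 2003,RWE,Avonex,169,120,338,2.4
Carra 2003,RWE,Avonex,26,14,35,2.02
Carra 2003,RWE,Rebif 44,20,22,27,2.08
Carra 2003,RWE,Betaferon,20,11,27,3.31
Carra 2003,RWE,Glatiramer acetate,30,8,40,2.45
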