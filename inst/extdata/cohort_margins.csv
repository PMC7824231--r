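variable,type,category,sample_x,sample_n,pop_x,pop_n,sample_mean,sample_sd,pop_mean
male,proportion,yes,116,201,748,1456,,,
maternal_smoking,proportion,yes,39,200,362,1442,,,
maternal_asthma,proportion,yes,25,200,158,1438,,,
caesarean,proportion,yes,19,167,110,1187,,,
ebf,proportion,yes,46,201,240,1319,,,
eff,proportion,yes,18,201,119,1343,,,
mixed,proportion,yes,137,201,956,1318,,,
birth_order,multinomial,1,80,188,491,1152,,,
birth_order,multinomial,2,60,188,394,1152,,,
birth_order,multinomial,3+,48,188,267,1152,,,
ses,multinomial,high,21,201,104,1293,,,
ses,multinomial,medium,115,201,995,1293,,,
ses,multinomial,low,25,201,194,1293,,,
season_birth,multinomial,winter,44,201,417,1455,,,
season_birth,multinomial,spring,45,201,364,1455,,,
season_birth,multinomial,summer,61,201,352,1455,,,
season_birth,multinomial,fall,51,201,322,1455,,,
season_age10,multinomial,winter,66,201,442,1456,,,
season_age10,multinomial,spring,29,201,285,1456,,,
season_age10,multinomial,summer,37,201,225,1456,,,
season_age10,multinomial,fall,69,201,504,1456,,,
birthweight,continuous,,,197,,,3.3,0.6,3.4
maternal_age,continuous,,,184,,,29.6,0.3,29.2
bf_duration_weeks,continuous,,,201,,,15.3,14.1,14.4
formula_intro_week,continuous,,,201,,,9.6,10.5,8.9
solids_intro_week,continuous,,,201,,,15.2,5.2,14.3
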