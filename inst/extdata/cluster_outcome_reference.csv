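cluster,n,death_rate,hospitalization_rate,mean_hosp,sd_hosp,mean_los,sd_los,prop_hosp_events_mental,prop_hospitalized_with_mental,published_asd_death,published_asd_hospitalization,published_asd_n_hospitalizations,published_asd_length_of_stay,published_asd_prop_hosp_events_mental,published_asd_prop_hospitalized_with_mental
1,4077,0.013,0.279,0.5,1.1,11.1,35.1,0.730,0.773,NA,NA,NA,NA,NA,NA
2,1386,0.021,0.361,0.8,1.4,14.5,39.3,0.718,0.772,6,18,24,9,3,0
3,1906,0.008,0.273,0.5,1.1,9.3,30.4,0.772,0.785,5,1,0,5,10,3
4,2105,0.014,0.276,0.6,1.3,10.2,34.0,0.662,0.710,1,1,8,3,15,15
5,3874,0.010,0.135,0.2,0.7,4.0,21.3,0.639,0.689,3,36,33,24,20,19
6,1617,0.046,0.351,0.7,1.4,9.4,32.2,0.353,0.445,20,16,16,5,82,71
7,3634,0.014,0.200,0.3,0.9,5.9,26.0,0.578,0.607,1,19,20,17,32,36
8,1401,0.026,0.511,1.4,2.2,22.8,52.9,0.641,0.721,9,49,52,26,19,12
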