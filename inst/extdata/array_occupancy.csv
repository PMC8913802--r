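array,role,n_sensors,occupancy_pre_2019,occupancy_post_2020,occupancy_post_5_10yr
Ulidarra NP,control,25,100,96,NA
Lower Bucca SF,treatment,26,100,92,NA
Bago Bluff NP,control,25,96,71,NA
Cowarra SF,treatment,26,92,85,NA
Kumbatine NP,control,25,100,100,NA
Kalateenee SF,treatment,25,96,100,NA
Kiwarrak SF,previously_harvested,26,NA,NA,100
Comboyne SF,previously_harvested,26,NA,NA,100
Cairncross SF,previously_harvested,25,NA,NA,100
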