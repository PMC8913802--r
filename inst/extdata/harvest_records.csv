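forest,years,area_ha,volume_m3,design_group
Cowarra,2020,264,6177,selective_baci
Kalateenee,2020,289,4771,selective_baci
Lower Bucca,2020,304,15480,selective_baci
Comboyne,2009;2011;2016,296,61209,heavy_previous
Cairncross,2012;2013,466,18370,heavy_previous
Kiwarrak,2011,169,9093,heavy_previous
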