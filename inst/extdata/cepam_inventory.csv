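region,year,source,rate_tons_per_day,printed_total
imperial,2022,mobile,12.4,15.2
imperial,2022,biomass_burning,0.1,15.2
imperial,2022,stationary,1.7,15.2
imperial,2022,biogenic_soil,0.9,15.2
coachella,2022,mobile,15.9,18.0
coachella,2022,biomass_burning,0.7,18.0
coachella,2022,stationary,1.3,18.0
coachella,2022,biogenic_soil,0.1,18.0
ssab,2022,mobile,28.3,33.2
ssab,2022,biomass_burning,0.8,33.2
ssab,2022,stationary,3.0,33.2
ssab,2022,biogenic_soil,1.0,33.2
imperial_nei,2020,mobile,11.9,16.3
imperial_nei,2020,biomass_burning,0.5,16.3
imperial_nei,2020,stationary,1.3,16.3
imperial_nei,2020,biogenic_soil,2.7,16.3
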