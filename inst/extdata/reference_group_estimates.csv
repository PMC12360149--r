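quantity,group,value,unit
mean_depth,immature,28.3,m
mean_depth,mature,18.3,m
predicted_region_use,wild,0.82,regions_per_season
predicted_region_use,stocked,0.71,regions_per_season
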