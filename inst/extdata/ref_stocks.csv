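climate_zone,soil_class,soc_ref_mg_c_ha
cold-temperate-dry,high-activity-mineral,50
cold-temperate-dry,low-activity-mineral,33
cold-temperate-dry,sandy,34
cold-temperate-moist,high-activity-mineral,95
cold-temperate-moist,low-activity-mineral,85
cold-temperate-moist,sandy,71
cold-temperate-moist,spodic,115
warm-temperate-dry,high-activity-mineral,38
warm-temperate-dry,low-activity-mineral,24
warm-temperate-dry,sandy,24
warm-temperate-moist,high-activity-mineral,88
warm-temperate-moist,low-activity-mineral,63
warm-temperate-moist,sandy,34
tropical-dry,high-activity-mineral,38
tropical-dry,low-activity-mineral,35
tropical-dry,sandy,31
tropical-moist,high-activity-mineral,65
tropical-moist,low-activity-mineral,47
tropical-moist,sandy,39
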