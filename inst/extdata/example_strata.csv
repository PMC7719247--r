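stratum_id,state,region,climate_zone,soil_class,rotation,input_level,area_ha,landuse_1982,tillage_1982,landuse_1997,tillage_1997
HR001,IA,HR,cold-temperate-moist,high-activity-mineral,continuous-row-crop,medium,1200000,long-term-cultivated,CT,long-term-cultivated,CT
HR002,IA,HR,cold-temperate-moist,high-activity-mineral,continuous-row-crop,medium,450000,long-term-cultivated,CT,long-term-cultivated,RT
HR003,IL,HR,cold-temperate-moist,high-activity-mineral,row-crop-small-grain,high,300000,long-term-cultivated,CT,long-term-cultivated,NT
NCR01,WI,NCR,cold-temperate-moist,sandy,hay-rotation,high,150000,non-crop,none,long-term-cultivated,CT
PGR01,TX,PGR,warm-temperate-dry,high-activity-mineral,wheat-fallow,low,800000,long-term-cultivated,CT,long-term-cultivated,CT
PGR02,TX,PGR,warm-temperate-dry,sandy,wheat-fallow,low,350000,long-term-cultivated,CT,long-term-cultivated,RT
PGR03,OK,PGR,warm-temperate-dry,low-activity-mineral,continuous-small-grain,medium,420000,long-term-cultivated,RT,long-term-cultivated,RT
SSR01,NC,SSR,warm-temperate-moist,sandy,continuous-row-crop,medium,220000,long-term-cultivated,RT,long-term-cultivated,NT
SSR02,NC,SSR,warm-temperate-moist,high-activity-mineral,continuous-row-crop,medium,260000,non-crop,none,long-term-cultivated,RT
CRP01,KS,PGR,cold-temperate-dry,high-activity-mineral,wheat-fallow,low,180000,long-term-cultivated,CT,set-aside,none
NC001,KY,EUR,warm-temperate-moist,high-activity-mineral,hay-rotation,high,140000,non-crop,none,non-crop,none
RTC01,NE,NGPR,cold-temperate-dry,high-activity-mineral,continuous-row-crop,medium,90000,long-term-cultivated,RT,long-term-cultivated,CT
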