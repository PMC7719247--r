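state,payment_usd_per_ha_yr
IA,25.50
IL,31.75
WI,44.20
TX,112.10
OK,51.40
NC,62.35
KS,38.90
KY,47.80
NE,29.60
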