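domain,category,class
water,piped water into the dwelling,improved
water,piped water to yard/plot/compound,improved
water,public tap or standpipe,improved
water,tubewell or borewell,improved
water,protected dug well,improved
water,protected spring,improved
water,rainwater,improved
water,unprotected dug well,unimproved
water,unprotected spring,unimproved
water,cart with small tank/drum,unimproved
water,tanker truck,unimproved
water,surface water,unimproved
water,river,unimproved
water,dam,unimproved
water,lake,unimproved
water,pond,unimproved
water,stream,unimproved
water,canal,unimproved
water,irrigation channel,unimproved
water,bottled water,unimproved
sanitation,flush toilet,improved
sanitation,piped sewer system,improved
sanitation,flush to piped sewer system,improved
sanitation,septic tank,improved
sanitation,flush to septic tank,improved
sanitation,ventilated improved pit latrine (vip),improved
sanitation,ventilated improved pit latrine,improved
sanitation,pit latrine with slab,improved
sanitation,composting toilet,improved
sanitation,pit latrine without slab,unimproved
sanitation,open pit,unimproved
sanitation,pit latrine,unimproved
sanitation,bucket,unimproved
sanitation,hanging toilet,unimproved
sanitation,hanging latrine,unimproved
sanitation,flush to somewhere else,unimproved
sanitation,flush to open drain,unimproved
sanitation,no facilities,open_defecation
sanitation,no facility,open_defecation
sanitation,bush,open_defecation
sanitation,field,open_defecation
sanitation,bush or field,open_defecation
sanitation,no facilities or bush or field,open_defecation
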