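method,kind,units_per_cyp,cyp_per_procedure,unit_cost_public,unit_cost_private,source_public_pct,source_private_pct,currency
tubal ligation,permanent,,10,2500000,4000000,90,10,IDR
pills,resupply,15,,5000,15000,30,70,IDR
IUD,long-acting,,4.6,100000,500000,45,55,IDR
injectable,resupply,4,,20000,35000,25,75,IDR
condoms,resupply,120,,1500,3000,30,70,IDR
implant,long-acting,,2.5,150000,600000,55,45,IDR
male sterilization,permanent,,10,2000000,3500000,95,5,IDR
other modern methods,resupply,1,,50000,100000,50,50,IDR
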