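sample_id,treatment,replicate_id,dilution_factor,cells_per_uL,droplet_uL,temperature_C,frozen_count,n_wells
DEMO-01,untreated,r1,1,100,20,-2,0,32
DEMO-01,untreated,r1,1,100,20,-4,0,32
DEMO-01,untreated,r1,1,100,20,-6,0,32
DEMO-01,untreated,r1,1,100,20,-8,26,32
DEMO-01,untreated,r1,1,100,20,-10,32,32
DEMO-01,untreated,r1,1,100,20,-12,32,32
DEMO-01,untreated,r1,1,100,20,-14,32,32
DEMO-01,untreated,r1,1,100,20,-16,32,32
DEMO-01,untreated,r1,1,100,20,-18,32,32
DEMO-01,untreated,r1,1,100,20,-20,32,32
DEMO-01,untreated,r1,1,100,20,-22,32,32
DEMO-01,untreated,r1,1,100,20,-24,32,32
DEMO-01,untreated,r1,1,100,20,-26,32,32
DEMO-01,untreated,r1,1,100,20,-28,32,32
DEMO-01,untreated,r2,1,100,20,-2,0,32
DEMO-01,untreated,r2,1,100,20,-4,0,32
DEMO-01,untreated,r2,1,100,20,-6,0,32
DEMO-01,untreated,r2,1,100,20,-8,26,32
DEMO-01,untreated,r2,1,100,20,-10,31,32
DEMO-01,untreated,r2,1,100,20,-12,32,32
DEMO-01,untreated,r2,1,100,20,-14,32,32
DEMO-01,untreated,r2,1,100,20,-16,32,32
DEMO-01,untreated,r2,1,100,20,-18,32,32
DEMO-01,untreated,r2,1,100,20,-20,32,32
DEMO-01,untreated,r2,1,100,20,-22,32,32
DEMO-01,untreated,r2,1,100,20,-24,32,32
DEMO-01,untreated,r2,1,100,20,-26,32,32
DEMO-01,untreated,r2,1,100,20,-28,32,32
DEMO-01,untreated,r3,1,100,20,-2,0,32
DEMO-01,untreated,r3,1,100,20,-4,0,32
DEMO-01,untreated,r3,1,100,20,-6,0,32
DEMO-01,untreated,r3,1,100,20,-8,27,32
DEMO-01,untreated,r3,1,100,20,-10,32,32
DEMO-01,untreated,r3,1,100,20,-12,32,32
DEMO-01,untreated,r3,1,100,20,-14,32,32
DEMO-01,untreated,r3,1,100,20,-16,32,32
DEMO-01,untreated,r3,1,100,20,-18,32,32
DEMO-01,untreated,r3,1,100,20,-20,32,32
DEMO-01,untreated,r3,1,100,20,-22,32,32
DEMO-01,untreated,r3,1,100,20,-24,32,32
DEMO-01,untreated,r3,1,100,20,-26,32,32
DEMO-01,untreated,r3,1,100,20,-28,32,32
DEMO-01,heated,r1,1,100,20,-2,0,32
DEMO-01,heated,r1,1,100,20,-4,0,32
DEMO-01,heated,r1,1,100,20,-6,0,32
DEMO-01,heated,r1,1,100,20,-8,0,32
DEMO-01,heated,r1,1,100,20,-10,0,32
DEMO-01,heated,r1,1,100,20,-12,0,32
DEMO-01,heated,r1,1,100,20,-14,0,32
DEMO-01,heated,r1,1,100,20,-16,0,32
DEMO-01,heated,r1,1,100,20,-18,0,32
DEMO-01,heated,r1,1,100,20,-20,0,32
DEMO-01,heated,r1,1,100,20,-22,0,32
DEMO-01,heated,r1,1,100,20,-24,0,32
DEMO-01,heated,r1,1,100,20,-26,1,32
DEMO-01,heated,r1,1,100,20,-28,4,32
DEMO-01,heated,r2,1,100,20,-2,0,32
DEMO-01,heated,r2,1,100,20,-4,0,32
DEMO-01,heated,r2,1,100,20,-6,0,32
DEMO-01,heated,r2,1,100,20,-8,0,32
DEMO-01,heated,r2,1,100,20,-10,0,32
DEMO-01,heated,r2,1,100,20,-12,0,32
DEMO-01,heated,r2,1,100,20,-14,0,32
DEMO-01,heated,r2,1,100,20,-16,0,32
DEMO-01,heated,r2,1,100,20,-18,0,32
DEMO-01,heated,r2,1,100,20,-20,0,32
DEMO-01,heated,r2,1,100,20,-22,0,32
DEMO-01,heated,r2,1,100,20,-24,1,32
DEMO-01,heated,r2,1,100,20,-26,3,32
DEMO-01,heated,r2,1,100,20,-28,7,32
DEMO-01,heated,r3,1,100,20,-2,0,32
DEMO-01,heated,r3,1,100,20,-4,0,32
DEMO-01,heated,r3,1,100,20,-6,0,32
DEMO-01,heated,r3,1,100,20,-8,0,32
DEMO-01,heated,r3,1,100,20,-10,0,32
DEMO-01,heated,r3,1,100,20,-12,0,32
DEMO-01,heated,r3,1,100,20,-14,0,32
DEMO-01,heated,r3,1,100,20,-16,0,32
DEMO-01,heated,r3,1,100,20,-18,0,32
DEMO-01,heated,r3,1,100,20,-20,0,32
DEMO-01,heated,r3,1,100,20,-22,0,32
DEMO-01,heated,r3,1,100,20,-24,2,32
DEMO-01,heated,r3,1,100,20,-26,2,32
DEMO-01,heated,r3,1,100,20,-28,6,32
DEMO-01,filtrate,r1,1,0,20,-2,0,32
DEMO-01,filtrate,r1,1,0,20,-4,0,32
DEMO-01,filtrate,r1,1,0,20,-6,0,32
DEMO-01,filtrate,r1,1,0,20,-8,0,32
DEMO-01,filtrate,r1,1,0,20,-10,0,32
DEMO-01,filtrate,r1,1,0,20,-12,0,32
DEMO-01,filtrate,r1,1,0,20,-14,0,32
DEMO-01,filtrate,r1,1,0,20,-16,0,32
DEMO-01,filtrate,r1,1,0,20,-18,0,32
DEMO-01,filtrate,r1,1,0,20,-20,0,32
DEMO-01,filtrate,r1,1,0,20,-22,0,32
DEMO-01,filtrate,r1,1,0,20,-24,0,32
DEMO-01,filtrate,r1,1,0,20,-26,1,32
DEMO-01,filtrate,r1,1,0,20,-28,5,32
DEMO-01,filtrate,r2,1,0,20,-2,0,32
DEMO-01,filtrate,r2,1,0,20,-4,0,32
DEMO-01,filtrate,r2,1,0,20,-6,0,32
DEMO-01,filtrate,r2,1,0,20,-8,0,32
DEMO-01,filtrate,r2,1,0,20,-10,0,32
DEMO-01,filtrate,r2,1,0,20,-12,0,32
DEMO-01,filtrate,r2,1,0,20,-14,0,32
DEMO-01,filtrate,r2,1,0,20,-16,0,32
DEMO-01,filtrate,r2,1,0,20,-18,0,32
DEMO-01,filtrate,r2,1,0,20,-20,0,32
DEMO-01,filtrate,r2,1,0,20,-22,0,32
DEMO-01,filtrate,r2,1,0,20,-24,2,32
DEMO-01,filtrate,r2,1,0,20,-26,2,32
DEMO-01,filtrate,r2,1,0,20,-28,5,32
DEMO-01,filtrate,r3,1,0,20,-2,0,32
DEMO-01,filtrate,r3,1,0,20,-4,0,32
DEMO-01,filtrate,r3,1,0,20,-6,0,32
DEMO-01,filtrate,r3,1,0,20,-8,0,32
DEMO-01,filtrate,r3,1,0,20,-10,0,32
DEMO-01,filtrate,r3,1,0,20,-12,0,32
DEMO-01,filtrate,r3,1,0,20,-14,0,32
DEMO-01,filtrate,r3,1,0,20,-16,0,32
DEMO-01,filtrate,r3,1,0,20,-18,0,32
DEMO-01,filtrate,r3,1,0,20,-20,0,32
DEMO-01,filtrate,r3,1,0,20,-22,0,32
DEMO-01,filtrate,r3,1,0,20,-24,0,32
DEMO-01,filtrate,r3,1,0,20,-26,0,32
DEMO-01,filtrate,r3,1,0,20,-28,4,32
DEMO-01,control,r1,1,0,20,-2,0,32
DEMO-01,control,r1,1,0,20,-4,0,32
DEMO-01,control,r1,1,0,20,-6,0,32
DEMO-01,control,r1,1,0,20,-8,0,32
DEMO-01,control,r1,1,0,20,-10,0,32
DEMO-01,control,r1,1,0,20,-12,0,32
DEMO-01,control,r1,1,0,20,-14,0,32
DEMO-01,control,r1,1,0,20,-16,0,32
DEMO-01,control,r1,1,0,20,-18,0,32
DEMO-01,control,r1,1,0,20,-20,0,32
DEMO-01,control,r1,1,0,20,-22,0,32
DEMO-01,control,r1,1,0,20,-24,2,32
DEMO-01,control,r1,1,0,20,-26,3,32
DEMO-01,control,r1,1,0,20,-28,5,32
DEMO-01,control,r2,1,0,20,-2,0,32
DEMO-01,control,r2,1,0,20,-4,0,32
DEMO-01,control,r2,1,0,20,-6,0,32
DEMO-01,control,r2,1,0,20,-8,0,32
DEMO-01,control,r2,1,0,20,-10,0,32
DEMO-01,control,r2,1,0,20,-12,0,32
DEMO-01,control,r2,1,0,20,-14,0,32
DEMO-01,control,r2,1,0,20,-16,0,32
DEMO-01,control,r2,1,0,20,-18,0,32
DEMO-01,control,r2,1,0,20,-20,0,32
DEMO-01,control,r2,1,0,20,-22,0,32
DEMO-01,control,r2,1,0,20,-24,1,32
DEMO-01,control,r2,1,0,20,-26,3,32
DEMO-01,control,r2,1,0,20,-28,6,32
DEMO-01,control,r3,1,0,20,-2,0,32
DEMO-01,control,r3,1,0,20,-4,0,32
DEMO-01,control,r3,1,0,20,-6,0,32
DEMO-01,control,r3,1,0,20,-8,0,32
DEMO-01,control,r3,1,0,20,-10,0,32
DEMO-01,control,r3,1,0,20,-12,0,32
DEMO-01,control,r3,1,0,20,-14,0,32
DEMO-01,control,r3,1,0,20,-16,0,32
DEMO-01,control,r3,1,0,20,-18,0,32
DEMO-01,control,r3,1,0,20,-20,0,32
DEMO-01,control,r3,1,0,20,-22,0,32
DEMO-01,control,r3,1,0,20,-24,1,32
DEMO-01,control,r3,1,0,20,-26,5,32
DEMO-01,control,r3,1,0,20,-28,10,32
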