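element,verdict,note,ld50_salt_mg_per_kg
Zr,biocompatible,zirconium salts show low acute oral toxicity; ZrCl4 oral-rat LD50 ~1688 mg/kg; widely used in biomedical frameworks,1688
Ti,biocompatible,titanium dioxide essentially non-toxic orally; LD50 > 10000 mg/kg,10000
Ca,biocompatible,essential element; calcium chloride oral-rat LD50 ~1000 mg/kg,1000
Mg,biocompatible,essential element; magnesium chloride oral-rat LD50 ~2800 mg/kg,2800
K,biocompatible,essential element; potassium chloride oral-rat LD50 ~2600 mg/kg,2600
Na,biocompatible,essential element; sodium chloride oral-rat LD50 ~3000 mg/kg,3000
Sr,biocompatible,strontium chloride oral-rat LD50 ~2250 mg/kg,2250
Fe,not_biocompatible,iron(III) chloride oral-rat LD50 ~450 mg/kg; admitted only via explicit whitelist on in-vivo evidence,450
Zn,not_biocompatible,zinc chloride oral-rat LD50 ~350 mg/kg; admitted only via explicit whitelist on in-vivo evidence,350
Cu,not_biocompatible,copper(II) sulfate oral-rat LD50 ~300 mg/kg,300
Mn,not_biocompatible,manganese chloride oral-rat LD50 ~1484 mg/kg; CNS accumulation concern,1484
Al,not_biocompatible,aluminium chloride oral-rat LD50 ~370 mg/kg,370
Cd,not_biocompatible,cadmium chloride oral-rat LD50 ~88 mg/kg; carcinogenic and nephrotoxic,88
Ni,not_biocompatible,nickel(II) chloride oral-rat LD50 ~105 mg/kg; sensitizer and carcinogen,105
Co,not_biocompatible,cobalt(II) chloride oral-rat LD50 ~80 mg/kg,80
Cr,not_biocompatible,chromium(VI) compounds acutely toxic and carcinogenic,50
Pb,not_biocompatible,cumulative neurotoxin,4665
Hg,not_biocompatible,mercuric chloride oral-rat LD50 ~1 mg/kg,1
As,not_biocompatible,arsenic trioxide oral-rat LD50 ~14 mg/kg,14
Ag,not_biocompatible,silver nitrate oral-rat LD50 ~1173 mg/kg; argyria on accumulation,1173
V,not_biocompatible,vanadium pentoxide oral-rat LD50 ~10 mg/kg,10
Ba,not_biocompatible,barium chloride oral-rat LD50 ~118 mg/kg,118
Be,not_biocompatible,beryllium compounds carcinogenic,86
Tl,not_biocompatible,thallium salts acutely toxic; LD50 ~16 mg/kg,16
La,not_biocompatible,lanthanum chloride oral-rat LD50 ~2370 mg/kg; bioaccumulation concern,2370
Ce,not_biocompatible,cerium chloride oral-rat LD50 ~2111 mg/kg; bioaccumulation concern,2111
Gd,not_biocompatible,free gadolinium nephrotoxic,378
U,not_biocompatible,radiotoxic and nephrotoxic,114
Th,not_biocompatible,radiotoxic,1000
Li,not_biocompatible,narrow therapeutic window; lithium chloride oral-rat LD50 ~526 mg/kg,526
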