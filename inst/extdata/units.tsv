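# term	canonical	concept_id (unit-of-measure lexicon)
ml	milliliter	UCUM:mL
milliliter	milliliter	UCUM:mL
milliliters	milliliter	UCUM:mL
mg	milligram	UCUM:mg
milligram	milligram	UCUM:mg
milligrams	milligram	UCUM:mg
mcg	microgram	UCUM:ug
microgram	microgram	UCUM:ug
g	gram	UCUM:g
gram	gram	UCUM:g
tablet	tablet	UCUM:{tbl}
tablets	tablet	UCUM:{tbl}
pill	pill	UCUM:{pill}
pills	pill	UCUM:{pill}
capsule	capsule	UCUM:{cap}
capsules	capsule	UCUM:{cap}
drop	drop	UCUM:{drp}
drops	drop	UCUM:{drp}
puff	puff	UCUM:{puff}
puffs	puff	UCUM:{puff}
tsp	teaspoon	UCUM:tsp
teaspoon	teaspoon	UCUM:tsp
tbsp	tablespoon	UCUM:tbs
tablespoon	tablespoon	UCUM:tbs
oz	ounce	UCUM:oz
units	unit	UCUM:U
unit	unit	UCUM:U
dose	dose	UCUM:{dose}
doses	dose	UCUM:{dose}
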