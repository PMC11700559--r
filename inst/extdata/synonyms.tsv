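tablets	tablet
tabs	tablet
tab	tablet
capsules	capsule
caps	capsule
cap	capsule
pills	pill
puffs	puff
drops	drop
sprays	spray
patches	patch
wks	week
wk	week
weeks	week
days	day
months	month
hrs	hr
hours	hr
hour	hr
minutes	minute
mins	minute
po	by mouth
orally	by mouth
milligrams	mg
milligram	mg
micrograms	mcg
microgram	mcg
ug	mcg
milliliters	ml
milliliter	ml
cc	ml
bid	2 times daily
tid	3 times daily
qid	4 times daily
qd	every day
qday	every day
qdaily	every day
qam	every morning
qpm	every evening
qhs	nightly
qod	every other day
twice a day	2 times daily
twice daily	2 times daily
twice	2 times
thrice	3 times
once	1 time
times per day	times daily
times a day	times daily
times each day	times daily
time per day	time daily
time a day	time daily
time each day	time daily
every night	nightly
at bedtime	nightly
each day	every day
every week	weekly
once weekly	weekly
as needed	prn
if needed	prn
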