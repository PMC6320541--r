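term	category
reef, buildup or bioherm	reefal
perireef or subreef	reefal
intrashelf/intraplatform reef	reefal
platform/shelf-margin reef	reefal
slope/ramp reef	reefal
basin reef	reefal
shallow subtidal indet.	shallow_subtidal
open shallow subtidal	shallow_subtidal
lagoonal/restricted shallow subtidal	shallow_subtidal
sand shoal	shallow_subtidal
shoreface	shallow_subtidal
foreshore	shallow_subtidal
transition zone/lower shoreface	shallow_subtidal
delta front	shallow_subtidal
ramp - inner	shallow_subtidal
platform - interior	shallow_subtidal
deep subtidal indet.	deep_subtidal
deep subtidal ramp	deep_subtidal
deep subtidal shelf	deep_subtidal
offshore	deep_subtidal
offshore indet.	deep_subtidal
offshore shelf	deep_subtidal
offshore ramp	deep_subtidal
storm-influenced	deep_subtidal
ramp - mid	deep_subtidal
platform - margin	deep_subtidal
marginal marine indet.	marginal_marine
peritidal	marginal_marine
lagoonal	marginal_marine
lagoonal indet.	marginal_marine
estuary/bay	marginal_marine
estuarine/bay	marginal_marine
paralic indet.	marginal_marine
delta plain	marginal_marine
interdistributary bay	marginal_marine
tidal flat	marginal_marine
sabkha	marginal_marine
coastal indet.	marginal_marine
slope	slope
slope indet.	slope
prodelta	slope
submarine fan	slope
ramp - outer	slope
deep ramp	slope
basinal (carbonate)	basin
basinal (siliceous)	basin
basinal (siliciclastic)	basin
basin indet.	basin
deep-water indet.	basin
abyssal	basin
pelagic	basin
marine indet.	unknown
carbonate indet.	unknown
siliciclastic indet.	unknown
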