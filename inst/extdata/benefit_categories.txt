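ornamental
soil improvers
hedges/shelters
human food
food additives
vertebrate food
invertebrate food
fuelwood
charcoal
biofuels
timber
cane
fibres
tannins/dyestuffs
beads
resins/gums
lipids
waxes
scents/essential oils
rubber
medicines
invertebrate poisons
vertebrate poisons
smoking materials/drugs
symbolism/inspiration
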