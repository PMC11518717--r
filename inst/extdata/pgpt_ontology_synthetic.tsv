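path	branch
PGPT	other
PGPT;direct_effect	direct
PGPT;direct_effect;biofertilization	direct
PGPT;direct_effect;biofertilization;nitrogen_acquisition	direct
PGPT;direct_effect;biofertilization;phosphate_solubilization	direct
PGPT;direct_effect;bioremediation	direct
PGPT;direct_effect;bioremediation;heavy_metal_detoxification	direct
PGPT;direct_effect;phytohormone_signaling	direct
PGPT;direct_effect;phytohormone_signaling;auxin_production	direct
PGPT;direct_effect;plant_vitamin_production	direct
PGPT;indirect_effect	indirect
PGPT;indirect_effect;stress_control	indirect
PGPT;indirect_effect;stress_control;abiotic_stress_neutralization	indirect
PGPT;indirect_effect;stress_control;biotic_stress_neutralization	indirect
PGPT;indirect_effect;immune_response_stimulation	indirect
PGPT;indirect_effect;colonization	indirect
PGPT;indirect_effect;colonization;surface_attachment	indirect
PGPT;indirect_effect;colonization;biofilm_formation	indirect
PGPT;indirect_effect;competitive_exclusion	indirect
PGPT;indirect_effect;competitive_exclusion;bacterial_fitness	indirect
PGPT;indirect_effect;competitive_exclusion;bacterial_secretion	indirect
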