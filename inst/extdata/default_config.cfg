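# forestmit experiment configuration — full factorial design (3456 scenarios)
# Syntax: key = value[, value...]; '#' starts a comment.

factor.rcp = RCP2.6, RCP4.5, RCP8.5
factor.disturbance_response = constant, linear, exponential
factor.forest_age = mature, young
factor.forest_type = BD, NE
factor.harvest_intensity = 0, 0.5, 1, 1.5
factor.salvage = yes, no
factor.material_usage = 1, 1.5
factor.cascade = 1, 1.5
factor.decarb_2050 = 0.25, 0.5, 0.75

run.n_patches = 100
run.n_sites = 1
run.seed = 1
run.horizons = 2050, 2100

# Emulator constants (defaults shown; uncomment to override)
# stand.npp_max = 0.714
# stand.carrying_capacity = 18
# stand.q10 = 2
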