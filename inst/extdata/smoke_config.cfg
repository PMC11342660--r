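# Minimal smoke-test design: one level per factor, runs in seconds.
factor.rcp = RCP4.5
factor.disturbance_response = exponential
factor.forest_age = mature
factor.forest_type = NE
factor.harvest_intensity = 1
factor.salvage = no
factor.material_usage = 1
factor.cascade = 1
factor.decarb_2050 = 0.5

run.n_patches = 10
run.seed = 1
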