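# Canonical internal units: lengths um, time s, pressure mmHg, viscosity mPa.s,
# oxygen amounts cm3 O2. Interface values use the field's customary units
# (mm^-3 densities, mL/100mL/min perfusion, mmHg partial pressures).

# Pa per mmHg
.PA_PER_MMHG <- 133.322

# conductance pi r^4 / (8 mu L) with r, L in um and mu in mPa.s, converted to
# um^3 / (s mmHg): factor = 1e3 (mPa.s -> Pa.s) * 133.322 (mmHg -> Pa)
.COND_UM3_S_MMHG <- 1e3 * .PA_PER_MMHG

# perfusion [mL/100mL/min] = Q[um^3/s] / V[um^3] * 6000
.PERFUSION_FACTOR <- 6000

.UM_PER_CM <- 1e4
.UM3_PER_CM3 <- 1e12
.UM3_PER_MM3 <- 1e9
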