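# Default model configuration: embryonic forebrain VZ/SVZ growth, control
# genotype. All durations are hours; embryonic time is decimal days
# (E13.5 -> 13.5); volumes are abstract model units with the carrying
# capacity V_max = 4 calibrated so the control combined VZ/SVZ volume at
# E14.5 is 4 units and the mutant's is 1 (the measured 4-fold ratio).

phases:
  t_G1P: 3.1     # G1 before a Type I (symmetric proliferative) division
  t_G1R: 9.3     # G1 before a Type II (asymmetric self-renewing) division
  t_G1D: 13.0    # G1 before a Type III (terminal differentiating) division
  t_S: 4.0
  t_G2: 1.6
  t_M: 0.5       # Type I transit = 3.1 + 4.0 + 1.6 + 0.5 = 9.2 h

fate:
  V_max: 4.0     # VZ carrying capacity; p = 1 - V_VZ / V_max
  K: 5           # divisions available before terminal differentiation

# Omit this block (or set rates to 0) for the "clean" no-apoptosis model.
apoptosis:
  delta_RG: 0.0  # per-hour entry rate into apoptosis, each RG phase
  delta_IP: 0.0
  t_clear: 2.0   # mean residence of apoptotic cells before clearance (h)

aux:
  t_IP_cycle: 14.0        # intermediate-progenitor single-pass cycle (h)
  t_migrate: 24.0         # newborn-neuron VZ/SVZ residence before migration (h)
  unit_cell_volume: 1000  # um^3 per cell, reporting-layer conversion

run:
  t_start: 13.5
  t_end: 17.5
  initial_volume: 1.0  # radial-glia volume at t_start (recalibrated per genotype)
  initial_age: 0       # all radial glia start with K divisions remaining
  erlang_m: 1          # sub-stages per phase; 1 = exponential stage times

genotype_modifiers:
  ccna2null:
    sg2_elongation: 1.25  # S and G2 lengthened 25% -> Type I transit 10.6 h
    K_delta: 1            # six divisions before terminal differentiation
    apoptosis_scale: 1.0
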