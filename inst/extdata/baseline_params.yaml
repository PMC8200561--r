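# Frozen baseline parameter set (see calibrate_baseline() for provenance).
# Printed inputs: fiber geometry (5 um diameter, 2 x 2 um nodes, 1.1 cm
# branches), NaV1.1/NaV1.6 nodal conductances, receptor agonist
# concentrations and the whole-nerve composition. Everything else was frozen
# by the deterministic baseline calibration anchored on the wild-type
# two-release branched-fiber response (5 spikes at a 15-ms interval, nodal
# action-potential overshoot inside +20..+45 mV).
version: "1.0"
passive:
  ra_ohm_cm: 70
  cm_node_uf_cm2: 1.0
  cm_internode_uf_cm2: 0.005
  g_leak_node_s_cm2: 0.04
  g_leak_internode_s_cm2: 0.0001
  g_leak_terminal_s_cm2: 0.04
  v_rest_mv: -65
geometry:
  fiber_diameter_um: 5
  node_length_um: 2
  node_diameter_um: 2
  internode_length_um: 300
  branch_length_um: 11000
  stem_length_um: 11000
  terminal_length_um: 200
  terminal_diameter_um: 1
  terminal_nseg: 4
adelta_densities:
  NaV1.1: 0.5
  NaV1.6: 0.35
  NaV1.7: 0.22
  NaV1.8: 0.02
  KV1: 0.02
  KV3: 0.25
  KV4: 0.03
  KCa: 0.04
terminal:
  density_scale: 0.5
  nav18_s_cm2: 1.6
  kca_at_nodes: false
receptors:
  gmax_atp_s_cm2: 0.063
  gmax_5ht_s_cm2: 0.0378
  p2x2_fraction_whole_nerve: 0.25
synapse:
  release_distance_um: 8
clearance:
  atp_halflife_ms: 200
  fiveht_halflife_ms: 2000
c_fiber:
  diameter_um: 0.8
  length_um: 5000
  segment_um: 50
  g_leak_s_cm2: 0.004
  densities:
    NaV1.7: 0.12
    NaV1.8: 0.1
    KV1: 0.03
    KCa: 0.02
  nav18_terminal_s_cm2: 1.0
  gmax_atp_s_cm2: 0.06
  gmax_5ht_s_cm2: 0.03
sim:
  dt_ms: 0.0125
  v_init_mv: -65
  slow_gate_init_mv: -80
  threshold_mv: 0
  refractory_ms: 1
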