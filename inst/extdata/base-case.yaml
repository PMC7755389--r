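# Base-case run configuration: reference chamber morphology (lengths in um,
# frequency in Hz) with the test solver profile. Keys map onto the arguments
# of chamber_geometry(), beat_kinematics(), solver_config() and
# track_particles().
geometry:
  d_ost: 7.0
  l_ost: 3.0
  d_col: 2.5
  l_col: 4.8
  d_mv: 0.1
  l_mv: 0.05
  flagella_spacing: 5
  n_choanocytes: 24
  gasket: false
kinematics:
  lambda: 5.0
  a: 1.0
  delta: 1.0
  f: 30
  vane_width: 0.7
solver:
  profile: test
tracers:
  n: 1000
  seed: 1
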