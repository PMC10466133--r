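# Canonical trial scenario: 1,000 demographically identical adults
# (36-year-old women, 70 kg, 170 cm), effect-site target 6 mg/L, one plasma
# measurement every 30 s becoming available 15 s later.
#
# Population values are representative published propofol population-PK
# estimates for the reference adult (volumes in L, clearances in L/min,
# ke0 in 1/min; omegas are log-scale SDs). The covariate equations that map
# demographics to parameters live outside this package: parameters are
# supplied here as data.
population:
  means: {CL: 1.79, V1: 6.28, V2: 25.5, V3: 273.0, Q2: 1.75, Q3: 1.11, ke0: 0.146}
  omegas: {CL: 0.515, V1: 0.781, V2: 0.752, V3: 0.773, Q2: 0.588, Q3: 0.457, ke0: 0.0}
  prop: 0.19
  add: 0.02
cohort:
  size: 1000
  seed: 20260922
  demographics: {age: 36, weight: 70, height: 170, sex: female}
tci:
  mode: effect_site
  target: 6.0
  control_interval: "10 s"
  duration: "15 min"
  max_rate: 200.0
sensor:
  period: "30 s"
  delay: "15 s"
  start: "30 s"
  failure_probability: 0.0
actuator:
  max_rate: 200.0
  min_rate_step: 0.0
  syringe_volume: 500.0
  low_reservoir_fraction: 0.1
arms: [open_loop, closed_loop]
output_grid: "6 s"
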