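# Example pipeline configuration: simulate a 60-d extractive campaign
# and analyse its steady window.
reactor:
  v_aq: 1.2          # L
  v_org: 0.24        # L (20% v/v sunflower-oil overlay)
  hrt: 2             # d
  diameter: 0.105    # m
  feed:
    lactate: 40      # g/L
    acetate: 5       # g/L
  ph_setpoint: 5.0
simulator:
  t_end: 60          # d
  dt_out: 0.5        # d
  noise_sd: 0.02     # CV of measurement noise (0 = clean)
periods:
  - label: adaptation
    t_start: 0
    t_end: 20
  - label: steady
    t_start: 40
    t_end: 60
oil:
  density: 0.902     # kg/L
  f_ca: 0.97         # carboxylic-acid mass fraction of the oil
seed: 1
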