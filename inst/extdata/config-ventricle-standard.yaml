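# Standard-of-care ventricular application: 30 W / 30 s, cylindrical tip,
# CF 10 g, 17 ml/min irrigation, low blood flow.
schema_version: 1
electrode:
  tip_shape: cylindrical
protocol:
  power_W: 30
  duration_s: 30
chamber:
  chamber: ventricle
contact_force_g: 10
cooling:
  blood_velocity_m_s: 0.1
  irrigation_ml_min: 17
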