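# HPSD application at the safest step-B settings (atrial form): 70 W / 8 s,
# spherical tip, CF 5 g, 60 ml/min irrigation, low blood flow.
schema_version: 1
electrode:
  tip_shape: spherical
protocol:
  power_W: 70
  duration_s: 8
chamber:
  chamber: atrium
contact_force_g: 5
cooling:
  blood_velocity_m_s: 0.1
  irrigation_ml_min: 60
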