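# Standard-of-care atrial application: 30 W / 30 s, spherical tip,
# CF 10 g, 17 ml/min irrigation, low blood flow. Unset fields take the
# documented defaults (bundled materials, desk numerics).
schema_version: 1
electrode:
  tip_shape: spherical
protocol:
  power_W: 30
  duration_s: 30
chamber:
  chamber: atrium
contact_force_g: 10
cooling:
  blood_velocity_m_s: 0.1
  irrigation_ml_min: 17
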