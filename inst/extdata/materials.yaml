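# Default material parameter set (schema version 1).
#
# Values are literature stand-ins in the style of the IT'IS tissue property
# database at ~500 kHz (myocardium, blood) and common RF-catheter modeling
# values (platinum-iridium electrode, polyurethane catheter body). They are
# synthetic defaults for the reduced desk-scale model, not measurements, and
# every entry can be overridden from a run configuration.
#
# Units: rho kg/m^3, c_ref J/(kg K), k_ref W/(m K), sigma_ref S/m,
# T_ref degrees C, c_slope J/(kg K) per degree C, k_frac_slope and
# sigma_frac_slope 1/degree C.
schema_version: 1
tissue:
  name: myocardium
  rho: 1081
  c_ref: 3686
  k_ref: 0.56
  sigma_ref: 0.54
  T_ref: 37
  c_slope: -0.42        # absolute decrease of specific heat per degree C
  k_frac_slope: -5.0e-4 # -0.05 % per degree C
  sigma_frac_slope: 1.5e-3 # +0.15 % per degree C
blood:
  name: blood
  rho: 1050
  c_ref: 3617
  k_ref: 0.52
  sigma_ref: 0.70
  T_ref: 37
  c_slope: 0
  k_frac_slope: 0
  sigma_frac_slope: 0
electrode_metal:
  name: platinum-iridium
  rho: 21500
  c_ref: 132
  k_ref: 71
  sigma_ref: 4.0e+6
  T_ref: 37
  c_slope: 0
  k_frac_slope: 0
  sigma_frac_slope: 0
catheter_body:
  name: polyurethane
  rho: 1440
  c_ref: 1670
  k_ref: 0.026
  sigma_ref: 1.0e-5
  T_ref: 37
  c_slope: 0
  k_frac_slope: 0
  sigma_frac_slope: 0
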