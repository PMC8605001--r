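# Bundled skin / blood / laser parameter preset.
#
# Tissue and blood rows are the homogeneous single-layer skin values the
# package is validated with; temperatures are given in degrees C and stored
# internally in kelvin.  The optical fit constants O1, O2, e1, e2 are the
# diffuse-reflectance (Rd = 0.05) evaluation of the Gardner-Jacques-Welch
# double-exponential fluence fit (identical to gardner_fit(0.05)); absorption,
# scattering and anisotropy are not independently tabulated for this source
# and were fixed once against the single-pulse validation temperatures (see
# the methods vignette).
tissue:
  density: 1000.0            # kg/m3
  specific_heat: 4187.0      # J/(kg K)
  conductivity: 0.628        # W/(m K)
  youngs_modulus: 1.0e+08    # Pa
  poisson: 0.4
  thermal_expansion: 1.0e-04 # 1/K
  damping: 0.0               # kg/(m3 s); no published value
  relaxation_time: 3.0       # s
  reference_temperature_C: 37.0
blood:
  density: 1060.0            # kg/m3
  specific_heat: 3860.0      # J/(kg K)
  perfusion_rate: 1.87e-03   # 1/s
optics:
  intensity: 3.0e+05         # W/m2
  absorption: 18.0           # 1/m
  scattering: 8000.0         # 1/m
  anisotropy: 0.9
  diffuse_reflectance: 0.05
  O1: 2.638448759
  O2: 1.263420072
  e1: 0.8452913336
  e2: 1.932046908
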