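# Example sensor registry (USER-SUPPLIED PLACEHOLDER VALUES).
#
# The package ships no literature constants: dissociation constants and Hill
# coefficients of published indicators vary between reports and calibration
# conditions, so supply the values appropriate to your constructs here. The
# numbers below are round placeholders that merely illustrate the intended
# regimes: an activity indicator (GECI) with sub-micromolar Kd, and death
# indicators (GEDIs) with Kd near organellar/extracellular Ca2+ levels.
sensors:
  geci_example:
    kd: 3.0e-7        # molar; physiological cytosolic transients
    hill_n: 2.5
    f_min: 0.0
    f_max: 1.0
  gedi_red_example:
    kd: 5.0e-4        # molar; responds only to catastrophic Ca2+ entry
    hill_n: 1.8
    f_min: 0.0
    f_max: 1.0
  gedi_er_example:
    kd: 1.5e-4        # molar; intermediate-affinity death indicator
    hill_n: 1.6
    f_min: 0.0
    f_max: 1.0
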