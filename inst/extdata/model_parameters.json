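{
  "control": {
    "V_tot": 2350,
    "k_on": 8.96e-09,
    "K_D": 0.407,
    "n": 7.38,
    "k1_max": 1.99e-02,
    "k_minus1": 4.70e-01,
    "k_20": 2.37e-02,
    "k_2cat": 3.95e+01,
    "k_minus20": 2.10e-02,
    "K_D_cat": 138,
    "k_3": 4.4,
    "k_minus3": 56,
    "k_4": 1450
  },
  "unc13b_ko": {
    "V_tot": 2350,
    "k_on": 2.25e-08,
    "K_D": 0.407,
    "n": 7.38,
    "k1_max": 6.89e-03,
    "k_minus1": 4.70e-01,
    "k_20": 2.95e-02,
    "k_2cat": 4.91e+01,
    "k_minus20": 2.10e-02,
    "K_D_cat": 138,
    "k_3": 4.4,
    "k_minus3": 56,
    "k_4": 1450
  },
  "munc13_1_oe": {
    "V_tot": 2350,
    "k_on": 2.25e-08,
    "K_D": 0.407,
    "n": 7.38,
    "k1_max": 7.44e-02,
    "k_minus1": 4.70e-01,
    "k_20": 1.29e-02,
    "k_2cat": 2.14e+01,
    "k_minus20": 2.10e-02,
    "K_D_cat": 138,
    "k_3": 4.4,
    "k_minus3": 56,
    "k_4": 1450
  },
  "ubmunc13_2_oe": {
    "V_tot": 2350,
    "k_on": 8.96e-09,
    "K_D": 0.407,
    "n": 7.38,
    "k1_max": 3.42e-01,
    "k_minus1": 4.70e-01,
    "k_20": 5.80e-03,
    "k_2cat": 9.65e+00,
    "k_minus20": 2.10e-02,
    "K_D_cat": 138,
    "k_3": 4.4,
    "k_minus3": 56,
    "k_4": 1450
  }
}
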