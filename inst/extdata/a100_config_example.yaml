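# Example A100 activation-index configuration.
#
# The 0 / 55 state thresholds are the published cut points (below 0
# inactive, 0-55 intermediate, above 55 active). The five distance pairs
# follow the interhelical contacts commonly used to score class A GPCR
# activation; the coefficients below are ILLUSTRATIVE SYNTHETIC values for
# demonstration and testing only -- substitute the published coefficient
# set of the A100 index before scoring real receptors.
distance_pairs:
  - ["3.50", "6.34"]
  - ["3.50", "7.53"]
  - ["3.40", "6.48"]
  - ["5.51", "6.44"]
  - ["2.50", "7.49"]
coefficients: [9.0, -5.0, -3.0, 4.0, -2.0]
intercept: -40.0
thresholds: [0, 55]
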