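# Example Ballesteros-Weinstein map: generic helix.position codes to
# (chain, residue number) of a concrete structure. Residue numbers below
# are those of the packaged "toy_receptor" fixture, not a real receptor.
receptor: toy_receptor
entries:
  "1.50": {chain: A, res_num: 101}
  "2.50": {chain: A, res_num: 102}
  "3.39": {chain: A, res_num: 103}
  "3.40": {chain: A, res_num: 104}
  "3.43": {chain: A, res_num: 105}
  "3.50": {chain: A, res_num: 106}
  "5.51": {chain: A, res_num: 107}
  "6.30": {chain: A, res_num: 108}
  "6.34": {chain: A, res_num: 109}
  "6.40": {chain: A, res_num: 110}
  "6.41": {chain: A, res_num: 111}
  "6.44": {chain: A, res_num: 112}
  "6.48": {chain: A, res_num: 113}
  "7.49": {chain: A, res_num: 114}
  "7.50": {chain: A, res_num: 115}
  "7.51": {chain: A, res_num: 116}
  "7.52": {chain: A, res_num: 117}
  "7.53": {chain: A, res_num: 118}
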