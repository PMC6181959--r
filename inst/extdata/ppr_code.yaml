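# Canonical P-class PPR code: specificity residue pair (position 5, position
# 35) -> preferred RNA base(s). primary = perfect match, secondary = partial.
# Residue pairs not listed are governed by default_policy.
pairs:
  "T,N": {primary: [A]}
  "T,D": {primary: [G]}
  "N,D": {primary: [U]}
  "N,N": {primary: [C], secondary: [U]}
  "S,N": {primary: [A]}
  "S,D": {primary: [G]}
default_policy: partial-all
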