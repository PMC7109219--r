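# Modified ICE (International Collaborative Effort) infant cause-of-death
# groups.  This is a documented approximation of the CPSS-style grouping used
# in Canadian perinatal surveillance; the exact published code boundaries are
# not public, so the list is shipped as replaceable reference data.  Prefixes
# must be pairwise disjoint across groups; any valid ICD-10 code not matching
# a prefix falls into the fallback group.
groups:
  - label: immaturity
    prefixes: [P05, P07, P22, P26, P27, P28, P77]
  - label: congenital
    prefixes: [Q]
  - label: asphyxia
    prefixes: [P03, P10, P15, P20, P21, P24]
  - label: infection
    prefixes: [A, B, J, P23, P35, P36, P37, P38, P39]
  - label: sids
    prefixes: [R95]
  - label: external
    prefixes: [V, W, X, Y]
fallback: other
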