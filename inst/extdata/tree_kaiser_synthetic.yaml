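name: kaiser-synthetic-reconstruction
version: "1.0"
# SYNTHETIC reconstruction of the Kaiser flowchart. The published flowchart
# (Dietzel & Baltzer) is not redistributed here; this tree is constrained to
# reproduce four published worked examples:
#   - no root sign, irregular margin, persistent enhancement -> 3
#   - no root sign, irregular margin, plateau enhancement    -> 5
#   - root sign present, no edema                            -> 7
#   - non-mass, persistent enhancement (inhomogeneous)       -> 6
# It is total and deterministic but is NOT the published decision rule.
paths:
  - {root_sign: yes, curve_type: "*", margin: "*", internal_enhancement: "*", edema: yes, score: 11}
  - {root_sign: yes, curve_type: "*", margin: "*", internal_enhancement: "*", edema: no, score: 7}
  - {root_sign: no, curve_type: washout, margin: not_circumscribed, internal_enhancement: "*", edema: yes, score: 10}
  - {root_sign: no, curve_type: washout, margin: not_circumscribed, internal_enhancement: "*", edema: no, score: 9}
  - {root_sign: no, curve_type: washout, margin: circumscribed, internal_enhancement: inhomogeneous, edema: "*", score: 8}
  - {root_sign: no, curve_type: washout, margin: circumscribed, internal_enhancement: homogeneous, edema: "*", score: 6}
  - {root_sign: no, curve_type: plateau, margin: not_circumscribed, internal_enhancement: "*", edema: "*", score: 5}
  - {root_sign: no, curve_type: plateau, margin: circumscribed, internal_enhancement: inhomogeneous, edema: "*", score: 4}
  - {root_sign: no, curve_type: plateau, margin: circumscribed, internal_enhancement: homogeneous, edema: "*", score: 2}
  - {root_sign: no, curve_type: persistent, margin: not_circumscribed, internal_enhancement: inhomogeneous, edema: "*", score: 6}
  - {root_sign: no, curve_type: persistent, margin: not_circumscribed, internal_enhancement: homogeneous, edema: "*", score: 3}
  - {root_sign: no, curve_type: persistent, margin: circumscribed, internal_enhancement: "*", edema: "*", score: 1}
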