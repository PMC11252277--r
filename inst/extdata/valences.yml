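# Default Pantle-Buck saprobic valence table.
#
# Numeric valences follow the conventional scale (oligosaprobic = 1 ...
# polysaprobic = 4), with two-zone transitional codes at the midpoint of
# their zones. Two rarer transitional codes, p-i and p-m, are read here as
# poly-leaning forms at 3.5; this is an assumption of this table, marked
# below, and can be overridden by supplying a different file to
# default_valence_table().
code_to_S:
  o: 1.0
  o-b: 1.5
  b: 2.0
  b-a: 2.5
  a-b: 2.5
  a: 3.0
  a-p: 3.5
  p-a: 3.5
  p: 4.0
  o-a: 2.0
  p-i: 3.5   # assumption: poly-leaning transitional form
  p-m: 3.5   # assumption: poly-to-meso transitional form
class_bands:
  - lower: 1.0
    upper: 1.5
    level: Oligosaprobic
    degree: Non-polluted
    class: I
  - lower: 1.5
    upper: 1.8
    level: Oligosaprobic to b-Mesosaprobic
    degree: Waters without organic load
    class: I-II
  - lower: 1.8
    upper: 2.3
    level: b-Mesosaprobic
    degree: Waters with a moderate organic load
    class: II
  - lower: 2.3
    upper: 2.7
    level: b-Mesosaprobic to a-Mesosaprobic
    degree: Waters with critical organic load
    class: II-III
  - lower: 2.7
    upper: 3.2
    level: a-Mesosaprobic
    degree: Waters strongly polluted
    class: III
  - lower: 3.2
    upper: 3.5
    level: a-Mesosaprobic to polysaprobic
    degree: Waters are very strongly polluted
    class: III-IV
  - lower: 3.5
    upper: 4.0
    level: Polysaprobic
    degree: Waters exceptionally polluted
    class: IV
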