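# Default controlled vocabulary for Cochlospermum-style surveys:
# 10 use categories, 9 exploited organs, affection (ailment) groups.
categories:
  - medicinal
  - food
  - handicraft
  - construction
  - fodder
  - dye
  - magic
  - fuel
  - veterinary
  - cosmetic
organs:
  - rootstock
  - root bark
  - leaf
  - stem
  - stem bark
  - fruit
  - fiber
  - flower
  - seed
affections:
  - dermatology
  - eye
  - gynecology/andrology
  - general health
  - gastrointestinal
  - infectious
  - liver
  - neurological
  - respiratory
  - skeleto-muscular
  - urological
  - unspecific
  - vascular/blood
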