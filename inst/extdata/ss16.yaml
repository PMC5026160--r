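# 16-item odor identification panel. The SS-8 subset composition is the
# published screening set; the remaining odors are the standard inventory
# and are editable without code changes.
name: SS-16
odors:
  - orange
  - leather
  - cinnamon
  - mint
  - banana
  - lemon
  - licorice
  - turpentine
  - garlic
  - coffee
  - apple
  - clove
  - pineapple
  - rose
  - anise
  - fish
subsets:
  SS-8:
    - licorice
    - anise
    - mint
    - cinnamon
    - banana
    - pineapple
    - rose
    - coffee
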