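# 12-item screening variant; odors are a subset of the SS-16 inventory so
# that SS-12 subscores can be derived from SS-16 response data.
name: SS-12
odors:
  - orange
  - leather
  - cinnamon
  - mint
  - banana
  - lemon
  - licorice
  - coffee
  - clove
  - pineapple
  - rose
  - fish
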