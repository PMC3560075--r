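# Species tree for the SSTR study taxa. Branch lengths are approximate
# divergence-time spans (million years); named internal nodes provide
# the relative-dating bounds. WGD markers: the two basal vertebrate
# tetraploidizations (2R-a, 2R-b) on the vertebrate stem and the
# teleost-specific tetraploidization (3R) on the teleost stem.
newick: "(fruit_fly:700,((coelacanth:420,(frog:360,((anole:280,chicken:280)reptilia:40,(opossum:180,(dog:160,(human:90,mouse:90)euarchontoglires:70)eutheria:20)mammalia:140)amniota:40)tetrapoda:60)coelacanth_tetrapod_split:10,(gar:350,(zebrafish:250,(stickleback:150,(medaka:120,(green_puffer:85,fugu:85)tetraodontidae:35)smegmamorpha:30)percomorpha:100)teleost_crown:100)gar_teleost_split:80)sarcopterygian_actinopterygian_split:270)protostome_deuterostome_split;"
wgd:
  - label: 2R-a
    branch: sarcopterygian_actinopterygian_split
    position: 0.4
  - label: 2R-b
    branch: sarcopterygian_actinopterygian_split
    position: 0.5
  - label: 3R
    branch: teleost_crown
    position: 0.5
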