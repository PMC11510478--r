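# Example residue-group configuration for grouped hydrogen-bond counting:
# the two charged clusters named in the construct's concave-surface
# annotation, defined per monomer (chains A and B). Further clusters are
# user-supplied in the same "chain:resno:resname" format.
groups:
  group1_A: ["A:19:ARG", "A:23:LYS"]
  group1_B: ["B:19:ARG", "B:23:LYS"]
  group2_A: ["A:47:LYS", "A:48:ARG", "A:132:LYS"]
  group2_B: ["B:47:LYS", "B:48:ARG", "B:132:LYS"]
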