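# Subsystem weights implied by the published per-system weight blocks
# (sums of the combined indicator weights within each subsystem). The
# original pairwise judgment matrices were not published, so the weights
# are entered directly; a 'pairwise' matrix may be given instead.
vegetation:
  direct_weights:
    tree: 0.6739
    herb: 0.2255
    litter: 0.1007
soil:
  direct_weights:
    basic: 0.2000
    nutrient: 0.8001
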