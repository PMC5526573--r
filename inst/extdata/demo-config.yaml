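# Demo pipeline: regenerate the four degenerate consensus primers used for
# family I.5 lipase prospecting from their conserved-motif anchors.
seed: 1
out_dir: lipoprospect-demo
verbose: 0
stages:
  primers:
    motifs:
      FWintLipGBCdeg: SSNWDRACE
      BWintLipGBCdeg: YDFKLDQW
      FWintLipGdeg: GWGREEM
      BWintLipGdeg: NDGIVNT
    direction: [forward, reverse, forward, reverse]
    out: primers.tsv
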