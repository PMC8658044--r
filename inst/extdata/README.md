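# Packaged data files

- `fig2_transcription.graphs` — hand transcription of the published worked
  transformation example: `G1`, a 4-node path labelled `[1]-[6]-[5]-[7]`
  (single bonds), and `G2`, the graph reached by the six printed edit
  operations. A transcription, not a machine-readable export.
- `garcia_single_costs.csv` — the four single-cost optimisation results
  reported per benchmark dataset by the earlier one-cost-at-a-time method
  (insert/delete `[6]`, substitute `[5]`/`[6]`, insert/delete `-`,
  substitute `-`/`=`). Shipped as reported, for reference only; not
  exercised by any test.
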