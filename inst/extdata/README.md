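# extdata

Small plain-text fixtures from a published cardio-renal (CVD vs. CKD)
microarray meta-analysis case study:

- `cardiorenal_shared_up.txt` — the 19 genes reported up-regulated in
  both conditions.
- `cardiorenal_shared_down.txt` — the 24 genes reported down-regulated
  in both conditions.
- `cardiorenal_modules.tsv` — the 10 seed-carrying interaction-network
  modules of that study (node/edge counts and the seed genes each
  retained).  Member lists beyond the seed genes were not published, so
  only the counts and seed genes are recorded here.

These drive the worked examples in the test-suite; all other test data
are generated programmatically by the `gen_deg_series()` / `gen_ppin()`
synthetic generators.
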