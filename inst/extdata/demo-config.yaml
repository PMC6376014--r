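# Demo pipeline configuration: one treatment-spot-scale run of the 200 MeV
# beam with a reduced iteration count; completes in well under a minute.
beam:
  label: 200MeV
run:
  n_primaries: 2.0e7
  rate_based: yes
  calib_primaries: 1.0e8
recon:
  iterations: 1000
analysis:
  reps: 3
root_seed: 1
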