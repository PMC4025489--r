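# Full-scale sampling-design grid: 4 x-levels x 6 y-levels x 4 z-levels
# (96 cells) at 30 replicates. The package defaults use the symmetric
# desk-scale subset; this config reproduces the complete design.
grid:
  x: [10, 30, 50, 100]
  y: [10, 30, 100, 200, 400, 700]
  z: [10, 30, 50, 100]
  replicates: 30
correction:
  mode: resample
  prior: uniform
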