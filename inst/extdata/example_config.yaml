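# Example run configuration for dhmwound::run_pipeline() / the CLI
# `analyze` subcommand. A two-condition wound assay: left side untreated
# control, right side EGF-stimulated, indices from suspended-cell fits.
optics:
  wavelength_nm: 532
  n_medium: 1.339
  alpha_m3_per_kg: 2.0e-4
  pixel_pitch_um: 0.5
segmentation:
  threshold: auto
geometry:
  axis: x
  gap_start_um: 100
  gap_end_um: 600
conditions:
  - name: control
    region: left
    n_cell: 1.3713
    dm_single_pg: 265
  - name: egf
    region: right
    n_cell: 1.3707
    dm_single_pg: 542
input: assay.tif
input_type: phase
frame_interval_min: 30
output_dir: results
seed: 1
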