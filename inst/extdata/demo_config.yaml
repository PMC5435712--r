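# Demo pipeline configuration: every artifact is regenerable from this
# file plus a seed (see ?read_pipeline_config for the recognized keys).
seed: 1
out_dir: wssmetrics_out
baseline_wss: 20        # Pa, steady WSS scale of the planted fields
amp_ratio_sd: 0.6       # animal-to-animal SD of the inner amplitude ratio
thresholds:
  tawss_low: 20         # Pa
  osi_high: 0.2
  rrt_high: 0.5         # 1/Pa
fluid:
  density: 1060         # kg/m^3
  viscosity: 0.0035     # Pa.s
arch:
  centerline_radius: 3  # mm
  vessel_radius: 1      # mm
  n_theta: 40
  n_phi: 96
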