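# Example run configuration: small pancreatic-tail-like phantom with a
# splenic-vein organ at risk. Units: mm, W, s, W/(m^2 K).
phantom:
  mode: voxel3d
  domain_size: [30, 30, 30]
  voxel_spacing: 1.25
  margin_thickness: 4
  probe_lateral_mm: 7
  tumor:
    semi_axes: [5, 5, 5]
  vessels:
    - name: splenic_vein
      p0: [25.5, 0, 15]
      p1: [25.5, 30, 15]
      radius: 2
      h: 750
laser:
  power: 5
solver:
  dt: 2
  t_end: 300
damage:
  T_d: 60
  t_n: 1
dose:
  powers: [2, 5, 8]
  durations: [100, 200, 300]
  ablation_threshold: 55
  oar_limit: 42
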