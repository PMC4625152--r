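# end-to-end demo: nanoparticle-labeled mouse phantom, pitch-8 grid
shape: [160, 160]
scatter_coupling: 0.05
grid:
  pitch_px: 8
  duty: 0.05
  open_transmission: 0.98
  wire_transmission: 0.10
  orientation_deg: 0
geometry:
  source_detector_m: 1.6
  sample_position_m: 0.8
acquisition:
  fluence: 20000
  seed: 7
  noise: true
regions:
  - name: body
    center: [80, 80]
    axes: [70, 70]
    optical_depth: 0.3
    gold_ugcm3: 2
  - name: liver
    center: [60, 60]
    axes: [20, 14]
    optical_depth: 0.2
    gold_ugcm3: 10
  - name: tumor_1
    center: [110, 100]
    axes: [10, 10]
    optical_depth: 0.05
    gold_ugcm3: 26
rois:
  - name: tumor_roi
    center: [110, 100]
    axes: [7, 7]
    role: target
  - name: control_roi
    center: [110, 52]
    axes: [7, 7]
    role: control
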