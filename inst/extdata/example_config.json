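{
  "phantom": { "preset": "pelvis", "grid_shape": 256, "spacing": 0.15 },
  "geometry": {
    "sad": 100, "sdd": 150,
    "n_cols": 400, "pitch": 0.225,
    "lateral_offset": 0,
    "n_angles": 360
  },
  "protocol": {
    "N0": 1e10,
    "allocation": "sqrt",
    "attenuation_mode": "central",
    "bowtie": null,
    "seed": 1
  },
  "recon": { "filter": "ramlak", "weighting": null },
  "metrics": {
    "rois": [
      { "name": "soft-tissue", "shape": "ellipse", "center": [128.5, 128.5], "extents": [18, 18] }
    ],
    "profiles": [ { "axis": "row", "index": 128 } ]
  },
  "dose": { "view_stride": 8, "downsample": 4 },
  "out_dir": null
}
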