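# Synthetic multi-dataset bundle study manifest (fixture; declares the full
# ten-confound contrast design over five subjects)
subjects: [sub01, sub02, sub03, sub04, sub05]
pathways: [ARC, STR]
datasets: [ref, rescan, scan1, scan2, ven1, ven2, res1, res2, dir1, dir2, bval]
reference_dataset: ref
dwi: false
templates:
  bundle: "{subject}/{dataset}/{pathway}.trk"
  grid: "{subject}/{dataset}/grid.nii.gz"
  dwi: "{subject}/{dataset}/dwi.nii.gz"
  bval: "{subject}/{dataset}/dwi.bval"
  bvec: "{subject}/{dataset}/dwi.bvec"
contrasts:
  - {confound: RESCAN, a: ref, b: rescan}
  - {confound: SCAN1, a: ref, b: scan1}
  - {confound: SCAN2, a: ref, b: scan2}
  - {confound: VEN1, a: ref, b: ven1}
  - {confound: VEN2, a: ref, b: ven2}
  - {confound: RES1, a: ref, b: res1}
  - {confound: RES2, a: ref, b: res2}
  - {confound: DIR1, a: ref, b: dir1}
  - {confound: DIR2, a: ref, b: dir2}
  - {confound: BVAL, a: ref, b: bval}
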