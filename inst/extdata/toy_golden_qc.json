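{
 "segment_qc_removed": {
  "T1_R1_carcinoma": "aligned_pct",
  "T2_R1_TME": "raw_reads"
 },
 "loq": {
  "T1_R1_TME": 4.0,
  "T1_R2_carcinoma": 4.0,
  "T1_R2_TME": 4.0,
  "T2_R1_carcinoma": 4.0,
  "T2_R2_carcinoma": 4.0,
  "T2_R2_TME": 4.0
 },
 "detection_removed_segments": [
  "T2_R2_carcinoma"
 ],
 "removed_genes": [
  "GLOW"
 ],
 "surviving_segments": [
  "T1_R1_TME",
  "T1_R2_carcinoma",
  "T1_R2_TME",
  "T2_R1_carcinoma",
  "T2_R2_TME"
 ],
 "surviving_genes": [
  "G1",
  "G2",
  "G3",
  "G4",
  "G5",
  "G6",
  "G7",
  "G8",
  "G9"
 ]
}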