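# Classifier parameters for benchmarking an annotated proteome FASTA.
# Flat key:value format read by read_classifier_config(). These are the
# package defaults; tune them per proteome when comparing the surface
# subset against published counts, since the heuristic's spans and
# thresholds are not standardized across studies.
sp_scan_len: 45
h_window: 8
h_thresh: 1.5
sp_cleave_min: 15
sp_cleave_max: 45
lipobox_c_min: 15
lipobox_c_max: 40
lpxtg_c_window: 50
tm_window: 15
tail_len: 10
tail_min_kr: 2
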