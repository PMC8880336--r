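# The 36-combination resolution sweep takes a couple of minutes; compute it
# once per test run and share it between the battery property tests and the
# acceptance suite.
.pv_cache <- new.env(parent = emptyenv())

pv_sweep <- function() {
  if (is.null(.pv_cache$res)) {
    .pv_cache$res <- partial_volume_battery(2:10, battery_config(seed = 1),
                                            verbose = FALSE)
  }
  .pv_cache$res
}

pv_per_nroi <- function() {
  dplyr::summarise(dplyr::group_by(pv_sweep(), n_roi),
                   med = median(median_diff_pct),
                   rms = median(rms), .groups = "drop")
}
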