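# shared fixtures built in code

wt_params <- function() reference_wt_params()

# small noiseless ensemble with known truth, for exact-recovery tests
noiseless_ensemble <- function(n = 5, seed = 11) {
  spec <- ensemble_spec(n_variants = n, noise_sd_log = 0, trace_noise_sd = 0,
                        seed = seed)
  simulate_ensemble(spec)
}

fast_ctrl <- function(n_starts = 2L) chevron_control(n_starts = n_starts)

# footnote-excluded variants of the packaged reference table
footnote_excluded <- c("L102A", "A105G", "T108S", "T127S", "V137A", "T168S",
                       "T191S", "T205S", "L206A", "L210A")
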