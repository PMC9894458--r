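# Shared fixtures: everything is generated in code at test time.

FLAT_SHIFT <- stats::setNames(rep(0, 9), STAGES)
FLAT_GAIN <- stats::setNames(rep(1, 9), STAGES)

# Reduced-epoch CNN config for fast test runs.
quick_cfg <- function(n_classes, seed = 1L, epochs = 20L, patience = 6L) {
  cnn_config(n_classes, max_epochs = epochs, patience = patience,
             seed = seed)
}

# Short synthetic leg (default 8 s per stage); short-duration warnings are
# expected and silenced.
tiny_leg <- function(duration_s = 8, seed = 1L, ...) {
  suppressWarnings(
    generate_leg(synthetic_leg_config(duration_s = duration_s, seed = seed,
                                      ...)))
}

# A leg with no stage effect at all: zero shift, flat gain, no slow
# frequency drift (within-leg CV would otherwise learn each stage's
# idiosyncratic drift realization), broadband noise kept.
null_leg <- function(duration_s = 8, seed = 1L) {
  tiny_leg(duration_s = duration_s, seed = seed,
           stage_peak_shift = FLAT_SHIFT, stage_gain = FLAT_GAIN,
           drift_sd = 0)
}

# The stand-in for the one publicly shipped leg (synthetic: the real
# recordings are not deposited). 60 s per stage keeps runtimes inside the
# test budget; segment counts stay large (299 per stage).
s1_standin_leg <- function() {
  suppressWarnings(generate_leg(
    synthetic_leg_config(pig_id = "S1", leg = "L", duration_s = 60,
                         seed = 101L)))
}

# Write a leg as a wide stage-table CSV in a temp file.
write_tmp_stage_csv <- function(leg) {
  p <- tempfile(fileext = ".csv")
  write_stage_table(leg, p)
  p
}
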