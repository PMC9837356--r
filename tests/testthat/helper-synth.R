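# Shared synthetic objects, built once per test run.  The cache avoids
# re-generating the (deterministic) input function and noiseless TACs in
# every file.

.synth_cache <- new.env(parent = emptyenv())

synth_fixture <- function() {
  if (is.null(.synth_cache$inp)) {
    .synth_cache$inp <- synth_input(t_max_min = 90)
    .synth_cache$sched <- make_frame_schedule("mmr_90")
    .synth_cache$truth <- feppa_truth()
    rates <- attr(.synth_cache$truth, "rates")
    .synth_cache$tacs <- lapply(names(rates), function(r)
      model_tac(rates[[r]], .synth_cache$inp, .synth_cache$sched, region = r))
    names(.synth_cache$tacs) <- names(rates)
  }
  .synth_cache
}

frontal_rates <- function() rate_constants(0.235, 0.100, 0.2390, 0.0470)

# quick options for tests that only need a working fit, not the full
# multi-start protocol
fast_options <- function() sime_options(n_starts = 2)

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(max(abs(object / expected - 1)), tol)
}
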