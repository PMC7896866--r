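# Shared fixtures: the default synthetic calibration campaign and a model
# fitted on it, built once per test run.
fx_campaign <- simulate_calibration_campaign(seed = 1)
fx_model <- fit_calibration(fx_campaign$scansets, fx_campaign$records,
                            split_plan(1))

# Small deterministic spectrum for unit tests.
toy_spectrum <- function(n = 10L, start = 1800, step = 4) {
  spectrum(seq(start, by = -step, length.out = n), seq_len(n) / n)
}
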