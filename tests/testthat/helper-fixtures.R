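# Shared fixtures, all generated in code (no stored data).

# a clean two-species analysis window: on-bin sinusoids with a known phase
# delay, ready for window_spectrum()
make_sine_window <- function(f = 1.25, fs = 100, dur = 4, dtheta = 0.1,
                             a1 = 0.009, a2 = 0.001) {
  t <- seq(0, by = 1 / fs, length.out = dur * fs)
  list(times = t,
       n_hbo2 = a1 * sin(2 * pi * f * t),
       n_hb = a2 * sin(2 * pi * f * t - dtheta),
       sample_rate = fs)
}

default_sim <- function(seed = 1, duration_s = 30, ...) {
  simulation_params(duration_s = duration_s, noise_sd = 0, quant_bits = 0,
                    hr_variation = 0, drift_amplitude = 0, seed = seed, ...)
}

# memoised 90-min sessions shared between the end-to-end tests so the
# expensive processing runs once per test session
.session_cache <- new.env(parent = emptyenv())

cached_session <- function(key, builder) {
  if (is.null(.session_cache[[key]])) .session_cache[[key]] <- builder()
  .session_cache[[key]]
}

challenge_session_results <- function() {
  cached_session("challenge", function() {
    cfg <- pipeline_config()
    sess <- simulate_session(simulation_params(duration_s = 5400, seed = 1))
    est <- process_ppg(sess$record, cfg)
    trend <- postprocess_mi(est, cfg)
    list(sess = sess, est = est, trend = trend, cfg = cfg)
  })
}

flat_session_results <- function() {
  cached_session("flat", function() {
    cfg <- pipeline_config()
    sess <- simulate_session(simulation_params(duration_s = 5400, seed = 1),
                             glucose_profile = function(t) rep(95, length(t)))
    est <- process_ppg(sess$record, cfg)
    trend <- postprocess_mi(est, cfg)
    list(sess = sess, est = est, trend = trend, cfg = cfg)
  })
}
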