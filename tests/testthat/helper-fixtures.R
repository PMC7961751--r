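# Small programmatic fixtures shared across tests.

# a flat recording with all four channels at constant values
flat_recording <- function(duration_s = 60, rate_hz = 10, hr = 70, br = 15,
                           sc = 5, st = 33, subject_id = "s1",
                           session_id = "sess1") {
  n <- round(duration_s * rate_hz)
  new_recording(
    tibble::tibble(
      time_s = (seq_len(n) - 1) / rate_hz,
      hr_bpm = rep(hr, n), br_bcpm = rep(br, n),
      sc_us = rep(sc, n), st_c = rep(st, n)
    ),
    subject_id = subject_id, session_id = session_id, rate_hz = rate_hz
  )
}

concentration_events <- function(times) {
  tibble::tibble(time_s = times, state = "concentration", source = "expert")
}

# random, valid HMM parameters for oracle comparisons
random_hmm_params <- function(k, d) {
  init <- runif(k) + 0.1
  init <- init / sum(init)
  trans <- matrix(runif(k * k) + 0.1, k, k)
  trans <- trans / rowSums(trans)
  hmm_params(init, trans,
             means = matrix(rnorm(k * d, sd = 2), k, d),
             variances = matrix(runif(k * d, 0.2, 2), k, d))
}

# small fitted-ready sequence sets drawn from two shifted regimes
toy_sequences <- function(n = 6, d = 2, t = 30, shift = 4, seed = 1) {
  withr::with_seed(seed, lapply(seq_len(n), function(i) {
    states <- rep(c(0, 1), each = ceiling(t / 2))[seq_len(t)]
    matrix(rnorm(d * t), d, t) + matrix(states * shift, d, t, byrow = TRUE)
  }))
}
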