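test_that("single-state likelihood equals the Gaussian closed form", {
  m <- hmm_params(1, matrix(1, 1, 1), means = matrix(c(0, 2), 1, 2),
                  variances = matrix(c(1, 0.5), 1, 2))
  x <- matrix(c(0.3, 1.9, -0.5, 2.2, 0.1, 2.0), 2, 3)
  expected <- sum(dnorm(x[1, ], 0, 1, log = TRUE)) +
    sum(dnorm(x[2, ], 2, sqrt(0.5), log = TRUE))
  expect_equal(hmm_loglik(m, x), expected, tolerance = 1e-12)
})

test_that("forward algorithm matches brute-force path enumeration", {
  withr::with_seed(41, {
    for (case in 1:40) {
      k <- sample(1:3, 1)
      d <- sample(1:3, 1)
      tt <- sample(1:5, 1)
      m <- random_hmm_params(k, d)
      x <- matrix(rnorm(d * tt, sd = 2), d, tt)
      expect_equal(
        hmm_loglik(m, x),
        brute_force_loglik(m$initial, m$transition, m$means, m$variances, x),
        tolerance = 1e-8
      )
    }
  })
})

test_that("likelihood is invariant under state relabelling", {
  withr::with_seed(42, {
    m <- random_hmm_params(3, 2)
    x <- matrix(rnorm(2 * 10), 2, 10)
    perm <- c(3, 1, 2)
    mp <- hmm_params(m$initial[perm], m$transition[perm, perm],
                     m$means[perm, ], m$variances[perm, ])
    expect_equal(hmm_loglik(m, x), hmm_loglik(mp, x), tolerance = 1e-10)
  })
})

test_that("scaled forward stays finite where raw probabilities underflow", {
  m <- hmm_params(c(0.5, 0.5), matrix(0.5, 2, 2),
                  means = matrix(c(0, 50, 0, 50, 0, 50, 0, 50), 2, 4),
                  variances = matrix(1e-4, 2, 4))
  x <- matrix(rnorm(4 * 60, mean = 25), 4, 60)   # far from both states
  ll <- hmm_loglik(m, x)
  expect_true(is.finite(ll))
  expect_lt(ll, -1e5)                            # astronomically unlikely data
})

test_that("identical sequences receive identical scores", {
  m <- random_hmm_params(2, 2)
  x <- matrix(rnorm(2 * 60), 2, 60)
  expect_identical(hmm_loglik(m, x), hmm_loglik(m, x + 0))
})

test_that("a one-state fit reduces to pooled per-channel moments", {
  seqs <- toy_sequences(n = 4, d = 2, t = 20, shift = 0, seed = 3)
  fit <- hmm_fit(seqs, n_states = 1, seed = 1, standardise = FALSE)
  pooled <- do.call(cbind, seqs)
  expect_equal(as.numeric(fit$means), rowMeans(pooled), tolerance = 1e-6)
  n <- ncol(pooled)
  expect_equal(as.numeric(fit$variances),
               apply(pooled, 1, function(r) mean((r - mean(r))^2)),
               tolerance = 1e-6)
})

test_that("constant training data collapses to floored variances", {
  seqs <- lapply(1:3, function(i) matrix(7, 2, 15))
  fit <- hmm_fit(seqs, n_states = 2, seed = 1, standardise = FALSE)
  expect_true(all(abs(fit$means - 7) < 1e-8))
  expect_true(all(fit$variances == 1e-6))
})

test_that("EM log-likelihood trace is non-decreasing", {
  seqs <- toy_sequences(n = 8, d = 3, t = 40, shift = 3, seed = 9)
  fit <- hmm_fit(seqs, n_states = 3, seed = 2)
  expect_true(all(diff(fit$fit$loglik_trace) >= -1e-8))
})

test_that("fit recovers the parameters of a well-separated 2-state model", {
  truth <- hmm_params(
    c(0.6, 0.4), rbind(c(0.9, 0.1), c(0.15, 0.85)),
    means = rbind(c(0, 1), c(5, -4)),
    variances = rbind(c(0.25, 0.25), c(0.25, 0.25))
  )
  seqs <- lapply(1:60, function(i) hmm_sample(truth, 60, seed = 100 + i))
  fit <- hmm_fit(seqs, n_states = 2, seed = 5, standardise = FALSE)
  perm <- if (fit$means[1, 1] < fit$means[2, 1]) 1:2 else 2:1
  expect_lt(max(abs(fit$means[perm, ] - truth$means)), 0.1)
  expect_lt(max(abs(fit$transition[perm, perm] - truth$transition)), 0.05)
})

test_that("insufficient or inconsistent training data errors out", {
  expect_error(hmm_fit(list(matrix(0, 2, 10)), n_states = 2),
               "at least 2")
  expect_error(hmm_fit(list(matrix(0, 2, 10), matrix(0, 3, 10))),
               "same number of channels")
  expect_error(hmm_loglik(random_hmm_params(2, 2), matrix(0, 3, 5)),
               "channels")
})

test_that("sampling is seeded and matches the transition law in the long run", {
  m <- hmm_params(c(0.5, 0.5), rbind(c(0.8, 0.2), c(0.3, 0.7)),
                  means = rbind(0, 10), variances = rbind(1, 1))
  a <- hmm_sample(m, 60, seed = 7)
  b <- hmm_sample(m, 60, seed = 7)
  expect_identical(a, b)

  long <- hmm_sample(m, 10000, seed = 8)
  states <- ifelse(long[1, ] > 5, 2, 1)        # states separated by 10 sd
  emp <- prop.table(table(factor(head(states, -1), 1:2),
                          factor(tail(states, -1), 1:2)), margin = 1)
  expect_lt(max(abs(emp - m$transition)), 0.02)
})

test_that("near-zero emission variance pins samples to the state mean", {
  m <- hmm_params(1, matrix(1, 1, 1), means = matrix(3, 1, 1),
                  variances = matrix(1e-12, 1, 1))
  x <- hmm_sample(m, 50, seed = 1)
  expect_lt(max(abs(x - 3)), 1e-4)
})

test_that("parameters survive a JSON round trip including scaling", {
  seqs <- toy_sequences(n = 5, d = 2, t = 30, shift = 2, seed = 13)
  fit <- hmm_fit(seqs, n_states = 2, seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  hmm_write_json(fit, path)
  back <- hmm_read_json(path)
  # agreement to 17 significant digits (at most one ulp)
  tol <- 1e-15
  expect_equal(back$initial, fit$initial, tolerance = tol)
  expect_equal(unname(back$transition), unname(fit$transition),
               tolerance = tol)
  expect_equal(unname(back$means), unname(fit$means), tolerance = tol)
  expect_equal(unname(back$variances), unname(fit$variances),
               tolerance = tol)
  x <- seqs[[1]]
  expect_equal(hmm_loglik(back, x), hmm_loglik(fit, x), tolerance = 1e-12)
})

test_that("tidy and glance summarise a fitted model", {
  seqs <- toy_sequences(seed = 17)
  fit <- hmm_fit(seqs, n_states = 2, seed = 1,
                 channels = c("HR", "ST"))
  td <- tidy(fit)
  expect_equal(nrow(td), 4)                    # 2 states x 2 channels
  expect_named(td, c("state", "channel", "mean", "variance", "initial"))
  gl <- glance(fit)
  expect_equal(gl$n_states, 2)
  expect_true(is.finite(gl$loglik))
})
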