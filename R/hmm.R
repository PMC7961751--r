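#' Construct hidden Markov model parameters
#'
#' The model has `K` hidden states with per-state diagonal Gaussian
#' emissions over `D` channels: an initial distribution, a row-stochastic
#' transition matrix, and per-state/per-channel means and variances. This
#' constructor validates the simplex/stochasticity constraints; fitted
#' models come from [hmm_fit()].
#'
#' @param initial Probability vector of length `K`.
#' @param transition `K x K` row-stochastic matrix.
#' @param means,variances `K x D` matrices (variances positive).
#' @param channels Optional channel codes of length `D`.
#' @param scaling Optional per-channel standardisation (list with `center`
#'   and `scale`) applied to sequences before likelihood evaluation.
#' @return A `conc_hmm` object.
#' @export
hmm_params <- function(initial, transition, means, variances,
                       channels = NULL, scaling = NULL) {
  means <- rbind(means)
  variances <- rbind(variances)
  transition <- as.matrix(transition)
  k <- length(initial)
  if (abs(sum(initial) - 1) > 1e-10) abort("`initial` must sum to 1.")
  if (any(initial < 0)) abort("`initial` must be non-negative.")
  if (!all(dim(transition) == c(k, k))) abort("`transition` must be K x K.")
  if (any(abs(rowSums(transition) - 1) > 1e-10)) {
    abort("`transition` rows must sum to 1.")
  }
  if (any(transition < 0)) abort("`transition` must be non-negative.")
  if (nrow(means) != k || !all(dim(means) == dim(variances))) {
    abort("`means` and `variances` must both be K x D.")
  }
  if (any(variances <= 0)) abort("`variances` must be positive.")
  if (is.null(channels)) channels <- paste0("ch", seq_len(ncol(means)))
  structure(
    list(n_states = k, channels = channels,
         initial = as.numeric(initial), transition = transition,
         means = means, variances = variances, scaling = scaling,
         fit = NULL),
    class = "conc_hmm"
  )
}

#' @export
print.conc_hmm <- function(x, ...) {
  cat(sprintf("<hmm> %d states, %d channels (%s)\n", x$n_states,
              length(x$channels), paste(x$channels, collapse = ", ")))
  if (!is.null(x$fit)) {
    cat(sprintf("  fitted: loglik %.4f after %d EM iterations (%s)\n",
                tail(x$fit$loglik_trace, 1), x$fit$n_iterations,
                if (x$fit$converged) "converged" else "max_iter reached"))
  }
  invisible(x)
}

# run expr under a seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, expr) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  })
  set.seed(seed)
  expr
}

# K x N matrix of per-frame emission log-densities for concatenated frames
emission_logdens <- function(x, means, variances) {
  k <- nrow(means)
  sds <- sqrt(variances)
  out <- matrix(0, k, ncol(x))
  for (j in seq_len(k)) {
    out[j, ] <- colSums(dnorm(x, mean = means[j, ], sd = sds[j, ], log = TRUE))
  }
  out
}

apply_scaling <- function(x, scaling) {
  if (is.null(scaling)) return(x)
  (x - scaling$center) / scaling$scale
}

check_sequences <- function(sequences) {
  if (!is.list(sequences) || length(sequences) == 0) {
    abort("`sequences` must be a nonempty list of D x T matrices.")
  }
  sequences <- lapply(sequences, rbind)
  d <- nrow(sequences[[1]])
  if (!all(vapply(sequences, nrow, integer(1)) == d)) {
    abort("All sequences must share the same number of channels.")
  }
  sequences
}

#' Fit a Gaussian-emission HMM by Baum-Welch
#'
#' Expectation-maximisation on all training sequences jointly. States are
#' initialised at evenly spaced quantiles of the pooled frames (perturbed by
#' seeded noise) with uniform initial and transition probabilities; the
#' E-step runs the scaled forward-backward recursions; iteration stops when
#' the total log-likelihood gain falls below `tol` or after `max_iter`
#' iterations. Emission variances are floored at `var_floor`.
#'
#' By default each channel is standardised (z-scored) with statistics pooled
#' over the training frames; the same constants are applied to any sequence
#' later scored with [hmm_loglik()], so channels on very different physical
#' scales (BPM vs microsiemens) contribute comparably.
#'
#' @param sequences List of `D x T` numeric matrices (at least two).
#' @param n_states Number of hidden states `K` (default 3).
#' @param seed Integer seed controlling initialisation.
#' @param max_iter,tol EM stopping rule (defaults 100, 1e-4).
#' @param var_floor Variance floor on the standardised scale (default 1e-6).
#' @param standardise Z-score channels with training statistics
#'   (default TRUE).
#' @param n_restarts Number of seeded EM restarts; the best final
#'   log-likelihood wins (default 1).
#' @param channels Optional channel codes.
#' @return A fitted `conc_hmm`; its `$fit` element holds the
#'   log-likelihood trace, iteration count and convergence flag.
#' @export
hmm_fit <- function(sequences, n_states = 3, seed = 1, max_iter = 100,
                    tol = 1e-4, var_floor = 1e-6, standardise = TRUE,
                    n_restarts = 1, channels = NULL) {
  sequences <- check_sequences(sequences)
  if (length(sequences) < 2) {
    abort("Insufficient data: at least 2 training sequences are required.")
  }
  if (any(vapply(sequences, ncol, integer(1)) < n_states)) {
    abort("Every sequence must have at least `n_states` frames.")
  }
  lengths <- vapply(sequences, ncol, integer(1))
  x <- do.call(cbind, sequences)           # D x N concatenated frames
  d <- nrow(x)

  scaling <- NULL
  if (standardise) {
    center <- rowMeans(x)
    scale <- apply(x, 1, sd)
    scale[!is.finite(scale) | scale < 1e-12] <- 1
    scaling <- list(center = center, scale = scale)
    x <- (x - center) / scale
  }

  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- hmm_em_once(x, lengths, n_states, seed + 1009L * (r - 1L),
                       max_iter, tol, var_floor)
    if (is.null(best) ||
        tail(fit$loglik_trace, 1) > tail(best$loglik_trace, 1)) {
      best <- fit
    }
  }

  out <- hmm_params(best$initial, best$transition, best$means,
                    best$variances, channels = channels, scaling = scaling)
  out$fit <- list(loglik_trace = best$loglik_trace,
                  n_iterations = best$n_iterations,
                  converged = best$converged, seed = seed)
  out
}

hmm_em_once <- function(x, lengths, k, seed, max_iter, tol, var_floor) {
  d <- nrow(x)
  init_par <- with_seed(seed, {
    probs <- seq_len(k) / (k + 1)
    q <- apply(x, 1, quantile, probs = probs, names = FALSE)  # k x d (k>1)
    q <- matrix(q, nrow = k, ncol = d)
    pooled_sd <- apply(x, 1, sd)
    pooled_sd[pooled_sd < 1e-8] <- 1e-8
    means <- q + matrix(rnorm(k * d, sd = 0.1), k, d) *
      matrix(pooled_sd, k, d, byrow = TRUE)
    list(means = means,
         variances = matrix(pmax(pooled_sd^2, var_floor), k, d, byrow = TRUE))
  })
  means <- init_par$means
  variances <- init_par$variances
  initial <- rep(1 / k, k)
  transition <- matrix(1 / k, k, k)

  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    logdens <- emission_logdens(x, means, variances)
    es <- forward_backward_cpp(logdens, initial, transition,
                               as.integer(lengths))
    trace <- c(trace, es$loglik)
    if (it > 1 && es$loglik - trace[it - 1] < tol) {
      converged <- TRUE
      break
    }
    g <- es$gamma                                    # k x N
    counts <- rowSums(g)
    initial <- es$init_sum / length(lengths)
    initial <- initial / sum(initial)
    if (k > 1) {
      transition <- es$xi_sum / rowSums(es$xi_sum)
    }
    means <- (g %*% t(x)) / counts
    variances <- (g %*% t(x^2)) / counts - means^2
    variances <- pmax(variances, var_floor)
  }
  list(initial = initial, transition = transition, means = means,
       variances = variances, loglik_trace = trace,
       n_iterations = length(trace), converged = converged)
}

#' Sequence log-likelihood under an HMM
#'
#' Computes `log p(X | theta)` by the forward algorithm with per-step
#' scaling, which stays finite for the 60-frame windows even where the
#' unscaled forward probabilities would underflow. If the model carries
#' training standardisation constants they are applied to the sequence
#' first, so scores of fitted models are directly comparable across test
#' samples.
#'
#' @param object A `conc_hmm`.
#' @param sequence `D x T` numeric matrix.
#' @return The log-likelihood (a single finite number).
#' @export
hmm_loglik <- function(object, sequence) {
  sequence <- rbind(sequence)
  if (nrow(sequence) != ncol(object$means)) {
    abort(sprintf("Sequence has %d channels but the model expects %d.",
                  nrow(sequence), ncol(object$means)))
  }
  if (ncol(sequence) < 1) abort("Sequence must have at least one frame.")
  z <- apply_scaling(sequence, object$scaling)
  logdens <- emission_logdens(z, object$means, object$variances)
  forward_loglik_cpp(logdens, object$initial, object$transition)
}

#' Draw a sequence from an HMM
#'
#' Samples a hidden state path from the initial/transition distributions and
#' Gaussian emissions per frame; if the model carries standardisation
#' constants the output is mapped back to the original signal scale.
#'
#' @param object A `conc_hmm`.
#' @param length Number of frames `T`.
#' @param seed Integer seed.
#' @return A `D x T` matrix.
#' @export
hmm_sample <- function(object, length, seed = 1) {
  k <- object$n_states
  d <- ncol(object$means)
  with_seed(seed, {
    states <- integer(length)
    states[1] <- sample.int(k, 1, prob = object$initial)
    if (length > 1) {
      for (t in 2:length) {
        states[t] <- sample.int(k, 1, prob = object$transition[states[t - 1], ])
      }
    }
    z <- t(object$means[states, , drop = FALSE]) +
      matrix(rnorm(d * length), d, length) *
        t(sqrt(object$variances[states, , drop = FALSE]))
    if (!is.null(object$scaling)) {
      z <- z * object$scaling$scale + object$scaling$center
    }
    z
  })
}

#' @export
tidy.conc_hmm <- function(x, ...) {
  k <- x$n_states
  tibble::tibble(
    state = rep(seq_len(k), each = length(x$channels)),
    channel = rep(x$channels, times = k),
    mean = as.vector(t(x$means)),
    variance = as.vector(t(x$variances)),
    initial = rep(x$initial, each = length(x$channels))
  )
}

#' @export
glance.conc_hmm <- function(x, ...) {
  tibble::tibble(
    n_states = x$n_states,
    n_channels = length(x$channels),
    loglik = if (is.null(x$fit)) NA_real_ else tail(x$fit$loglik_trace, 1),
    n_iterations = if (is.null(x$fit)) NA_integer_ else x$fit$n_iterations,
    converged = if (is.null(x$fit)) NA else x$fit$converged
  )
}

#' Serialise HMM parameters to JSON
#'
#' Round-trips all parameters (and any standardisation constants) through a
#' flat JSON document at 17 significant digits, which is exact for doubles.
#'
#' @param object A `conc_hmm`.
#' @param path Output path.
#' @return `path` (write) / a `conc_hmm` (read).
#' @export
hmm_write_json <- function(object, path) {
  doc <- list(
    n_states = object$n_states,
    channels = object$channels,
    initial = object$initial,
    transition = object$transition,
    means = object$means,
    variances = object$variances,
    scaling_center = object$scaling$center,
    scaling_scale = object$scaling$scale
  )
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = FALSE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname hmm_write_json
#' @export
hmm_read_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  scaling <- NULL
  if (!is.null(doc$scaling_center)) {
    scaling <- list(center = as.numeric(doc$scaling_center),
                    scale = as.numeric(doc$scaling_scale))
  }
  hmm_params(doc$initial, doc$transition, doc$means, doc$variances,
             channels = doc$channels, scaling = scaling)
}
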