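#' Semi-Markov process (SMP) parameters for one participant
#'
#' Bundles the seven free parameters of the SMP account of free-association
#' generation and regulation:
#'
#' * `beta` — tempering of the typicality-based generation distribution.
#'   Association probabilities are proportional to `pTP^exp(beta)`, so
#'   `beta < 0` flattens the distribution (less-constrained associative maps)
#'   and `beta > 0` sharpens it.
#' * `alpha_i` — regulation threshold in `[0, 1]`: the min–max-transformed
#'   typicality at which the accept/reject stage is indifferent.
#' * `alpha_sign` — direction of regulation, `+1` (atypical associations are
#'   preferentially rejected) or `-1` (typical ones are).
#' * `s_mu` — log-slope linking an association's surprisal
#'   (`-log P(A_i | c)`) to its mean generation time in seconds.
#' * `lambda` — ratio of the standard deviation to the mean of the gamma
#'   generation-time distribution (constant coefficient of variation).
#' * `tau0` — minimum non-decision time, seconds.
#' * `tau_r` — range of the uniform non-decision time, seconds.
#'
#' @param beta Real scalar.
#' @param alpha_i Real scalar in `[0, 1]`.
#' @param alpha_sign `+1` or `-1`.
#' @param s_mu Real scalar.
#' @param lambda Positive real scalar.
#' @param tau0 Nonnegative real scalar, seconds.
#' @param tau_r Positive real scalar, seconds.
#'
#' @return An object of class `smp_parameters` (a named list of the seven
#'   values).
#' @examples
#' smp_parameters(beta = 0, alpha_i = 0.5, alpha_sign = 1,
#'                s_mu = 0, lambda = 0.5, tau0 = 0.3, tau_r = 0.5)
#' @export
smp_parameters <- function(beta, alpha_i, alpha_sign, s_mu, lambda,
                           tau0, tau_r) {
  p <- list(beta = as.numeric(beta), alpha_i = as.numeric(alpha_i),
            alpha_sign = as.numeric(alpha_sign), s_mu = as.numeric(s_mu),
            lambda = as.numeric(lambda), tau0 = as.numeric(tau0),
            tau_r = as.numeric(tau_r))
  validate_smp_parameters(p)
  structure(p, class = "smp_parameters")
}

validate_smp_parameters <- function(p) {
  stopifnot(length(p) == 7L)
  if (!all(vapply(p, function(x) is.numeric(x) && length(x) == 1L &&
                    is.finite(x), logical(1)))) {
    stop("all SMP parameters must be finite numeric scalars", call. = FALSE)
  }
  if (!p$alpha_sign %in% c(-1, 1)) {
    stop("`alpha_sign` must be -1 or +1", call. = FALSE)
  }
  if (p$alpha_i < 0 || p$alpha_i > 1) {
    stop("`alpha_i` must lie in [0, 1]", call. = FALSE)
  }
  if (p$lambda <= 0) stop("`lambda` must be > 0", call. = FALSE)
  if (p$tau_r <= 0) stop("`tau_r` must be > 0", call. = FALSE)
  if (p$tau0 < 0) stop("`tau0` must be >= 0", call. = FALSE)
  invisible(p)
}

#' @export
print.smp_parameters <- function(x, ...) {
  cat("<smp_parameters>\n")
  cat(sprintf("  beta = %.4g, alpha_i = %.4g, alpha_sign = %+d\n",
              x$beta, x$alpha_i, as.integer(x$alpha_sign)))
  cat(sprintf("  s_mu = %.4g, lambda = %.4g, tau0 = %.4g s, tau_r = %.4g s\n",
              x$s_mu, x$lambda, x$tau0, x$tau_r))
  invisible(x)
}

#' Canonical parameter names of the SMP model
#'
#' @return Character vector of the seven parameter names in canonical order.
#' @export
smp_parameter_names <- function() {
  c("beta", "alpha_i", "alpha_sign", "s_mu", "lambda", "tau0", "tau_r")
}

#' Serialize / deserialize SMP parameters as JSON
#'
#' Parameters are written with the seven canonical names so that parameter
#' sets round-trip losslessly between R sessions and other tools.
#'
#' @param params An [smp_parameters()] object.
#' @param path File path.
#' @return `write_smp_parameters()` returns `path` invisibly;
#'   `read_smp_parameters()` returns an [smp_parameters()] object.
#' @export
write_smp_parameters <- function(params, path) {
  validate_smp_parameters(params)
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_smp_parameters
#' @export
read_smp_parameters <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(smp_parameters, x[smp_parameter_names()])
}

#' Tempered generation distribution over a cue's candidate associations
#'
#' The probability that candidate association `i` is generated in response to
#' a cue is its typicality raised to `exp(beta)`, renormalized:
#' `P(A_i) = pTP_i^exp(beta) / sum_j pTP_j^exp(beta)`. `beta -> -Inf` gives a
#' uniform distribution over candidates; large `beta` concentrates mass on
#' the most typical association.
#'
#' @param typicality Numeric vector of candidate typicalities, all `> 0`
#'   (names, if present, are preserved). A one-cue norms tibble (with columns
#'   `lemma` and `typicality`) is also accepted.
#' @param beta Tempering parameter (real scalar).
#' @return Numeric probability vector over the candidate set, summing to 1.
#' @examples
#' generation_distribution(c(sky = 0.6, sea = 0.3, ink = 0.1), beta = log(2))
#' @export
generation_distribution <- function(typicality, beta) {
  typicality <- as_typicality_vector(typicality)
  if (length(typicality) == 0L) {
    stop("candidate set is empty", call. = FALSE)
  }
  if (any(typicality <= 0)) {
    stop("all typicalities must be > 0", call. = FALSE)
  }
  # work on the log scale: pTP^exp(beta) under/overflows for extreme beta
  lw <- exp(beta) * log(typicality)
  lw <- lw - max(lw)
  w <- exp(lw)
  w / sum(w)
}

as_typicality_vector <- function(typicality) {
  if (is.data.frame(typicality)) {
    stopifnot(all(c("lemma", "typicality") %in% names(typicality)))
    stats::setNames(typicality$typicality, typicality$lemma)
  } else {
    typicality
  }
}

#' Min–max transformation
#'
#' Rescales a vector to `[0, 1]` as `(x - min) / (max - min)`. The regulated
#' acceptance stage applies this to a cue's typicalities so that rejection
#' probabilities are insensitive to cue entropy. A degenerate all-equal
#' vector maps every element to 0.5 (the least-informative value, keeping
#' acceptance defined).
#'
#' @param x Nonempty numeric vector.
#' @return Numeric vector in `[0, 1]` of the same length.
#' @examples
#' minmax_transform(c(0.6, 0.3, 0.1))
#' @export
minmax_transform <- function(x) {
  stopifnot(length(x) >= 1L, is.numeric(x))
  rng <- range(x)
  if (rng[1] == rng[2]) {
    return(rep(0.5, length(x)))
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Acceptance probability of a generated association
#'
#' After an association is generated it is either accepted and reported or
#' rejected (and generation restarts). Acceptance follows a logistic in the
#' min–max-transformed typicality with a fixed slope of 10 (the slope is a
#' model constant, not a free parameter):
#' with `alpha_sign = +1`, `P(accept) = logistic(10 * (MX(pTP)_i - alpha_i))`;
#' with `alpha_sign = -1` the transform is applied to `1 - pTP`, which by the
#' affine identity `MX(1 - pTP)_i = 1 - MX(pTP)_i` mirrors the direction.
#'
#' @inheritParams generation_distribution
#' @param alpha_i Regulation threshold in `[0, 1]`.
#' @param alpha_sign Direction of regulation, `+1` or `-1`.
#' @param index Optional integer (or vector of) candidate index; if omitted,
#'   acceptance probabilities for the whole candidate set are returned.
#' @return Numeric vector of acceptance probabilities in `(0, 1)`.
#' @examples
#' acceptance_probability(c(0.6, 0.3, 0.1), alpha_i = 0.5, alpha_sign = 1)
#' @export
acceptance_probability <- function(typicality, alpha_i, alpha_sign,
                                   index = NULL) {
  typicality <- as_typicality_vector(typicality)
  stopifnot(alpha_sign %in% c(-1, 1))
  mx <- minmax_transform(typicality)
  if (alpha_sign < 0) mx <- minmax_transform(1 - typicality)
  p <- stats::plogis(SMP_ACCEPTANCE_SLOPE * (mx - alpha_i))
  if (!is.null(index)) {
    stopifnot(all(index >= 1L), all(index <= length(p)))
    p <- p[index]
  }
  p
}

# Fixed logistic slope of the acceptance stage; a model constant (a variant
# with a free slope is not recoverable).
SMP_ACCEPTANCE_SLOPE <- 10

#' Gamma generation-time specification per candidate association
#'
#' The time to generate candidate `i` is gamma distributed with mean
#' `mu_i = exp(s_mu) * (-log P(A_i))` (mean time grows with surprisal, so
#' weaker associations are slower) and standard deviation
#' `sigma_i = lambda * mu_i`. Moment matching gives a constant gamma shape
#' `1 / lambda^2` and scale `lambda^2 * mu_i`. A candidate with probability 1
#' (single-association cue) has `mu = 0`: a point mass at time zero.
#'
#' @param prob Numeric probability vector (a [generation_distribution()]).
#' @param s_mu Log-slope of the surprisal-to-mean-time link.
#' @param lambda Positive sd/mean ratio.
#' @return A tibble with one row per candidate and columns `prob`, `mu`,
#'   `sigma`, `gamma_shape`, `gamma_scale` (times in seconds).
#' @export
generation_time_spec <- function(prob, s_mu, lambda) {
  stopifnot(is.numeric(prob), length(prob) >= 1L, lambda > 0,
            abs(sum(prob) - 1) < 1e-8)
  mu <- exp(s_mu) * (-log(prob))
  tibble::tibble(
    prob = as.numeric(prob),
    mu = mu,
    sigma = lambda * mu,
    gamma_shape = ifelse(mu > 0, 1 / lambda^2, NA_real_),
    gamma_scale = ifelse(mu > 0, lambda^2 * mu, 0)
  )
}

#' Simulate one free-association trial under the SMP
#'
#' Runs the generative process forward: candidates are sampled with
#' replacement from the tempered generation distribution, each sampled
#' candidate incurs a gamma-distributed generation time, and is accepted with
#' its regulated acceptance probability; sampling restarts (memorylessly) on
#' rejection. The reaction time is the sum of all generation times plus a
#' uniform non-decision time on `[tau0, tau0 + tau_r]`.
#'
#' @param typicality Candidate typicalities (named vector or one-cue norms
#'   tibble), all `> 0`.
#' @param params An [smp_parameters()] object.
#' @param max_draws Candidate cap: the trial aborts with a divergence error
#'   if no candidate is accepted after this many draws.
#' @param no_rejection If `TRUE`, simulate the no-rejection model variant
#'   (acceptance probability identically 1).
#' @return A list with elements `reported` (lemma, or index if `typicality`
#'   is unnamed), `rt` (seconds) and `n_rejected`.
#' @examples
#' set.seed(1)
#' simulate_trial(c(sky = 0.6, sea = 0.3, ink = 0.1),
#'                smp_parameters(0, 0.5, 1, 0, 0.5, 0.3, 0.5))
#' @export
simulate_trial <- function(typicality, params, max_draws = 10000L,
                           no_rejection = FALSE) {
  out <- simulate_trials(typicality, params, n = 1L, max_draws = max_draws,
                         no_rejection = no_rejection)
  list(reported = out$reported[1], rt = out$rt[1],
       n_rejected = out$n_rejected[1])
}

#' Simulate many independent trials for one cue and parameter set
#'
#' Vectorized companion to [simulate_trial()]; used for Monte-Carlo oracles
#' and for dataset simulation.
#'
#' @inheritParams simulate_trial
#' @param n Number of independent trials.
#' @return A tibble with columns `reported`, `rt` (seconds), `n_rejected`.
#' @export
simulate_trials <- function(typicality, params, n, max_draws = 10000L,
                            no_rejection = FALSE) {
  typicality <- as_typicality_vector(typicality)
  validate_smp_parameters(params)
  prob <- generation_distribution(typicality, params$beta)
  acc <- if (no_rejection) rep(1, length(prob)) else
    acceptance_probability(typicality, params$alpha_i, params$alpha_sign)
  if (all(acc <= 1e-6)) {
    stop("SMP divergence: all acceptance probabilities <= 1e-6",
         call. = FALSE)
  }
  spec <- generation_time_spec(prob, params$s_mu, params$lambda)
  k <- length(prob)
  reported <- integer(n)
  gen_time <- numeric(n)
  n_rejected <- integer(n)
  pending <- seq_len(n)
  draws <- 0L
  while (length(pending) > 0L) {
    draws <- draws + 1L
    if (draws > max_draws) {
      stop("SMP divergence: no acceptance within ", max_draws,
           " candidate draws", call. = FALSE)
    }
    m <- length(pending)
    i <- sample.int(k, m, replace = TRUE, prob = prob)
    t_i <- ifelse(spec$mu[i] > 0,
                  stats::rgamma(m, shape = 1 / params$lambda^2,
                                scale = spec$gamma_scale[i]),
                  0)
    gen_time[pending] <- gen_time[pending] + t_i
    accepted <- stats::runif(m) < acc[i]
    reported[pending[accepted]] <- i[accepted]
    n_rejected[pending[!accepted]] <- n_rejected[pending[!accepted]] + 1L
    pending <- pending[!accepted]
  }
  rt <- gen_time + stats::runif(n, params$tau0, params$tau0 + params$tau_r)
  rep_out <- if (!is.null(names(typicality))) names(typicality)[reported]
             else reported
  tibble::tibble(reported = rep_out, rt = rt, n_rejected = n_rejected)
}

#' Joint density of a reported association and its reaction time
#'
#' Evaluates the SMP's joint probability density of observing a given
#' reported association together with a reaction time `rt`. The trial-level
#' process is a semi-Markov chain: a geometric number of rejected candidates
#' (each drawn from the tempered generation distribution and carrying a gamma
#' generation time) precedes the accepted one, and the total generation time
#' is convolved with the uniform non-decision window
#' `[tau0, tau0 + tau_r]`. In transform space the candidate-path density is
#' `L_j(s) = P(A_j) acc_j G_j(s) / (1 - sum_i P(A_i)(1 - acc_i) G_i(s))`
#' with `G_i` the gamma-time transform.
#'
#' Numerically, the geometric rejection count is truncated at `K` where its
#' tail falls below `1e-8`; the `K`-term convolution series is accumulated on
#' a uniform grid (gamma components discretised by cell masses, i.e. CDF
#' differences, so mass is conserved even for near-degenerate components),
#' and the non-decision window is applied exactly as a difference of the
#' generation-time CDF divided by `tau_r`.
#'
#' @inheritParams simulate_trial
#' @param reported Reported lemma (if `typicality` is named) or candidate
#'   index; a scalar.
#' @param rt Numeric vector of reaction times in seconds; the density is
#'   evaluated at each.
#' @param n_grid Grid resolution for the convolution (cells).
#' @param no_rejection Evaluate the no-rejection variant (acceptance = 1).
#' @return Numeric vector of joint densities, one per `rt` value; `rt`
#'   values at or below `tau0` have density 0.
#' @export
trial_joint_density <- function(typicality, params, reported, rt,
                                n_grid = 4096L, no_rejection = FALSE) {
  typicality <- as_typicality_vector(typicality)
  validate_smp_parameters(params)
  prob <- generation_distribution(typicality, params$beta)
  j <- resolve_candidate(typicality, reported)
  acc <- if (no_rejection) rep(1, length(prob)) else
    acceptance_probability(typicality, params$alpha_i, params$alpha_sign)
  smp_density_grid(prob, acc, j, rt, params, n_grid)
}

resolve_candidate <- function(typicality, reported) {
  if (is.character(reported)) {
    j <- match(reported, names(typicality))
    if (is.na(j)) {
      stop("reported association '", reported,
           "' is not in the candidate set", call. = FALSE)
    }
    j
  } else {
    stopifnot(reported >= 1L, reported <= length(typicality))
    as.integer(reported)
  }
}

# Density core on a mass grid. prob/acc: per-candidate generation and
# acceptance probabilities; j: accepted candidate index; rt: vector, seconds.
smp_density_grid <- function(prob, acc, j, rt, params, n_grid) {
  tau0 <- params$tau0
  tau_r <- params$tau_r
  lambda <- params$lambda
  mu <- exp(params$s_mu) * (-log(prob))
  shape <- 1 / lambda^2
  scl <- lambda^2 * mu
  w_rej <- prob * (1 - acc)
  q <- sum(w_rej)
  w_j <- prob[j] * acc[j]

  u1 <- rt - tau0
  u2 <- rt - tau0 - tau_r
  out <- numeric(length(rt))
  live <- u1 > 0
  if (!any(live)) return(out)

  # degenerate: every reachable generation time is 0 (single-candidate cue)
  if (all(mu < 1e-12)) {
    out[live] <- w_j / (1 - q) *
      ((u1[live] >= 0) - (u2[live] >= 0)) / tau_r
    return(out)
  }

  # grid extent: cover the largest rt and the bulk of the total-time mass
  m_rej <- if (q > 0) sum(w_rej * mu) / q else 0
  v_rej <- if (q > 0) sum(w_rej * ((lambda * mu)^2 + mu^2)) / q - m_rej^2
           else 0
  e_n <- if (q < 1) q / (1 - q) else Inf
  v_n <- if (q < 1) q / (1 - q)^2 else Inf
  m_tot <- e_n * m_rej + mu[j]
  v_tot <- e_n * v_rej + v_n * m_rej^2 + (lambda * mu[j])^2
  t_max <- max(max(u1[live]) * 1.01, m_tot + 10 * sqrt(v_tot), 1e-3)
  n <- as.integer(n_grid)
  dt <- t_max / n
  edges <- seq(0, t_max, length.out = n + 1L)

  cell_mass <- function(sh, sc) {
    if (sc <= 0) return(c(1, rep(0, n - 1L)))  # point mass at 0
    diff(stats::pgamma(edges, shape = sh, scale = sc))
  }
  g_j <- cell_mass(shape, scl[j])
  npad <- 2L * n
  pad <- function(x) c(x, rep(0, npad - n))
  g_hat <- stats::fft(pad(g_j))
  if (q > 1e-12) {
    m_pmf <- numeric(n)
    for (i in seq_along(prob)) {
      if (w_rej[i] > 0) m_pmf <- m_pmf + (w_rej[i] / q) * cell_mass(shape, scl[i])
    }
    # truncate the geometric rejection-count series where its tail < 1e-8;
    # the truncated sum has closed pointwise form in the transform domain
    k_max <- ceiling(log(1e-8 * (1 - q)) / log(q))
    x <- q * stats::fft(pad(m_pmf))
    series <- (1 - x^(k_max + 1)) / (1 - x)
    c_hat <- g_hat * series
  } else {
    c_hat <- g_hat
  }
  total_pmf <- pmax(Re(stats::fft(c_hat, inverse = TRUE)) / npad, 0)
  cdf <- c(0, cumsum(total_pmf))            # CDF at padded-grid cell edges
  cdf_at <- function(u) {
    # linear interpolation on edges of the padded grid [0, 2*t_max]
    pos <- pmin(pmax(u / dt, 0), npad)
    lo <- floor(pos)
    frac <- pos - lo
    cdf[lo + 1L] * (1 - frac) + cdf[pmin(lo + 2L, npad + 1L)] * frac
  }
  out[live] <- w_j * (cdf_at(u1[live]) - cdf_at(pmax(u2[live], 0))) / tau_r
  out
}

#' Marginal probability that each association is the one reported
#'
#' Integrating the joint density over reaction time gives the marginal report
#' probability `P(A_j) acc_j / sum_i P(A_i) acc_i`.
#'
#' @inheritParams trial_joint_density
#' @return Named numeric probability vector over the candidate set.
#' @export
report_probability <- function(typicality, params, no_rejection = FALSE) {
  typicality <- as_typicality_vector(typicality)
  prob <- generation_distribution(typicality, params$beta)
  acc <- if (no_rejection) rep(1, length(prob)) else
    acceptance_probability(typicality, params$alpha_i, params$alpha_sign)
  p <- prob * acc / sum(prob * acc)
  names(p) <- names(typicality)
  p
}
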