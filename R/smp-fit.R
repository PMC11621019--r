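#' Group-level prior for one SMP parameter
#'
#' The hierarchical fitter constrains participant-level parameters with
#' empirical group-level priors, one per parameter. Four families are
#' supported, chosen to respect each parameter's support with two
#' hyperparameters each (one for `bernoulli_pm1`):
#'
#' * `normal(mean, sd)` — unbounded parameters (`beta`, `s_mu`).
#' * `lognormal(meanlog, sdlog)` — positive parameters (`lambda`, `tau0`,
#'   `tau_r`).
#' * `beta(shape1, shape2)` — `alpha_i` on `[0, 1]`.
#' * `bernoulli_pm1(prob_plus)` — `alpha_sign` on `{-1, +1}`.
#'
#' A `normal` or `lognormal` prior with zero spread, or a `bernoulli_pm1`
#' prior with `prob_plus` 0 or 1, is a point mass; point masses pass through
#' the M-step unchanged.
#'
#' @param family One of `"normal"`, `"lognormal"`, `"beta"`,
#'   `"bernoulli_pm1"`.
#' @param ... Family hyperparameters (see above), positional or named.
#' @return An object of class `group_prior`.
#' @examples
#' group_prior("normal", mean = -0.5, sd = 0.75)
#' group_prior("beta", 2, 2)
#' @export
group_prior <- function(family = c("normal", "lognormal", "beta",
                                   "bernoulli_pm1"), ...) {
  family <- match.arg(family)
  hp <- c(...)
  names(hp) <- switch(family,
    normal = c("mean", "sd"),
    lognormal = c("meanlog", "sdlog"),
    beta = c("shape1", "shape2"),
    bernoulli_pm1 = "prob_plus"
  )[seq_along(hp)]
  prior <- structure(list(family = family, hyper = hp),
                     class = "group_prior")
  validate_group_prior(prior)
  prior
}

validate_group_prior <- function(prior) {
  hp <- prior$hyper
  ok <- switch(prior$family,
    normal = length(hp) == 2L && is.finite(hp[["mean"]]) && hp[["sd"]] >= 0,
    lognormal = length(hp) == 2L && is.finite(hp[["meanlog"]]) &&
      hp[["sdlog"]] >= 0,
    beta = length(hp) == 2L && hp[["shape1"]] > 0 && hp[["shape2"]] > 0,
    bernoulli_pm1 = length(hp) == 1L && hp[["prob_plus"]] >= 0 &&
      hp[["prob_plus"]] <= 1
  )
  if (!isTRUE(ok)) {
    stop("improper ", prior$family, " group prior", call. = FALSE)
  }
  invisible(prior)
}

#' @export
print.group_prior <- function(x, ...) {
  cat(sprintf("<group_prior %s(%s)>\n", x$family,
              paste(sprintf("%s = %.4g", names(x$hyper), x$hyper),
                    collapse = ", ")))
  invisible(x)
}

n_hyper <- function(prior) {
  if (prior$family == "bernoulli_pm1") 1L else 2L
}

is_point_mass <- function(prior) {
  switch(prior$family,
    normal = prior$hyper[["sd"]] == 0,
    lognormal = prior$hyper[["sdlog"]] == 0,
    beta = FALSE,
    bernoulli_pm1 = prior$hyper[["prob_plus"]] %in% c(0, 1)
  )
}

sample_group_prior <- function(prior, n) {
  hp <- prior$hyper
  switch(prior$family,
    normal = stats::rnorm(n, hp[["mean"]], hp[["sd"]]),
    lognormal = stats::rlnorm(n, hp[["meanlog"]], hp[["sdlog"]]),
    beta = stats::rbeta(n, hp[["shape1"]], hp[["shape2"]]),
    bernoulli_pm1 = ifelse(stats::runif(n) < hp[["prob_plus"]], 1, -1)
  )
}

# Weighted method-of-moments refit of one family. x: sampled values,
# w: nonnegative weights summing to 1. Point masses pass through unchanged.
refit_group_prior <- function(prior, x, w) {
  if (is_point_mass(prior)) return(prior)
  m <- sum(w * x)
  v <- max(sum(w * (x - m)^2), 0)
  switch(prior$family,
    normal = group_prior("normal", mean = m, sd = max(sqrt(v), 1e-3)),
    lognormal = {
      lx <- log(pmax(x, 1e-12))
      lm <- sum(w * lx)
      lv <- max(sum(w * (lx - lm)^2), 1e-6)
      group_prior("lognormal", meanlog = lm, sdlog = sqrt(lv))
    },
    beta = {
      m <- min(max(m, 1e-3), 1 - 1e-3)
      v <- min(max(v, 1e-6), m * (1 - m) * 0.999)
      nu <- m * (1 - m) / v - 1
      group_prior("beta", shape1 = max(m * nu, 0.02),
                  shape2 = max((1 - m) * nu, 0.02))
    },
    bernoulli_pm1 = {
      p <- sum(w * (x > 0))
      group_prior("bernoulli_pm1", prob_plus = min(max(p, 0.01), 0.99))
    }
  )
}

#' Default (non-informative) group-level priors
#'
#' Starting priors for the hierarchical fit, wide relative to the plausible
#' participant-level range of each parameter: `beta ~ N(0, 1)`,
#' `s_mu ~ N(0, 0.75)`, `alpha_i ~ Beta(1.2, 1.2)`,
#' `alpha_sign ~ Bernoulli_pm1(0.5)`, `lambda ~ LogNormal(log 0.5, 0.5)`,
#' `tau0 ~ LogNormal(log 0.3, 0.7)`, `tau_r ~ LogNormal(log 0.5, 0.7)`.
#'
#' @param trials Optional trial tibble (with `rt_ms`); when supplied, the
#'   `tau0` prior is re-centred below the cohort's minimum reaction time,
#'   because participants vary dramatically in their minimum RT and the
#'   non-decision floor must start below it.
#' @return Named list of [group_prior()] objects, one per SMP parameter.
#' @export
default_group_priors <- function(trials = NULL) {
  tau0_meanlog <- log(0.3)
  if (!is.null(trials) && nrow(trials) > 0) {
    min_rt <- min(trials$rt_ms, na.rm = TRUE) / 1000
    tau0_meanlog <- log(max(min_rt * 0.5, 1e-3))
  }
  list(
    beta = group_prior("normal", mean = 0, sd = 1),
    alpha_i = group_prior("beta", shape1 = 1.2, shape2 = 1.2),
    alpha_sign = group_prior("bernoulli_pm1", prob_plus = 0.5),
    s_mu = group_prior("normal", mean = 0, sd = 0.75),
    lambda = group_prior("lognormal", meanlog = log(0.5), sdlog = 0.5),
    tau0 = group_prior("lognormal", meanlog = tau0_meanlog, sdlog = 0.7),
    tau_r = group_prior("lognormal", meanlog = log(0.5), sdlog = 0.7)
  )
}

validate_group_priors <- function(priors) {
  need <- smp_parameter_names()
  if (!all(need %in% names(priors))) {
    stop("group priors must cover: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  purrr::walk(priors[need], validate_group_prior)
  invisible(priors)
}

#' Draw parameter settings from group-level priors
#'
#' @param priors Named list of [group_prior()] objects covering the seven
#'   SMP parameters.
#' @param n Number of settings.
#' @param variant Model variant: `"full"`, `"no_rejection"` (acceptance
#'   fixed at 1; `alpha_i`, `alpha_sign` are not free) or `"fixed_sign"`
#'   (`alpha_sign` clamped to `fixed_sign`).
#' @param fixed_sign Clamp value for the `fixed_sign` variant.
#' @return Tibble with `n` rows and the seven parameter columns; sampled
#'   values are clamped into each parameter's support.
#' @export
sample_settings <- function(priors, n, variant = "full", fixed_sign = 1) {
  validate_group_priors(priors)
  s <- purrr::map(priors[smp_parameter_names()],
                  function(p) sample_group_prior(p, n))
  s <- tibble::as_tibble(s)
  s$alpha_i <- pmin(pmax(s$alpha_i, 0), 1)
  s$lambda <- pmax(s$lambda, 1e-4)
  s$tau0 <- pmax(s$tau0, 0)
  s$tau_r <- pmax(s$tau_r, 1e-4)
  s$alpha_sign <- ifelse(s$alpha_sign >= 0, 1, -1)
  if (variant == "no_rejection") {
    s$alpha_i <- 0.5
    s$alpha_sign <- 1
  } else if (variant == "fixed_sign") {
    s$alpha_sign <- fixed_sign
  }
  s
}

free_hyper_count <- function(priors, variant) {
  drop <- switch(variant,
    full = character(0),
    no_rejection = c("alpha_i", "alpha_sign"),
    fixed_sign = "alpha_sign"
  )
  keep <- setdiff(smp_parameter_names(), drop)
  sum(vapply(priors[keep], n_hyper, integer(1)))
}

# Precompute per-participant trial structures for the likelihood kernel:
# candidate typicality vectors, reported index (appending unseen responses
# with smoothed typicality 1/(n_respondents + 1)), and RT in seconds.
prepare_likelihood_data <- function(trials, norms) {
  stopifnot(all(c("participant_id", "cue_id", "response", "rt_ms")
                %in% names(trials)))
  if ("valid" %in% names(trials)) trials <- trials[trials$valid %in% TRUE |
                                                     trials$valid %in% 1, ]
  cue_split <- split(norms, norms$cue_id)
  missing_cues <- setdiff(unique(trials$cue_id), names(cue_split))
  if (length(missing_cues) > 0) {
    stop("cue(s) absent from norms: ",
         paste(utils::head(missing_cues, 5), collapse = ", "),
         call. = FALSE)
  }
  by_part <- split(trials, trials$participant_id)
  purrr::map(by_part, function(tt) {
    ptp <- vector("list", nrow(tt))
    idx <- integer(nrow(tt))
    for (i in seq_len(nrow(tt))) {
      nf <- cue_split[[as.character(tt$cue_id[i])]]
      tv <- stats::setNames(nf$typicality, nf$lemma)
      j <- match(tt$response[i], names(tv))
      if (is.na(j)) {
        n_resp <- if ("n_respondents" %in% names(nf)) nf$n_respondents[1]
                  else length(tv)
        tv <- c(tv, stats::setNames(1 / (n_resp + 1), tt$response[i]))
        j <- length(tv)
      }
      ptp[[i]] <- unname(tv)
      idx[i] <- j
    }
    list(ptp = ptp, rep_idx = idx, rt = tt$rt_ms / 1000)
  })
}

#' Per-setting log-likelihood of one participant's trials
#'
#' For each candidate parameter setting, sums the log joint density of the
#' reported association and RT over all of the participant's valid trials.
#' Log densities are floored at -745 so that a single underflowing trial
#' cannot annihilate a setting's importance weight.
#'
#' @param trials Trial tibble for one participant (columns `participant_id`,
#'   `cue_id`, `response`, `rt_ms`, optionally `valid`).
#' @param norms Norms tibble (columns `cue_id`, `lemma`, `typicality`,
#'   optionally `n_respondents`).
#' @param settings Tibble of parameter settings (as from
#'   [sample_settings()]) or a single [smp_parameters()] object.
#' @param variant Model variant (see [sample_settings()]).
#' @return Numeric vector: one log-likelihood per setting (all zero when the
#'   participant has no trials).
#' @export
participant_loglik <- function(trials, norms, settings,
                               variant = "full") {
  if (inherits(settings, "smp_parameters")) {
    settings <- tibble::as_tibble(unclass(settings))
  }
  smat <- as.matrix(settings[, smp_parameter_names()])
  if (nrow(trials) == 0L) return(rep(0, nrow(smat)))
  pd <- prepare_likelihood_data(trials, norms)
  if (length(pd) != 1L) {
    stop("`trials` must contain a single participant", call. = FALSE)
  }
  pd <- pd[[1L]]
  participant_loglik_cpp(pd$ptp, pd$rep_idx, pd$rt, smat,
                         variant == "no_rejection")
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' One iteration of the hierarchical importance-sampling EM
#'
#' For each participant independently, draws `n_settings` random parameter
#' settings from the current group priors and evaluates the joint likelihood
#' of that participant's associations and RTs under each setting. The
#' normalized likelihoods serve as importance weights; each prior family is
#' then refitted by weighted moment matching pooled over participants
#' (participants weighted equally). The iBIC of the incoming priors is
#' computed from the same samples:
#' `-2 * sum_s log( (1/K) sum_k exp(ll_sk) ) + H * log(total trials)`,
#' where `H` counts free group-prior hyperparameters.
#'
#' A participant whose weights all underflow contributes uniform weights
#' (with a warning).
#'
#' @param trials Trial tibble, all participants.
#' @param norms Norms tibble.
#' @param prior Named list of [group_prior()] objects.
#' @param n_settings Settings sampled per participant (default matches the
#'   full-scale run constant of 1,000 per iteration).
#' @inheritParams participant_loglik
#' @return List with elements `prior` (refitted), `ibic` (of the incoming
#'   prior) and `n_settings`.
#' @export
em_iteration <- function(trials, norms, prior, n_settings = 1000L,
                         variant = "full") {
  stopifnot(n_settings >= 2L)
  validate_group_priors(prior)
  pd <- prepare_likelihood_data(trials, norms)
  n_trials_total <- sum(vapply(pd, function(p) length(p$rt), integer(1)))
  vals <- list()
  wts <- list()
  ibic_ll <- 0
  for (s in names(pd)) {
    settings <- sample_settings(prior, n_settings, variant)
    smat <- as.matrix(settings[, smp_parameter_names()])
    ll <- participant_loglik_cpp(pd[[s]]$ptp, pd[[s]]$rep_idx, pd[[s]]$rt,
                                 smat, variant == "no_rejection")
    ibic_ll <- ibic_ll + (logsumexp(ll) - log(n_settings))
    w <- exp(ll - logsumexp(ll))
    if (!all(is.finite(w)) || sum(w) == 0) {
      warning("importance weights underflowed for participant ", s,
              "; using uniform weights", call. = FALSE)
      w <- rep(1 / n_settings, n_settings)
    }
    vals[[s]] <- settings
    wts[[s]] <- w
  }
  n_part <- length(pd)
  pooled <- dplyr::bind_rows(vals)
  pooled_w <- unlist(wts, use.names = FALSE) / n_part
  new_prior <- prior
  refit_names <- switch(variant,
    no_rejection = setdiff(smp_parameter_names(),
                           c("alpha_i", "alpha_sign")),
    fixed_sign = setdiff(smp_parameter_names(), "alpha_sign"),
    smp_parameter_names()
  )
  for (nm in refit_names) {
    new_prior[[nm]] <- refit_group_prior(prior[[nm]], pooled[[nm]], pooled_w)
  }
  h <- free_hyper_count(prior, variant)
  ibic <- -2 * ibic_ll + h * log(n_trials_total)
  list(prior = new_prior, ibic = ibic, n_settings = n_settings)
}

#' Fitting configuration for the hierarchical EM
#'
#' @param n_settings Settings per participant per EM iteration (full-scale
#'   default 1,000).
#' @param n_settings_final Shared settings for the final participant-level
#'   estimates (full-scale default 10,000).
#' @param max_iter Iteration cap (the full-scale procedure stops after
#'   9–15 iterations; the cap defaults to 15).
#' @param variant Model variant: `"full"`, `"no_rejection"` or
#'   `"fixed_sign"`.
#' @param fixed_sign Clamp value for the `fixed_sign` variant.
#' @param seed Optional integer seed; when supplied the whole fit is
#'   reproducible.
#' @return A list of class `smp_fit_config`.
#' @export
fit_config <- function(n_settings = 1000L, n_settings_final = 10000L,
                       max_iter = 15L, variant = c("full", "no_rejection",
                                                   "fixed_sign"),
                       fixed_sign = 1, n_grid = 512L, seed = NULL) {
  variant <- match.arg(variant)
  structure(list(n_settings = as.integer(n_settings),
                 n_settings_final = as.integer(n_settings_final),
                 max_iter = as.integer(max_iter), variant = variant,
                 fixed_sign = fixed_sign, seed = seed),
            class = "smp_fit_config")
}

#' Hierarchical EM fit of the SMP model
#'
#' Runs [em_iteration()] repeatedly, starting from `init_prior`, until the
#' iBIC ceases to decrease or the iteration cap is reached, then derives
#' participant-level estimates with [estimate_participants()] under the
#' best (lowest-iBIC) priors.
#'
#' @param trials Trial tibble (columns `participant_id`, `cue_id`,
#'   `response`, `rt_ms`, optionally `valid`); at least 2 participants.
#' @param norms Norms tibble.
#' @param init_prior Named list of [group_prior()] objects; defaults to
#'   [default_group_priors()] centred using the data's minimum RT.
#' @param config An [fit_config()] object.
#' @return An object of class `smp_fit`: a list with `iterations` (tibble of
#'   `iteration`, `ibic`), `prior` (best priors), `prior_trace`, `estimates`
#'   (tibble from [estimate_participants()]), `converged`, `variant`,
#'   `config` and bookkeeping counts. Supports [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @export
fit_hierarchical <- function(trials, norms, init_prior = NULL,
                             config = fit_config()) {
  if (is.null(init_prior)) init_prior <- default_group_priors(trials)
  validate_group_priors(init_prior)
  n_part <- length(unique(trials$participant_id))
  if (n_part < 2L) stop("need at least 2 participants", call. = FALSE)
  run <- function() {
    prior <- init_prior
    trace <- list(init_prior)
    ibics <- numeric(0)
    converged <- FALSE
    for (it in seq_len(config$max_iter)) {
      res <- em_iteration(trials, norms, prior,
                          n_settings = config$n_settings,
                          variant = config$variant)
      ibics[it] <- res$ibic
      if (it > 1L && res$ibic >= ibics[it - 1L]) {
        converged <- TRUE
        break
      }
      prior <- res$prior
      trace[[it + 1L]] <- prior
    }
    best_it <- which.min(ibics)
    best_prior <- trace[[best_it]]
    est <- estimate_participants(trials, norms, best_prior,
                                 n_settings = config$n_settings_final,
                                 variant = config$variant)
    structure(list(
      iterations = tibble::tibble(iteration = seq_along(ibics),
                                  ibic = ibics),
      prior = best_prior,
      prior_trace = trace,
      estimates = est,
      converged = converged,
      variant = config$variant,
      config = config,
      n_participants = n_part,
      n_trials = nrow(trials)
    ), class = "smp_fit")
  }
  if (!is.null(config$seed)) withr::with_seed(config$seed, run()) else run()
}

#' Posterior-weighted participant-level parameter estimates
#'
#' Draws one shared set of `n_settings` parameter settings from the final
#' group priors (the same settings for every participant, so that
#' between-participant differences are not driven by sampling variation),
#' evaluates each participant's likelihood over the set, and returns the
#' likelihood-weighted mean of each parameter. For `alpha_sign` the weighted
#' mean of the ±1 values is reported as `alpha_sign_mean` together with its
#' sign as the discrete estimate (ties broken to +1).
#'
#' @inheritParams em_iteration
#' @param n_settings Size of the shared settings sample (full-scale default
#'   10,000).
#' @return Tibble: one row per participant with the seven parameter
#'   estimates plus `alpha_sign_mean` and `ess` (effective sample size of
#'   the importance weights).
#' @export
estimate_participants <- function(trials, norms, prior,
                                  n_settings = 10000L,
                                  variant = "full") {
  validate_group_priors(prior)
  pd <- prepare_likelihood_data(trials, norms)
  settings <- sample_settings(prior, n_settings, variant)
  smat <- as.matrix(settings[, smp_parameter_names()])
  rows <- purrr::imap(pd, function(p, id) {
    ll <- participant_loglik_cpp(p$ptp, p$rep_idx, p$rt, smat,
                                 variant == "no_rejection")
    w <- exp(ll - logsumexp(ll))
    if (!all(is.finite(w)) || sum(w) == 0) w <- rep(1 / n_settings,
                                                    n_settings)
    est <- colSums(smat * w)
    sign_mean <- est[["alpha_sign"]]
    tibble::tibble(
      participant_id = id,
      beta = est[["beta"]], alpha_i = est[["alpha_i"]],
      alpha_sign = ifelse(sign_mean >= 0, 1, -1),
      alpha_sign_mean = sign_mean,
      s_mu = est[["s_mu"]], lambda = est[["lambda"]],
      tau0 = est[["tau0"]], tau_r = est[["tau_r"]],
      ess = 1 / sum(w^2)
    )
  })
  dplyr::bind_rows(rows)
}

#' @export
print.smp_fit <- function(x, ...) {
  cat(sprintf("<smp_fit: %s variant, %d participants, %d trials>\n",
              x$variant, x$n_participants, x$n_trials))
  cat(sprintf("  %d EM iteration(s); final iBIC %.2f; %s\n",
              nrow(x$iterations), min(x$iterations$ibic),
              if (x$converged) "converged" else "iteration cap reached"))
  invisible(x)
}

#' Tidy participant-level estimates of a hierarchical SMP fit
#'
#' @param x An `smp_fit` object.
#' @param ... Unused.
#' @return A long tibble with columns `participant_id`, `parameter`,
#'   `estimate`.
#' @method tidy smp_fit
#' @export
tidy.smp_fit <- function(x, ...) {
  x$estimates |>
    dplyr::select(dplyr::all_of(c("participant_id",
                                  smp_parameter_names()))) |>
    tidyr::pivot_longer(-"participant_id", names_to = "parameter",
                        values_to = "estimate")
}

#' One-row summary of a hierarchical SMP fit
#'
#' @inheritParams tidy.smp_fit
#' @return A one-row tibble: `variant`, `n_participants`, `n_trials`,
#'   `n_iterations`, `ibic`, `converged`.
#' @method glance smp_fit
#' @export
glance.smp_fit <- function(x, ...) {
  tibble::tibble(
    variant = x$variant,
    n_participants = x$n_participants,
    n_trials = x$n_trials,
    n_iterations = nrow(x$iterations),
    ibic = min(x$iterations$ibic),
    converged = x$converged
  )
}

#' iBIC trace plot for a hierarchical SMP fit
#'
#' @param object An `smp_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot smp_fit
#' @export
autoplot.smp_fit <- function(object, ...) {
  ggplot2::ggplot(object$iterations,
                  ggplot2::aes(x = .data$iteration, y = .data$ibic)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "EM iteration", y = "iBIC",
                  title = "Model evidence across EM iterations") +
    ggplot2::theme_minimal()
}

#' Export participant estimates as TSV
#'
#' @param fit An `smp_fit` object (or the estimates tibble itself).
#' @param path Output file path.
#' @param seed,config_hash Optional provenance recorded in header comments.
#' @return `path`, invisibly.
#' @export
write_estimates_tsv <- function(fit, path, seed = NULL, config_hash = NULL) {
  est <- if (inherits(fit, "smp_fit")) fit$estimates else fit
  write_tsv_with_header(est, path, seed = seed, config_hash = config_hash)
}

#' Serialize a fit report to JSON
#'
#' Writes the iBIC trace, final group priors and participant estimates in a
#' machine-readable form.
#'
#' @param fit An `smp_fit` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  payload <- list(
    variant = fit$variant,
    converged = fit$converged,
    iterations = fit$iterations,
    prior = purrr::map(fit$prior, function(p)
      list(family = p$family, hyper = as.list(p$hyper))),
    estimates = fit$estimates,
    n_settings_per_iteration = fit$config$n_settings,
    n_settings_final = fit$config$n_settings_final,
    seed = fit$config$seed
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
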