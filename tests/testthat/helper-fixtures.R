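# Shared fixtures: all synthetic, built in code at test time.

# a fixed 5-association cue used across density/simulation tests
fixture_typicality <- function() {
  c(sky = 0.4, sea = 0.3, jeans = 0.15, ink = 0.1, vein = 0.05)
}

fixture_params <- function(...) {
  args <- utils::modifyList(
    list(beta = -0.3, alpha_i = 0.6, alpha_sign = 1, s_mu = 0.2,
         lambda = 0.5, tau0 = 0.3, tau_r = 0.5),
    list(...)
  )
  do.call(smp_parameters, args)
}

# point-mass group priors pinning every parameter at the given values
point_priors <- function(beta = -0.3, alpha_i = 0.6, alpha_sign = 1,
                         s_mu = 0.2, lambda = 0.5, tau0 = 0.3,
                         tau_r = 0.5) {
  list(
    beta = group_prior("normal", mean = beta, sd = 0),
    alpha_i = group_prior("normal", mean = alpha_i, sd = 0),
    alpha_sign = group_prior("bernoulli_pm1",
                             prob_plus = if (alpha_sign > 0) 1 else 0),
    s_mu = group_prior("normal", mean = s_mu, sd = 0),
    lambda = group_prior("lognormal", meanlog = log(lambda), sdlog = 0),
    tau0 = group_prior("lognormal", meanlog = log(tau0), sdlog = 0),
    tau_r = group_prior("lognormal", meanlog = log(tau_r), sdlog = 0)
  )
}

norms_tibble_for <- function(typicality, cue_id = "c1") {
  tibble::tibble(cue_id = cue_id, lemma = names(typicality),
                 typicality = unname(typicality))
}

# simulate one participant's trial table over a small cue set
simulate_participant_trials <- function(norms, params, participant_id = "p1",
                                        no_rejection = FALSE) {
  cues <- unique(norms$cue_id)
  purrr::map_dfr(cues, function(cue) {
    nf <- norms[norms$cue_id == cue, ]
    tv <- stats::setNames(nf$typicality, nf$lemma)
    tr <- simulate_trial(tv, params, no_rejection = no_rejection)
    tibble::tibble(participant_id = participant_id, cue_id = cue,
                   response = tr$reported, rt_ms = tr$rt * 1000)
  })
}

# small multi-cue norms table with distinct typicality profiles
fixture_multi_norms <- function(n_cues = 8, n_assoc = 6, seed = 42) {
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_cues), function(ci) {
      w <- sort(stats::rexp(n_assoc) + 0.05, decreasing = TRUE)
      w <- w / sum(w)
      tibble::tibble(cue_id = sprintf("c%02d", ci),
                     lemma = sprintf("c%02d_a%02d", ci, seq_len(n_assoc)),
                     typicality = w)
    })
  })
}

# random orthogonal matrix (QR of a Gaussian matrix)
random_rotation <- function(d, seed = 1) {
  withr::with_seed(seed, {
    qr.Q(qr(matrix(stats::rnorm(d * d), d, d)))
  })
}
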