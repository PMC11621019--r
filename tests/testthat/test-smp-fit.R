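test_that("group priors validate, sample and respect point masses", {
  expect_error(group_prior("beta", -1, 2), "improper")
  expect_error(group_prior("bernoulli_pm1", 1.5), "improper")
  withr::with_seed(2, {
    s <- sample_settings(default_group_priors(), 500)
    expect_equal(nrow(s), 500L)
    expect_true(all(s$alpha_i >= 0 & s$alpha_i <= 1))
    expect_true(all(s$alpha_sign %in% c(-1, 1)))
    expect_true(all(s$lambda > 0 & s$tau_r > 0 & s$tau0 >= 0))
    sp <- sample_settings(point_priors(beta = 1.1), 10)
    expect_true(all(sp$beta == 1.1))
  })
})

test_that("variant handling clamps regulation parameters and H counts", {
  withr::with_seed(3, {
    s <- sample_settings(default_group_priors(), 20,
                         variant = "no_rejection")
    expect_true(all(s$alpha_sign == 1))
    sf <- sample_settings(default_group_priors(), 20,
                          variant = "fixed_sign", fixed_sign = -1)
    expect_true(all(sf$alpha_sign == -1))
  })
  pri <- default_group_priors()
  expect_equal(smpassoc:::free_hyper_count(pri, "full"), 13L)
  expect_equal(smpassoc:::free_hyper_count(pri, "no_rejection"), 10L)
  expect_equal(smpassoc:::free_hyper_count(pri, "fixed_sign"), 12L)
})

test_that("participant log-likelihood matches a naive per-trial oracle", {
  norms <- fixture_multi_norms(n_cues = 3)
  params <- fixture_params()
  trials <- withr::with_seed(14,
    simulate_participant_trials(norms, params))
  settings <- withr::with_seed(15,
    sample_settings(default_group_priors(), 4))
  ll <- participant_loglik(trials, norms, settings)
  # naive loop: per-trial densities from the R reference implementation
  oracle <- vapply(seq_len(nrow(settings)), function(k) {
    p <- do.call(smp_parameters,
                 as.list(settings[k, smp_parameter_names()]))
    sum(vapply(seq_len(nrow(trials)), function(i) {
      nf <- norms[norms$cue_id == trials$cue_id[i], ]
      tv <- stats::setNames(nf$typicality, nf$lemma)
      d <- trial_joint_density(tv, p, trials$response[i],
                               trials$rt_ms[i] / 1000, n_grid = 16384L)
      max(log(max(d, 0)), -745)
    }, numeric(1)))
  }, numeric(1))
  expect_equal(ll, oracle, tolerance = 1e-3)
  # zero trials: log of an empty product
  expect_equal(participant_loglik(trials[0, ], norms, settings),
               rep(0, 4))
})

test_that("tau0 above a participant's minimum RT floors the likelihood", {
  norms <- norms_tibble_for(fixture_typicality())
  trials <- tibble::tibble(participant_id = "p1", cue_id = "c1",
                           response = "sky", rt_ms = 800)
  late <- fixture_params(tau0 = 2)  # above the 0.8 s trial
  ll <- participant_loglik(trials, norms,
                           tibble::as_tibble(unclass(late)))
  expect_equal(ll, -745)
})

test_that("EM leaves point-mass priors unchanged", {
  norms <- fixture_multi_norms(n_cues = 4)
  pri <- point_priors()
  trials <- withr::with_seed(5, dplyr::bind_rows(
    simulate_participant_trials(norms, fixture_params(), "p1"),
    simulate_participant_trials(norms, fixture_params(), "p2")
  ))
  res <- withr::with_seed(6, em_iteration(trials, norms, pri,
                                          n_settings = 20))
  expect_equal(res$prior, pri)
  expect_true(is.finite(res$ibic))
})

test_that("the iBIC recomputes from the importance-sampling identity", {
  norms <- fixture_multi_norms(n_cues = 3)
  pri <- default_group_priors()
  trials <- withr::with_seed(7, dplyr::bind_rows(
    simulate_participant_trials(norms, fixture_params(), "p1"),
    simulate_participant_trials(norms, fixture_params(beta = 0.3), "p2")
  ))
  k <- 50
  res <- withr::with_seed(8, em_iteration(trials, norms, pri,
                                          n_settings = k))
  # replay the same sampling stream by hand
  manual <- withr::with_seed(8, {
    acc <- 0
    for (pid in c("p1", "p2")) {
      settings <- sample_settings(pri, k)
      ll <- participant_loglik(trials[trials$participant_id == pid, ],
                               norms, settings)
      m <- max(ll)
      acc <- acc + m + log(mean(exp(ll - m)))
    }
    -2 * acc + 13 * log(nrow(trials))
  })
  expect_equal(res$ibic, manual, tolerance = 1e-8)
})

test_that("iBIC is invariant to permuting participants", {
  norms <- fixture_multi_norms(n_cues = 3)
  pri <- point_priors()  # sampling identical for every participant
  trials <- withr::with_seed(9, dplyr::bind_rows(
    simulate_participant_trials(norms, fixture_params(), "pA"),
    simulate_participant_trials(norms, fixture_params(beta = 0.5), "pB")
  ))
  i1 <- withr::with_seed(10, em_iteration(trials, norms, pri, 10))$ibic
  perm <- trials[rev(seq_len(nrow(trials))), ]
  i2 <- withr::with_seed(10, em_iteration(perm, norms, pri, 10))$ibic
  expect_equal(i1, i2)
})

test_that("one EM iteration shrinks the beta prior toward the truth", {
  # data generated at group mean beta = -1; prior initialized at 0:
  # the refit mean must move strictly into (-1, 0)
  gen <- point_priors()
  gen$beta <- group_prior("normal", mean = -1, sd = 0.3)
  cfg <- synthetic_config(n_cues = 30, cue_pool_size = 30,
                          trials_per_participant = 15,
                          group_prior = gen, seed = 11)
  norms <- generate_cue_norms(cfg)
  cohort <- generate_cohort(25, gen, seed = 11)
  sim <- simulate_dataset(cohort, norms, cfg)
  pri <- default_group_priors(sim$trials)  # beta prior mean 0
  res <- withr::with_seed(12, em_iteration(sim$trials, norms, pri,
                                           n_settings = 200))
  new_mean <- res$prior$beta$hyper[["mean"]]
  expect_lt(new_mean, 0)
  expect_gt(new_mean, -1)
})

test_that("hierarchical fits are reproducible and well-formed", {
  cfg <- synthetic_config(n_cues = 15, cue_pool_size = 15,
                          trials_per_participant = 8, seed = 21)
  norms <- generate_cue_norms(cfg)
  cohort <- generate_cohort(4, seed = 21)
  sim <- simulate_dataset(cohort, norms, cfg)
  fc <- fit_config(n_settings = 40, n_settings_final = 60, max_iter = 2,
                   seed = 100)
  f1 <- fit_hierarchical(sim$trials, norms, config = fc)
  f2 <- fit_hierarchical(sim$trials, norms, config = fc)
  expect_equal(f1$iterations, f2$iterations)
  expect_equal(f1$estimates, f2$estimates)
  expect_s3_class(f1, "smp_fit")
  expect_equal(nrow(f1$estimates), 4L)
  expect_true(all(sort(f1$estimates$participant_id) ==
                    sort(cohort$participant_id)))
  expect_error(fit_hierarchical(sim$trials[sim$trials$participant_id ==
                                             "p0001", ], norms),
               "2 participants")
  # broom-style accessors
  td <- tidy(f1)
  expect_equal(nrow(td), 4L * 7L)
  gl <- glance(f1)
  expect_equal(gl$n_participants, 4L)
  expect_s3_class(autoplot(f1), "ggplot")
})

test_that("importance weights are a proper distribution per participant", {
  norms <- fixture_multi_norms(n_cues = 3)
  trials <- withr::with_seed(31,
    simulate_participant_trials(norms, fixture_params()))
  settings <- withr::with_seed(32,
    sample_settings(default_group_priors(), 100))
  ll <- participant_loglik(trials, norms, settings)
  w <- exp(ll - max(ll))
  w <- w / sum(w)
  expect_true(all(w >= 0))
  expect_equal(sum(w), 1)
})

test_that("estimates equal the setting that carries all the weight", {
  norms <- fixture_multi_norms(n_cues = 4)
  p_true <- fixture_params()
  trials <- withr::with_seed(41, dplyr::bind_rows(
    simulate_participant_trials(norms, p_true, "p1"),
    simulate_participant_trials(norms, p_true, "p2")
  ))
  pri <- point_priors(beta = 0.7, alpha_i = 0.3)
  est <- withr::with_seed(42,
    estimate_participants(trials, norms, pri, n_settings = 30))
  expect_equal(est$beta, c(0.7, 0.7))
  expect_equal(est$alpha_i, c(0.3, 0.3))
  expect_equal(est$alpha_sign, c(1, 1))
})

test_that("fitting no-rejection data does not falsely prefer regulation", {
  # simulate under acceptance == 1; the full model may beat the
  # no-rejection variant by at most its extra iBIC penalty (3 ln N)
  gen <- true_group_priors()
  cfg <- synthetic_config(n_cues = 20, cue_pool_size = 20,
                          trials_per_participant = 10,
                          group_prior = gen, seed = 51)
  norms <- generate_cue_norms(cfg)
  cohort <- generate_cohort(20, gen, seed = 51)
  sim <- simulate_dataset(cohort, norms, cfg, no_rejection = TRUE)
  fc <- function(v) fit_config(n_settings = 100, n_settings_final = 100,
                               max_iter = 3, variant = v, seed = 52)
  fit_full <- fit_hierarchical(sim$trials, norms, config = fc("full"))
  fit_nr <- fit_hierarchical(sim$trials, norms,
                             config = fc("no_rejection"))
  ibic_full <- min(fit_full$iterations$ibic)
  ibic_nr <- min(fit_nr$iterations$ibic)
  penalty_gap <- 3 * log(nrow(sim$trials))
  expect_gt(ibic_full - ibic_nr, -penalty_gap)
})

test_that("fit reports serialize to JSON and TSV", {
  cfg <- synthetic_config(n_cues = 10, cue_pool_size = 10,
                          trials_per_participant = 5, seed = 61)
  norms <- generate_cue_norms(cfg)
  cohort <- generate_cohort(2, seed = 61)
  sim <- simulate_dataset(cohort, norms, cfg)
  fit <- fit_hierarchical(sim$trials, norms,
                          config = fit_config(n_settings = 20,
                                              n_settings_final = 20,
                                              max_iter = 1, seed = 62))
  jpath <- withr::local_tempfile(fileext = ".json")
  write_fit_report(fit, jpath)
  back <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  expect_equal(back$variant, "full")
  expect_equal(length(back$prior), 7L)
  tpath <- withr::local_tempfile(fileext = ".tsv")
  write_estimates_tsv(fit, tpath, seed = 62)
  est <- read_trials_tsv(tpath)
  expect_equal(nrow(est), 2L)
})
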