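test_that("generation distribution tempers typicalities correctly", {
  ptp <- c(0.6, 0.3, 0.1)
  # exp(beta) = 1 leaves an already-normalized vector unchanged
  expect_equal(generation_distribution(ptp, beta = 0), ptp)
  # exp(beta) = 2 squares and renormalizes
  expect_equal(generation_distribution(ptp, beta = log(2)),
               c(0.36, 0.09, 0.01) / 0.46, tolerance = 1e-12)
  # beta -> -Inf flattens to uniform
  expect_equal(generation_distribution(ptp, beta = -50), rep(1 / 3, 3),
               tolerance = 1e-9)
  expect_error(generation_distribution(numeric(0), 0), "empty")
  expect_error(generation_distribution(c(0.5, 0), 0), "> 0")
})

test_that("generation-distribution entropy strictly decreases in beta", {
  entropy <- function(p) -sum(p * log(p))
  withr::with_seed(11, {
    for (rep in 1:5) {
      ptp <- stats::runif(6, 0.01, 1)
      ptp <- ptp / sum(ptp)
      ent <- vapply(c(-2, -1, 0, 1, 2), function(b)
        entropy(generation_distribution(ptp, b)), numeric(1))
      expect_true(all(diff(ent) < 0))
    }
  })
  # degenerate all-equal typicalities: entropy constant
  ent_eq <- vapply(c(-2, 0, 2), function(b)
    entropy(generation_distribution(rep(0.25, 4), b)), numeric(1))
  expect_equal(diff(ent_eq), c(0, 0))
})

test_that("min-max transform rescales to [0,1] with 0.5 degenerate case", {
  expect_equal(minmax_transform(c(0.6, 0.3, 0.1)), c(1, 0.4, 0))
  withr::with_seed(3, {
    x <- stats::runif(10)
    mx <- minmax_transform(x)
    expect_equal(mx[which.min(x)], 0)
    expect_equal(mx[which.max(x)], 1)
  })
  expect_equal(minmax_transform(c(0.2, 0.2, 0.2)), rep(0.5, 3))
})

test_that("acceptance probability follows the slope-10 logistic", {
  # at the threshold the probability is exactly 1/2
  ptp <- c(0.1, 0.3, 0.6)
  mx <- minmax_transform(ptp)
  p <- acceptance_probability(ptp, alpha_i = mx[2], alpha_sign = 1)
  expect_equal(p[2], 0.5)
  # most typical association with alpha_i = 0: logistic(10)
  p1 <- acceptance_probability(ptp, alpha_i = 0, alpha_sign = 1, index = 3)
  expect_equal(p1, 1 / (1 + exp(-10)), tolerance = 1e-10)
  expect_equal(p1, 0.9999546, tolerance = 1e-5)
})

test_that("alpha_sign = -1 mirrors the acceptance curve", {
  withr::with_seed(7, {
    for (rep in 1:5) {
      ptp <- stats::runif(8, 0.01, 1)
      a <- stats::runif(1)
      neg <- acceptance_probability(ptp, a, -1)
      mirrored <- stats::plogis(10 * ((1 - minmax_transform(ptp)) - a))
      expect_equal(neg, mirrored, tolerance = 1e-12)
    }
  })
})

test_that("acceptance is monotone in typicality with direction alpha_sign", {
  withr::with_seed(8, {
    ptp <- sort(stats::runif(7, 0.01, 1))
    expect_true(all(diff(acceptance_probability(ptp, 0.5, 1)) >= 0))
    expect_true(all(diff(acceptance_probability(ptp, 0.5, -1)) <= 0))
  })
})

test_that("generation-time spec matches the gamma moment identities", {
  # P = e^-1 with s_mu = 0 gives a mean of exactly 1 s
  spec <- generation_time_spec(c(exp(-1), 1 - exp(-1)), s_mu = 0,
                               lambda = 0.5)
  expect_equal(spec$mu[1], 1)
  # lambda = 0.5, mu = 2: sigma 1, shape 4, scale 0.5
  p2 <- exp(-2)
  spec2 <- generation_time_spec(c(p2, 1 - p2), s_mu = 0, lambda = 0.5)
  expect_equal(spec2$mu[1], 2)
  expect_equal(spec2$sigma[1], 1)
  expect_equal(spec2$gamma_shape[1], 4)
  expect_equal(spec2$gamma_scale[1], 0.5)
  # moment-matching identities on random rows
  withr::with_seed(5, {
    pr <- generation_distribution(stats::runif(5, 0.01, 1), 0.3)
    sp <- generation_time_spec(pr, s_mu = 0.4, lambda = 0.7)
    expect_equal(sp$gamma_shape * sp$gamma_scale, sp$mu)
    expect_equal(sp$gamma_shape * sp$gamma_scale^2, sp$sigma^2)
  })
  # single-association cue: point mass at time 0
  spec1 <- generation_time_spec(1, s_mu = 0.3, lambda = 0.5)
  expect_equal(spec1$mu, 0)
  expect_equal(spec1$gamma_scale, 0)
})

test_that("simulated trials respect the no-rejection variant and RNG", {
  tv <- fixture_typicality()
  params <- fixture_params()
  withr::with_seed(1, {
    sim <- simulate_trials(tv, params, n = 200, no_rejection = TRUE)
    expect_true(all(sim$n_rejected == 0))
    expect_true(all(sim$rt >= params$tau0))
  })
  r1 <- withr::with_seed(99, simulate_trial(tv, params))
  r2 <- withr::with_seed(99, simulate_trial(tv, params))
  expect_identical(r1, r2)
})

test_that("rejection counts follow the geometric-distribution oracle", {
  # equal typicalities make acceptance constant, so the number of rejected
  # candidates is Geometric(p) with p = logistic(10 * (0.5 - alpha_i))
  tv <- rep(0.2, 5)
  names(tv) <- paste0("w", 1:5)
  params <- fixture_params(alpha_i = 0.7)
  p_acc <- stats::plogis(10 * (0.5 - 0.7))
  n <- 50000
  sim <- withr::with_seed(21, simulate_trials(tv, params, n))
  geo_mean <- (1 - p_acc) / p_acc
  geo_se <- sqrt(1 - p_acc) / p_acc / sqrt(n)
  expect_lt(abs(mean(sim$n_rejected) - geo_mean), 3 * geo_se)
})

test_that("mean simulated RT matches the Wald-identity oracle", {
  # constant acceptance (equal typicalities): E[RT] = E[N] * mu + E[ndt]
  tv <- stats::setNames(rep(1 / 6, 6), paste0("w", 1:6))
  params <- fixture_params(alpha_i = 0.55, s_mu = 0.1, lambda = 0.6)
  p_acc <- stats::plogis(10 * (0.5 - params$alpha_i))
  mu <- exp(params$s_mu) * log(6)
  n <- 10000
  sim <- withr::with_seed(31, simulate_trials(tv, params, n))
  e_rt <- mu / p_acc + params$tau0 + params$tau_r / 2
  # var of total = E[N] var_t + Var[N] mu^2, N counts all draws (geometric+1)
  var_n <- (1 - p_acc) / p_acc^2
  var_t <- (params$lambda * mu)^2
  v_rt <- var_t / p_acc + var_n * mu^2 + params$tau_r^2 / 12
  expect_lt(abs(mean(sim$rt) - e_rt), 3 * sqrt(v_rt / n))
})

test_that("simulation diverges cleanly when nothing can be accepted", {
  tv <- rep(0.25, 4)
  params <- fixture_params(alpha_i = 1, alpha_sign = 1)
  # acceptance = logistic(10 * (0.5 - 1)) ~ 0.0067: not divergent
  expect_silent(withr::with_seed(1, simulate_trial(tv, params)))
  expect_error(
    withr::with_seed(1, simulate_trial(tv, fixture_params(alpha_i = 0.9),
                                       max_draws = 1L)),
    "divergence")
})

test_that("joint density vanishes below the non-decision floor", {
  tv <- fixture_typicality()
  params <- fixture_params()
  expect_equal(trial_joint_density(tv, params, "sky",
                                   c(0.05, 0.2, params$tau0)), c(0, 0, 0))
  expect_gt(trial_joint_density(tv, params, "sky", 1.0), 0)
})

test_that("joint density integrates to one over associations and time", {
  tv <- fixture_typicality()
  params <- fixture_params()
  rtg <- seq(params$tau0 + 1e-4, 40, length.out = 4000)
  dt <- diff(rtg[1:2])
  total <- 0
  for (j in names(tv)) {
    total <- total + sum(trial_joint_density(tv, params, j, rtg)) * dt
  }
  expect_lt(abs(total - 1), 0.005)
})

test_that("time-integrated density equals the marginal report probability", {
  tv <- fixture_typicality()
  params <- fixture_params(beta = 0.2, alpha_i = 0.4, alpha_sign = -1)
  rtg <- seq(params$tau0 + 1e-4, 40, length.out = 4000)
  dt <- diff(rtg[1:2])
  marg <- report_probability(tv, params)
  for (j in c("sky", "ink")) {
    m <- sum(trial_joint_density(tv, params, j, rtg)) * dt
    expect_lt(abs(m - marg[[j]]), 1e-3)
  }
})

test_that("transform-inversion and grid-convolution densities agree", {
  tv <- fixture_typicality()
  cases <- list(
    fixture_params(),
    fixture_params(beta = 0.8, alpha_i = 0.2, alpha_sign = -1),
    fixture_params(s_mu = 0.8, lambda = 1.2, tau0 = 0.1, tau_r = 0.2)
  )
  for (params in cases) {
    pv <- unlist(unclass(params))
    for (j in c(1L, 4L)) {
      for (rt in c(0.6, 1.5, 4, 10)) {
        r_val <- trial_joint_density(tv, params, j, rt, n_grid = 16384L)
        c_val <- smpassoc:::trial_density_cpp(unname(tv), j, rt, pv, FALSE)
        expect_equal(c_val, r_val, tolerance = 5e-3)
      }
    }
  }
})

test_that("single-association cues give uniform non-decision densities", {
  params <- fixture_params()
  tv <- c(only = 1)
  inside <- params$tau0 + params$tau_r / 2
  expect_equal(trial_joint_density(tv, params, "only", inside),
               1 / params$tau_r)
  expect_equal(trial_joint_density(tv, params, "only",
                                   params$tau0 + params$tau_r + 0.5), 0)
})

test_that("mean simulated RT is nondecreasing in the regulation threshold", {
  tv <- fixture_typicality()
  means <- vapply(c(0.1, 0.35, 0.6, 0.85), function(a) {
    sim <- withr::with_seed(17,
      simulate_trials(tv, fixture_params(alpha_i = a, alpha_sign = 1),
                      n = 50000))
    mean(sim$rt)
  }, numeric(1))
  expect_true(all(diff(means) >= 0))
})

test_that("more probable associations are reported faster", {
  tv <- fixture_typicality()
  params <- fixture_params(alpha_i = 0.3)
  sim <- withr::with_seed(23, simulate_trials(tv, params, n = 100000))
  mean_rt <- tapply(sim$rt, factor(sim$reported, levels = names(tv)), mean)
  expect_true(all(diff(as.numeric(mean_rt)) >= 0))
})

test_that("SMP parameters validate and round-trip through JSON", {
  expect_error(smp_parameters(0, 0.5, 0, 0, 0.5, 0.3, 0.5), "alpha_sign")
  expect_error(smp_parameters(0, 0.5, 1, 0, -1, 0.3, 0.5), "lambda")
  expect_error(smp_parameters(0, 1.5, 1, 0, 0.5, 0.3, 0.5), "alpha_i")
  expect_length(unclass(fixture_params()), 7L)
  path <- withr::local_tempfile(fileext = ".json")
  p <- fixture_params(beta = 0.123456789)
  write_smp_parameters(p, path)
  expect_equal(read_smp_parameters(path), p)
})
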