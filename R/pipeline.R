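#' Configuration of the end-to-end parameter-recovery experiment
#'
#' Defaults are the reduced desk-scale recovery design: 60 synthetic
#' participants with 30 trials each, 300 settings per EM iteration, at most
#' 6 iterations, and 2,000 shared settings for the final estimates.
#'
#' @param n_participants Cohort size.
#' @param trials_per_participant Trials simulated per participant.
#' @param n_settings Settings per participant per EM iteration.
#' @param n_settings_final Shared settings for final estimates.
#' @param max_iter EM iteration cap.
#' @param variant Model variant fitted.
#' @param n_assoc_per_cue,skew_exponent,cue_pool_size Synthetic norms shape
#'   (see [synthetic_config()]).
#' @param seed Integer seed driving every stage.
#' @return A list of class `recovery_config`.
#' @export
recovery_config <- function(n_participants = 60L,
                            trials_per_participant = 30L,
                            n_settings = 300L, n_settings_final = 2000L,
                            max_iter = 6L,
                            variant = "full", n_assoc_per_cue = 12L,
                            skew_exponent = 1, cue_pool_size = 148L,
                            seed = 1L) {
  structure(list(n_participants = as.integer(n_participants),
                 trials_per_participant = as.integer(trials_per_participant),
                 n_settings = as.integer(n_settings),
                 n_settings_final = as.integer(n_settings_final),
                 max_iter = as.integer(max_iter), variant = variant,
                 n_assoc_per_cue = as.integer(n_assoc_per_cue),
                 skew_exponent = as.numeric(skew_exponent),
                 cue_pool_size = as.integer(cue_pool_size),
                 seed = as.integer(seed)),
            class = "recovery_config")
}

#' Run the end-to-end parameter-recovery experiment
#'
#' Generates synthetic cue norms, a cohort with known SMP parameters and a
#' simulated trial dataset; fits the hierarchical model to the simulated
#' data; and measures recovery — the Pearson correlation between true and
#' estimated values for each of the seven parameters, plus the accuracy of
#' the recovered regulation direction (`alpha_sign`), overall and among
#' strongly regulating participants (`alpha_i >= 0.6`).
#'
#' @param config A [recovery_config()].
#' @return An object of class `smp_recovery`: `report` (tibble of
#'   `parameter`, `pearson_r`), `sign_accuracy`, `sign_accuracy_strong`,
#'   `n_strong`, `truth` (cohort), `estimates`, `fit`, `config`. Supports
#'   `tidy()`, `glance()` and `autoplot()`.
#' @export
run_recovery_experiment <- function(config = recovery_config()) {
  stopifnot(inherits(config, "recovery_config"))
  scfg <- synthetic_config(
    cue_pool_size = config$cue_pool_size,
    trials_per_participant = config$trials_per_participant,
    n_assoc_per_cue = config$n_assoc_per_cue,
    skew_exponent = config$skew_exponent,
    seed = config$seed
  )
  norms <- generate_cue_norms(scfg)
  cohort <- generate_cohort(config$n_participants, scfg$group_prior,
                            seed = config$seed)
  sim <- simulate_dataset(cohort, norms, scfg)
  fit <- fit_hierarchical(
    sim$trials, norms,
    config = fit_config(n_settings = config$n_settings,
                        n_settings_final = config$n_settings_final,
                        max_iter = config$max_iter,
                        variant = config$variant,
                        seed = config$seed + 10L)
  )
  truth <- cohort
  est <- fit$estimates
  merged <- dplyr::inner_join(truth, est, by = "participant_id",
                              suffix = c("_true", "_est"))
  cont <- setdiff(smp_parameter_names(), "alpha_sign")
  report <- tibble::tibble(
    parameter = smp_parameter_names(),
    pearson_r = vapply(smp_parameter_names(), function(p) {
      x <- merged[[paste0(p, "_true")]]
      y <- if (p == "alpha_sign") merged[["alpha_sign_mean"]]
           else merged[[paste0(p, "_est")]]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_
      else stats::cor(x, y)
    }, numeric(1))
  )
  sign_ok <- merged$alpha_sign_true == merged$alpha_sign_est
  strong <- merged$alpha_i_true >= 0.6
  structure(list(
    report = report,
    sign_accuracy = mean(sign_ok),
    sign_accuracy_strong = if (any(strong)) mean(sign_ok[strong])
                           else NA_real_,
    n_strong = sum(strong),
    truth = truth,
    estimates = est,
    fit = fit,
    config = config
  ), class = "smp_recovery")
}

#' @export
print.smp_recovery <- function(x, ...) {
  cat(sprintf("<smp_recovery: %d participants x %d trials>\n",
              x$config$n_participants, x$config$trials_per_participant))
  for (i in seq_len(nrow(x$report))) {
    cat(sprintf("  r(%s) = %.3f\n", x$report$parameter[i],
                x$report$pearson_r[i]))
  }
  cat(sprintf("  alpha_sign accuracy: %.1f%% overall, %.1f%% strong (n=%d)\n",
              100 * x$sign_accuracy, 100 * x$sign_accuracy_strong,
              x$n_strong))
  invisible(x)
}

#' @rdname run_recovery_experiment
#' @param x,object An `smp_recovery` object.
#' @param ... Unused.
#' @method tidy smp_recovery
#' @export
tidy.smp_recovery <- function(x, ...) {
  x$report
}

#' @rdname run_recovery_experiment
#' @method glance smp_recovery
#' @export
glance.smp_recovery <- function(x, ...) {
  tibble::tibble(
    n_participants = x$config$n_participants,
    trials_per_participant = x$config$trials_per_participant,
    r_beta = x$report$pearson_r[x$report$parameter == "beta"],
    r_s_mu = x$report$pearson_r[x$report$parameter == "s_mu"],
    sign_accuracy = x$sign_accuracy,
    sign_accuracy_strong = x$sign_accuracy_strong,
    ibic = min(x$fit$iterations$ibic),
    converged = x$fit$converged
  )
}

#' @rdname run_recovery_experiment
#' @method autoplot smp_recovery
#' @export
autoplot.smp_recovery <- function(object, ...) {
  merged <- dplyr::inner_join(object$truth, object$estimates,
                              by = "participant_id",
                              suffix = c("_true", "_est"))
  cont <- setdiff(smp_parameter_names(), "alpha_sign")
  long <- purrr::map_dfr(cont, function(p) {
    tibble::tibble(parameter = p,
                   true = merged[[paste0(p, "_true")]],
                   estimated = merged[[paste0(p, "_est")]])
  })
  ggplot2::ggplot(long, ggplot2::aes(x = .data$true, y = .data$estimated)) +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = "True parameter", y = "Estimated parameter",
                  title = "Parameter recovery") +
    ggplot2::theme_minimal()
}

#' Write a machine-readable recovery summary
#'
#' @param recovery An `smp_recovery` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_recovery_report <- function(recovery, path) {
  payload <- list(
    config = unclass(recovery$config),
    pearson_r = stats::setNames(as.list(recovery$report$pearson_r),
                                recovery$report$parameter),
    sign_accuracy = recovery$sign_accuracy,
    sign_accuracy_strong = recovery$sign_accuracy_strong,
    n_strong = recovery$n_strong,
    ibic_trace = recovery$fit$iterations$ibic,
    seed = recovery$config$seed
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# hash over a type-canonical rendering so that a config read from YAML and
# the same config built as an R list hash identically
pipeline_config_hash <- function(cfg) {
  cfg <- cfg[order(names(cfg))]
  rlang::hash(paste(names(cfg),
                    vapply(cfg, function(v)
                      paste(format(v, digits = 15), collapse = ","),
                      character(1)),
                    sep = "=", collapse = ";"))
}

read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    yaml::read_yaml(config)
  } else {
    as.list(config)
  }
}

cfg_get <- function(cfg, key, default) {
  if (!is.null(cfg[[key]])) cfg[[key]] else default
}

#' Run one pipeline stage
#'
#' A file-level interface over the package's functions, suitable for
#' scripting: each stage reads and writes the documented plain-text formats
#' (TSV, JSON, word2vec text) and embeds the seed and a config hash in every
#' output header. Stages compose: running them individually in order equals
#' the full pipeline.
#'
#' Stages and their flat config keys (a YAML file path or a named list):
#' * `"simulate"` — keys `n_participants`, `trials_per_participant`,
#'   `cue_pool_size`, `n_assoc_per_cue`, `skew_exponent`; writes
#'   `trials.tsv`, `norms.tsv` (generator norms) and `ground_truth.json`
#'   under `out_dir`.
#' * `"build-norms"` — key `trials` (TSV path); writes `norms.tsv` built
#'   from the data.
#' * `"fit"` — keys `trials`, `norms`, `n_settings`, `max_iter`, `variant`;
#'   writes `fit.json`.
#' * `"estimate"` — keys `trials`, `norms`, `fit` (JSON from the fit
#'   stage), `n_settings_final`; writes `estimates.tsv`.
#' * `"narrative-metrics"` — keys `docs` (long TSV), `embeddings`
#'   (word2vec text), `windows`; writes `narrative_scores.tsv`.
#' * `"recover"` — [recovery_config()] keys; writes `recovery.json`.
#'
#' @param stage Stage name (see above).
#' @param config Named list or path to a flat YAML config file.
#' @param seed Integer seed (overrides any `seed` key in `config`).
#' @param out_dir Output directory (overrides the `out_dir` key; created if
#'   missing).
#' @return Character vector of the files written, invisibly.
#' @export
run_stage <- function(stage = c("simulate", "build-norms", "fit",
                                "estimate", "narrative-metrics", "recover"),
                      config = list(), seed = NULL, out_dir = NULL) {
  stage <- match.arg(stage)
  cfg <- read_pipeline_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  seed <- as.integer(cfg_get(cfg, "seed", 1L))
  dir <- cfg_get(cfg, "out_dir", ".")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  hash <- pipeline_config_hash(cfg[setdiff(names(cfg), "out_dir")])
  need_input <- function(key) {
    path <- cfg[[key]]
    if (is.null(path) || !file.exists(path)) {
      stop("stage '", stage, "': required input `", key,
           "` missing or not found (", if (is.null(path)) "unset"
           else path, ")", call. = FALSE)
    }
    path
  }
  outfile <- function(name) file.path(dir, name)
  written <- switch(stage,
    "simulate" = {
      scfg <- synthetic_config(
        cue_pool_size = cfg_get(cfg, "cue_pool_size", 148L),
        trials_per_participant = cfg_get(cfg, "trials_per_participant",
                                         20L),
        n_assoc_per_cue = cfg_get(cfg, "n_assoc_per_cue", 12L),
        skew_exponent = cfg_get(cfg, "skew_exponent", 1),
        seed = seed
      )
      norms <- generate_cue_norms(scfg)
      cohort <- generate_cohort(cfg_get(cfg, "n_participants", 60L),
                                scfg$group_prior, seed = seed)
      sim <- simulate_dataset(cohort, norms, scfg)
      write_trials_tsv(sim$trials, outfile("trials.tsv"), seed = seed,
                       config_hash = hash)
      write_norms_tsv(norms, outfile("norms.tsv"), seed = seed,
                      config_hash = hash)
      write_ground_truth(cohort, outfile("ground_truth.json"))
      outfile(c("trials.tsv", "norms.tsv", "ground_truth.json"))
    },
    "build-norms" = {
      trials <- read_trials_tsv(need_input("trials"))
      norms <- build_typicality_norms(trials)
      write_norms_tsv(norms, outfile("norms.tsv"), seed = seed,
                      config_hash = hash)
      outfile("norms.tsv")
    },
    "fit" = {
      trials <- read_trials_tsv(need_input("trials"))
      norms <- read_norms_tsv(need_input("norms"))
      fit <- fit_hierarchical(
        trials, norms,
        config = fit_config(
          n_settings = cfg_get(cfg, "n_settings", 1000L),
          n_settings_final = cfg_get(cfg, "n_settings_final", 10000L),
          max_iter = cfg_get(cfg, "max_iter", 15L),
          variant = cfg_get(cfg, "variant", "full"),
          seed = seed
        )
      )
      write_fit_report(fit, outfile("fit.json"))
      outfile("fit.json")
    },
    "estimate" = {
      trials <- read_trials_tsv(need_input("trials"))
      norms <- read_norms_tsv(need_input("norms"))
      rep <- jsonlite::read_json(need_input("fit"), simplifyVector = TRUE)
      prior <- purrr::map(rep$prior, function(p)
        do.call(group_prior, c(list(family = p$family), p$hyper)))
      est <- withr::with_seed(seed, estimate_participants(
        trials, norms, prior,
        n_settings = cfg_get(cfg, "n_settings_final", 10000L),
        variant = cfg_get(cfg, "variant", "full")
      ))
      write_estimates_tsv(est, outfile("estimates.tsv"), seed = seed,
                          config_hash = hash)
      outfile("estimates.tsv")
    },
    "narrative-metrics" = {
      docs <- read_docs_tsv(need_input("docs"))
      emb <- read_word2vec(need_input("embeddings"))
      windows <- cfg_get(cfg, "windows", 1:5)
      typ <- narrative_typicality(docs)
      coh <- coherence_profile(docs, emb, window_sizes = windows,
                               metric = cfg_get(cfg, "metric", "wmd"))
      coh_mean <- coh |>
        dplyr::group_by(.data$participant_id, .data$prompt_id) |>
        dplyr::summarise(value = mean(.data$coherence, na.rm = TRUE),
                         .groups = "drop") |>
        dplyr::mutate(measure = "coherence")
      scores <- dplyr::bind_rows(
        dplyr::mutate(typ, measure = "typicality",
                      value = .data$typicality,
                      typicality = NULL),
        coh_mean
      )
      comp <- composite_scores(scores) |>
        dplyr::mutate(prompt_id = "composite", .after = "participant_id") |>
        dplyr::rename(value = "composite")
      out <- dplyr::bind_rows(
        dplyr::select(scores, dplyr::all_of(c("participant_id", "prompt_id",
                                              "measure", "value"))),
        dplyr::select(comp, dplyr::all_of(c("participant_id", "prompt_id",
                                            "measure", "value")))
      )
      write_tsv_with_header(out, outfile("narrative_scores.tsv"),
                            seed = seed, config_hash = hash)
      outfile("narrative_scores.tsv")
    },
    "recover" = {
      rc <- recovery_config(
        n_participants = cfg_get(cfg, "n_participants", 60L),
        trials_per_participant = cfg_get(cfg, "trials_per_participant",
                                         30L),
        n_settings = cfg_get(cfg, "n_settings", 300L),
        n_settings_final = cfg_get(cfg, "n_settings_final", 2000L),
        max_iter = cfg_get(cfg, "max_iter", 6L),
        variant = cfg_get(cfg, "variant", "full"),
        n_assoc_per_cue = cfg_get(cfg, "n_assoc_per_cue", 12L),
        skew_exponent = cfg_get(cfg, "skew_exponent", 1),
        cue_pool_size = cfg_get(cfg, "cue_pool_size", 148L),
        seed = seed
      )
      rec <- run_recovery_experiment(rc)
      write_recovery_report(rec, outfile("recovery.json"))
      outfile("recovery.json")
    }
  )
  invisible(written)
}
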