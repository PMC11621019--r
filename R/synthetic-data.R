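#' Configuration for synthetic free-association data
#'
#' The generator emulates the structure of a large-scale color
#' free-association task: a pool of 148 cues, each participant
#' responding to a random subset of 20 of them, with skewed (power-law)
#' per-cue association-typicality distributions and participant
#' heterogeneity in the seven SMP parameters.
#'
#' @param n_cues Number of cues to generate norms for (defaults to the full
#'   cue pool).
#' @param cue_pool_size Size of the cue pool the task draws from
#'   (default 148).
#' @param trials_per_participant Cues presented to each participant, drawn
#'   without replacement from the pool (default 20).
#' @param n_assoc_per_cue Distinct candidate associations per cue
#'   (default 12).
#' @param skew_exponent Power-law shape of the typicality distribution:
#'   typicality of the rank-`r` association is proportional to
#'   `r^(-skew_exponent)`. 0 gives a uniform distribution; 1 (the default)
#'   gives a Zipf-like skew.
#' @param group_prior Named list of [group_prior()] objects used as the
#'   cohort's data-generating (ground-truth) distribution; defaults to
#'   [true_group_priors()].
#' @param seed Integer seed; a single global seed expands into fixed
#'   per-component child seeds so each stage is independently reproducible.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_cues = cue_pool_size, cue_pool_size = 148L,
                             trials_per_participant = 20L,
                             n_assoc_per_cue = 12L, skew_exponent = 1,
                             group_prior = true_group_priors(),
                             seed = 1L) {
  cfg <- list(n_cues = as.integer(n_cues),
              cue_pool_size = as.integer(cue_pool_size),
              trials_per_participant = as.integer(trials_per_participant),
              n_assoc_per_cue = as.integer(n_assoc_per_cue),
              skew_exponent = as.numeric(skew_exponent),
              group_prior = group_prior,
              seed = as.integer(seed))
  if (any(c(cfg$n_cues, cfg$cue_pool_size, cfg$trials_per_participant,
            cfg$n_assoc_per_cue) < 1L)) {
    stop("all counts in a synthetic_config must be >= 1", call. = FALSE)
  }
  if (cfg$trials_per_participant > cfg$cue_pool_size) {
    stop("trials_per_participant cannot exceed cue_pool_size",
         call. = FALSE)
  }
  if (cfg$skew_exponent < 0) {
    stop("skew_exponent must be nonnegative", call. = FALSE)
  }
  validate_group_priors(cfg$group_prior)
  structure(cfg, class = "synthetic_config")
}

#' Ground-truth group priors for synthetic cohorts
#'
#' The data-generating distribution of participant-level SMP parameters:
#' `beta ~ N(-0.5, 0.75)`, `s_mu ~ N(0, 0.5)`, `alpha_i ~ Beta(2, 2)`,
#' `alpha_sign ~ Bernoulli_pm1(0.5)`, `lambda ~ LogNormal(log 0.5, 0.3)`,
#' `tau0 ~ LogNormal(log 0.3, 0.3)`, `tau_r ~ LogNormal(log 0.5, 0.3)`.
#' Chosen once as a realistic degree of participant heterogeneity (RTs on
#' the order of a second; both regulation directions present in the
#' population); distinct from the wider [default_group_priors()] used to
#' initialize fitting.
#'
#' @return Named list of [group_prior()] objects.
#' @export
true_group_priors <- function() {
  list(
    beta = group_prior("normal", mean = -0.5, sd = 0.75),
    alpha_i = group_prior("beta", shape1 = 2, shape2 = 2),
    alpha_sign = group_prior("bernoulli_pm1", prob_plus = 0.5),
    s_mu = group_prior("normal", mean = 0, sd = 0.5),
    lambda = group_prior("lognormal", meanlog = log(0.5), sdlog = 0.3),
    tau0 = group_prior("lognormal", meanlog = log(0.3), sdlog = 0.3),
    tau_r = group_prior("lognormal", meanlog = log(0.5), sdlog = 0.3)
  )
}

# fixed child-seed offsets: component-level reproducibility from one seed
child_seed <- function(seed, component) {
  offset <- c(norms = 1L, cohort = 2L, trials = 3L, embeddings = 4L,
              narratives = 5L)[[component]]
  (as.integer(seed) + offset) %% .Machine$integer.max
}

#' Generate synthetic cue-association typicality norms
#'
#' For each cue, `n_assoc_per_cue` associations receive typicalities
#' proportional to `rank^(-skew_exponent)`, normalized to sum to exactly 1
#' per cue (each synthetic respondent contributes one association, so the
#' per-cue typicalities form a probability distribution). Lemmas are opaque
#' ids; deterministic given the config seed.
#'
#' @param cfg A [synthetic_config()].
#' @return A norms tibble: `cue_id`, `lemma`, `rank`, `typicality`.
#' @examples
#' norms <- generate_cue_norms(synthetic_config(n_cues = 3))
#' @export
generate_cue_norms <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  withr::with_seed(child_seed(cfg$seed, "norms"), {
    k <- cfg$n_assoc_per_cue
    w <- seq_len(k)^(-cfg$skew_exponent)
    w <- w / sum(w)
    purrr::map_dfr(seq_len(cfg$n_cues), function(ci) {
      cue <- sprintf("cue%03d", ci)
      tibble::tibble(
        cue_id = cue,
        lemma = sprintf("%s_assoc%02d", cue, seq_len(k)),
        rank = seq_len(k),
        typicality = w
      )
    })
  })
}

#' Generate a cohort of participants with known SMP parameters
#'
#' Each participant's seven parameters are drawn independently from the
#' group priors; the result is the ground truth against which parameter
#' recovery is measured.
#'
#' @param n_participants Number of participants.
#' @param group_prior Named list of [group_prior()] objects (defaults to
#'   [true_group_priors()]).
#' @param seed Integer seed.
#' @return Tibble with `participant_id` and the seven parameter columns
#'   (`alpha_i` clamped to `[0, 1]`, `alpha_sign` in `{-1, +1}`).
#' @export
generate_cohort <- function(n_participants, group_prior = true_group_priors(),
                            seed = 1L) {
  stopifnot(n_participants >= 1L)
  validate_group_priors(group_prior)
  withr::with_seed(child_seed(seed, "cohort"), {
    s <- sample_settings(group_prior, n_participants)
    dplyr::bind_cols(
      tibble::tibble(participant_id = sprintf("p%04d",
                                              seq_len(n_participants))),
      s
    )
  })
}

#' Simulate a free-association trial dataset from a cohort
#'
#' Runs the SMP generative process forward for every participant: a random
#' subset of `trials_per_participant` cues is drawn without replacement from
#' the cue pool, and each trial is simulated with [simulate_trial()] under
#' the participant's true parameters. Latent diagnostics (true parameters
#' and per-trial rejection counts) are returned in a separate sidecar, never
#' in the primary trial table, so fitting code cannot see ground truth.
#'
#' @param cohort Cohort tibble from [generate_cohort()].
#' @param norms Norms tibble from [generate_cue_norms()].
#' @param cfg A [synthetic_config()].
#' @param no_rejection Simulate the no-rejection generative variant
#'   (acceptance identically 1; every latent rejection count is 0).
#' @return A list of class `smp_simulation` with elements `trials` (tibble:
#'   `participant_id`, `cue_id`, `response`, `rt_ms`, `valid`), `latent`
#'   (tibble: `participant_id`, `cue_id`, `n_rejected`) and `cohort`.
#' @export
simulate_dataset <- function(cohort, norms, cfg, no_rejection = FALSE) {
  stopifnot(inherits(cfg, "synthetic_config"))
  pool <- unique(norms$cue_id)
  if (length(pool) < cfg$trials_per_participant) {
    stop("cue pool smaller than trials_per_participant", call. = FALSE)
  }
  cue_split <- split(norms, norms$cue_id)
  withr::with_seed(child_seed(cfg$seed, "trials"), {
    rows <- purrr::map(seq_len(nrow(cohort)), function(i) {
      pr <- cohort[i, ]
      params <- smp_parameters(pr$beta, pr$alpha_i, pr$alpha_sign, pr$s_mu,
                               pr$lambda, pr$tau0, pr$tau_r)
      cues <- sample(pool, cfg$trials_per_participant, replace = FALSE)
      res <- purrr::map(cues, function(cue) {
        nf <- cue_split[[cue]]
        tv <- stats::setNames(nf$typicality, nf$lemma)
        simulate_trial(tv, params, no_rejection = no_rejection)
      })
      tibble::tibble(
        participant_id = pr$participant_id,
        cue_id = cues,
        response = purrr::map_chr(res, "reported"),
        rt_ms = purrr::map_dbl(res, "rt") * 1000,
        n_rejected = purrr::map_int(res, "n_rejected")
      )
    })
    all <- dplyr::bind_rows(rows)
  })
  structure(list(
    trials = dplyr::mutate(
      dplyr::select(all, !"n_rejected"), valid = TRUE),
    latent = dplyr::select(all, dplyr::all_of(c("participant_id", "cue_id",
                                                "n_rejected"))),
    cohort = cohort
  ), class = "smp_simulation")
}

#' @export
print.smp_simulation <- function(x, ...) {
  cat(sprintf("<smp_simulation: %d trials, %d participants>\n",
              nrow(x$trials), nrow(x$cohort)))
  invisible(x)
}

#' Write cohort ground truth as a JSON sidecar
#'
#' @param cohort Cohort tibble from [generate_cohort()].
#' @param path Output path; JSON maps `participant_id` to the seven named
#'   parameters.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(cohort, path) {
  payload <- stats::setNames(
    purrr::map(seq_len(nrow(cohort)), function(i)
      as.list(cohort[i, smp_parameter_names()])),
    cohort$participant_id
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Configuration for synthetic narrative corpora
#'
#' Documents are topical random walks through a clustered synthetic
#' embedding space: with probability `1 - drift_probability` the next word
#' comes from the current topic; otherwise the walk jumps to a topic chosen
#' uniformly at random (possibly the same one). Low drift gives coherent
#' documents, high drift incoherent ones.
#'
#' @param n_topics Number of topic clusters.
#' @param words_per_topic Vocabulary size per topic.
#' @param embedding_dim Embedding dimensionality (>= 2).
#' @param drift_probability Per-step probability of jumping topics, in
#'   `[0, 1]`.
#' @param min_words Document length (default 100, the minimum narrative
#'   length participants must produce).
#' @param n_prompts Prompts per participant (default 2).
#' @param n_participants Number of participants (documents per prompt).
#' @param within_noise Isotropic noise added to a topic centre before
#'   renormalization; controls cluster tightness.
#' @param seed Integer seed.
#' @return A list of class `narrative_gen_config`.
#' @export
narrative_gen_config <- function(n_topics = 8L, words_per_topic = 40L,
                                 embedding_dim = 50L,
                                 drift_probability = 0.1,
                                 min_words = 100L, n_prompts = 2L,
                                 n_participants = 60L, within_noise = 0.1,
                                 seed = 1L) {
  cfg <- list(n_topics = as.integer(n_topics),
              words_per_topic = as.integer(words_per_topic),
              embedding_dim = as.integer(embedding_dim),
              drift_probability = as.numeric(drift_probability),
              min_words = as.integer(min_words),
              n_prompts = as.integer(n_prompts),
              n_participants = as.integer(n_participants),
              within_noise = as.numeric(within_noise),
              seed = as.integer(seed))
  if (cfg$embedding_dim < 2L) {
    stop("embedding_dim must be >= 2", call. = FALSE)
  }
  if (cfg$drift_probability < 0 || cfg$drift_probability > 1) {
    stop("drift_probability must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$min_words < 1L || cfg$n_topics < 1L || cfg$words_per_topic < 1L ||
      cfg$n_prompts < 1L || cfg$n_participants < 1L) {
    stop("all counts in a narrative_gen_config must be >= 1", call. = FALSE)
  }
  structure(cfg, class = "narrative_gen_config")
}

#' Generate a clustered synthetic embedding space
#'
#' Topic centres are drawn uniformly on the unit sphere; cluster members are
#' the centre plus small isotropic noise, renormalized to unit length, so
#' within-cluster cosine similarity is much higher than across clusters.
#'
#' @param cfg A [narrative_gen_config()].
#' @return A list with `embeddings` (numeric matrix, one row per token,
#'   rownames `t<topic>_w<word>`) and `vocab` (tibble: `token`, `topic`).
#' @export
generate_embedding_space <- function(cfg) {
  stopifnot(inherits(cfg, "narrative_gen_config"))
  withr::with_seed(child_seed(cfg$seed, "embeddings"), {
    d <- cfg$embedding_dim
    centers <- matrix(stats::rnorm(cfg$n_topics * d), cfg$n_topics, d)
    centers <- centers / sqrt(rowSums(centers^2))
    tokens <- character(0)
    emb <- matrix(0, cfg$n_topics * cfg$words_per_topic, d)
    topic_of <- integer(0)
    r <- 0L
    for (tp in seq_len(cfg$n_topics)) {
      for (wd in seq_len(cfg$words_per_topic)) {
        r <- r + 1L
        v <- centers[tp, ] + stats::rnorm(d, sd = cfg$within_noise)
        emb[r, ] <- v / sqrt(sum(v^2))
        tokens[r] <- sprintf("t%02d_w%03d", tp, wd)
        topic_of[r] <- tp
      }
    }
    rownames(emb) <- tokens
    list(embeddings = emb, vocab = tibble::tibble(token = tokens,
                                                  topic = topic_of))
  })
}

#' Generate a drifting synthetic narrative corpus
#'
#' Builds the embedding space with [generate_embedding_space()] and then,
#' for each participant and prompt, generates a document as a topical random
#' walk of `min_words` lemmas (see [narrative_gen_config()] for the drift
#' process). The topic of every emitted word is recorded in a latent sidecar
#' for testing.
#'
#' @param cfg A [narrative_gen_config()].
#' @return A list of class `narrative_corpus` with `docs` (long tibble:
#'   `participant_id`, `prompt_id`, `position`, `lemma`), `embeddings`
#'   (matrix), `vocab`, and `latent_topics` (tibble mirroring `docs` with
#'   the generating topic).
#' @export
generate_narrative_corpus <- function(cfg) {
  stopifnot(inherits(cfg, "narrative_gen_config"))
  space <- generate_embedding_space(cfg)
  by_topic <- split(space$vocab$token, space$vocab$topic)
  withr::with_seed(child_seed(cfg$seed, "narratives"), {
    rows <- list()
    k <- 0L
    for (s in seq_len(cfg$n_participants)) {
      for (pr in seq_len(cfg$n_prompts)) {
        topic <- sample.int(cfg$n_topics, 1L)
        topics <- integer(cfg$min_words)
        lemmas <- character(cfg$min_words)
        for (w in seq_len(cfg$min_words)) {
          if (w > 1L && stats::runif(1) < cfg$drift_probability) {
            topic <- sample.int(cfg$n_topics, 1L)
          }
          topics[w] <- topic
          lemmas[w] <- sample(by_topic[[topic]], 1L)
        }
        k <- k + 1L
        rows[[k]] <- tibble::tibble(
          participant_id = sprintf("p%04d", s),
          prompt_id = sprintf("prompt%d", pr),
          position = seq_len(cfg$min_words),
          lemma = lemmas,
          topic = topics
        )
      }
    }
    docs <- dplyr::bind_rows(rows)
  })
  structure(list(
    docs = dplyr::select(docs, !"topic"),
    embeddings = space$embeddings,
    vocab = space$vocab,
    latent_topics = docs
  ), class = "narrative_corpus")
}

#' @export
print.narrative_corpus <- function(x, ...) {
  cat(sprintf(
    "<narrative_corpus: %d documents, %d tokens, %d-dim embeddings>\n",
    nrow(dplyr::distinct(x$docs, .data$participant_id, .data$prompt_id)),
    nrow(x$docs), ncol(x$embeddings)))
  invisible(x)
}
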