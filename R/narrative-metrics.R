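#' Preprocess a free narrative into an ordered lemma sequence
#'
#' Standard narrative preprocessing: lowercases, tokenizes on whitespace and
#' punctuation, removes non-words/misspellings (tokens absent from the
#' lexicon), digits, stop words, single letters and any configured extra
#' common words, then lemmatizes the survivors (order preserved).
#'
#' @param raw_text A single character string.
#' @param stopwords Character vector of stop words.
#' @param lexicon Character vector of known words (spell check); tokens
#'   absent from it are dropped.
#' @param extra_common Character vector of additional high-frequency words
#'   to drop (e.g. corpus-specific filler words).
#' @param lemmatizer Function mapping words to dictionary forms; defaults to
#'   [default_lemmatizer()] bound to `lexicon`.
#' @return Character vector of content lemmas in input order; length 0 for
#'   an unscoreable document (attribute `scoreable` is set accordingly).
#' @examples
#' preprocess_narrative("Going to do the chores!", stopwords = c("to", "the"),
#'                      lexicon = c("go", "do", "chore"))
#' @export
preprocess_narrative <- function(raw_text, stopwords = character(0),
                                 lexicon, extra_common = character(0),
                                 lemmatizer = NULL) {
  stopifnot(length(raw_text) == 1L)
  lexicon <- tolower(lexicon)
  if (is.null(lemmatizer)) {
    lemmatizer <- function(w) default_lemmatizer(w, lexicon)
  }
  toks <- unlist(strsplit(tolower(raw_text), "[^a-z0-9']+"))
  toks <- toks[toks != ""]
  toks <- toks[!grepl("[0-9]", toks)]
  toks <- toks[nchar(toks) > 1L]
  toks <- toks[!toks %in% tolower(stopwords)]
  toks <- toks[!toks %in% tolower(extra_common)]
  lemmas <- lemmatizer(toks)
  keep <- lemmas %in% lexicon
  lemmas <- lemmas[keep]
  structure(lemmas, scoreable = length(lemmas) > 0L)
}

# term-frequency / smoothed-inverse-document-frequency matrix over a list of
# lemma vectors; idf = ln((1 + N)/(1 + df)) + 1, rows l2-normalized
tfidf_matrix <- function(doc_lemmas) {
  vocab <- sort(unique(unlist(doc_lemmas)))
  n <- length(doc_lemmas)
  tf <- matrix(0, n, length(vocab), dimnames = list(NULL, vocab))
  for (i in seq_len(n)) {
    tab <- table(doc_lemmas[[i]])
    tf[i, names(tab)] <- as.numeric(tab)
  }
  df <- colSums(tf > 0)
  idf <- log((1 + n) / (1 + df)) + 1
  x <- sweep(tf, 2, idf, `*`)
  nrm <- sqrt(rowSums(x^2))
  nrm[nrm == 0] <- 1
  x / nrm
}

#' TF-IDF narrative typicality
#'
#' Scores how typical each participant's narrative is of the corpus: for
#' each prompt, documents are embedded as TF-IDF vectors (smoothed IDF
#' `ln((1+N)/(1+df)) + 1`, downweighting words common across narratives)
#' and a document's typicality is the mean cosine similarity between it and
#' every *other* document written for the same prompt.
#'
#' @param docs Long-format document tibble: `participant_id`, `prompt_id`,
#'   `position`, `lemma` (as produced by [generate_narrative_corpus()] or
#'   assembled from [preprocess_narrative()] output).
#' @return Tibble with one row per document: `participant_id`, `prompt_id`,
#'   `typicality` (`NA` for unscoreable documents).
#' @export
narrative_typicality <- function(docs) {
  purrr::map_dfr(split(docs, docs$prompt_id), function(dd) {
    dd <- dd[order(dd$participant_id, dd$position), ]
    doc_list <- split(dd$lemma, dd$participant_id)
    ids <- names(doc_list)
    if (length(doc_list) < 2L) {
      stop("narrative typicality needs >= 2 documents per prompt",
           call. = FALSE)
    }
    x <- tfidf_matrix(doc_list)
    sim <- x %*% t(x)
    score <- (rowSums(sim) - diag(sim)) / (nrow(sim) - 1)
    empty <- lengths(doc_list) == 0L
    score[empty] <- NA_real_
    tibble::tibble(participant_id = ids,
                   prompt_id = dd$prompt_id[1],
                   typicality = as.numeric(score))
  })
}

lookup_embeddings <- function(lemmas, embeddings) {
  hit <- lemmas %in% rownames(embeddings)
  if (!all(hit)) {
    message(sum(!hit), " lemma(s) without embeddings dropped")
  }
  embeddings[lemmas[hit], , drop = FALSE]
}

#' Relaxed (nearest-neighbour) word mover's distance between word groups
#'
#' The aggregate minimum distance each word in one group must move to reach
#' its closest word in the other group, symmetrized by averaging the two
#' directions: `(mean_i min_j d(v_i, w_j) + mean_j min_i d(w_j, v_i)) / 2`
#' with Euclidean distance in embedding space. Zero iff the two groups cover
#' the same set of vectors; for singleton groups it reduces to the Euclidean
#' distance between the two word vectors.
#'
#' @param group1,group2 Character vectors of lemmas. Lemmas without
#'   embeddings are dropped (with a message).
#' @param embeddings Numeric matrix with token rownames.
#' @return Nonnegative distance, or `NA` if either group is empty after
#'   embedding lookup.
#' @export
relaxed_wmd <- function(group1, group2, embeddings) {
  v <- lookup_embeddings(group1, embeddings)
  w <- lookup_embeddings(group2, embeddings)
  if (nrow(v) == 0L || nrow(w) == 0L) return(NA_real_)
  # pairwise Euclidean distances
  d2 <- outer(rowSums(v^2), rowSums(w^2), `+`) - 2 * v %*% t(w)
  d <- sqrt(pmax(d2, 0))
  (mean(apply(d, 1, min)) + mean(apply(d, 2, min))) / 2
}

#' Windowed narrative coherence
#'
#' Multi-scale coherence of a lemma sequence: for each starting offset
#' `0 .. window-1`, the document is cut into consecutive *non-overlapping*
#' windows of `window` lemmas and each consecutive window pair is scored —
#' by the cosine of the two windows' mean vectors (`metric = "agg_cosine"`)
#' or by the negated relaxed word mover's distance (`metric = "wmd"`; the
#' negation makes higher always mean more coherent). Pair scores are
#' averaged within an offset and then across offsets.
#'
#' For the phrase `cinderella beautiful girl wicked mother` with window 2,
#' offset 0 compares (cinderella, beautiful) with (girl, wicked) and offset
#' 1 compares (beautiful, girl) with (wicked, mother); the result is the
#' mean of those two pair scores.
#'
#' @param lemmas Character vector: the document's ordered content lemmas.
#' @param embeddings Numeric matrix with token rownames.
#' @param window Positive window size; the document must contain at least
#'   `2 * window` lemmas.
#' @param metric `"wmd"` or `"agg_cosine"`.
#' @return A single coherence score (higher = more coherent), or `NA` if
#'   the document is too short.
#' @export
windowed_coherence <- function(lemmas, embeddings, window,
                               metric = c("wmd", "agg_cosine")) {
  metric <- match.arg(metric)
  window <- as.integer(window)
  stopifnot(window >= 1L)
  n <- length(lemmas)
  if (n < 2L * window) return(NA_real_)
  offset_scores <- numeric(0)
  for (o in 0:(window - 1L)) {
    m <- (n - o) %/% window
    if (m < 2L) next
    wins <- purrr::map(seq_len(m), function(k)
      lemmas[(o + (k - 1L) * window + 1L):(o + k * window)])
    pair_scores <- purrr::map_dbl(seq_len(m - 1L), function(k) {
      if (metric == "wmd") {
        -relaxed_wmd(wins[[k]], wins[[k + 1L]], embeddings)
      } else {
        v1 <- colMeans(lookup_embeddings(wins[[k]], embeddings))
        v2 <- colMeans(lookup_embeddings(wins[[k + 1L]], embeddings))
        sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
      }
    })
    offset_scores <- c(offset_scores, mean(pair_scores, na.rm = TRUE))
  }
  if (length(offset_scores) == 0L) return(NA_real_)
  mean(offset_scores)
}

#' Coherence profile of a document corpus
#'
#' Applies [windowed_coherence()] to every document at each requested window
#' size.
#'
#' @param docs Long-format document tibble (`participant_id`, `prompt_id`,
#'   `position`, `lemma`).
#' @param embeddings Numeric matrix with token rownames.
#' @param window_sizes Integer vector of window sizes.
#' @param metric `"wmd"` or `"agg_cosine"`.
#' @return A tibble of class `coherence_profile`: `participant_id`,
#'   `prompt_id`, `window`, `metric`, `coherence`.
#' @export
coherence_profile <- function(docs, embeddings, window_sizes = 1:5,
                              metric = c("wmd", "agg_cosine")) {
  metric <- match.arg(metric)
  docs <- docs[order(docs$participant_id, docs$prompt_id, docs$position), ]
  keys <- dplyr::distinct(docs, .data$participant_id, .data$prompt_id)
  doc_list <- split(docs$lemma,
                    paste(docs$participant_id, docs$prompt_id, sep = "\r"))
  out <- purrr::map_dfr(seq_len(nrow(keys)), function(i) {
    lemmas <- doc_list[[paste(keys$participant_id[i], keys$prompt_id[i],
                              sep = "\r")]]
    coh <- purrr::map_dbl(window_sizes, function(w)
      windowed_coherence(lemmas, embeddings, w, metric))
    tibble::tibble(
      participant_id = keys$participant_id[i],
      prompt_id = keys$prompt_id[i],
      window = as.integer(window_sizes),
      metric = metric,
      coherence = coh
    )
  })
  class(out) <- c("coherence_profile", class(out))
  out
}

#' Plot a corpus coherence profile
#'
#' Mean coherence (with a pointwise standard-error ribbon) across documents
#' at each window size.
#'
#' @param object A [coherence_profile()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot coherence_profile
#' @export
autoplot.coherence_profile <- function(object, ...) {
  summ <- object |>
    dplyr::group_by(.data$window) |>
    dplyr::summarise(mean = mean(.data$coherence, na.rm = TRUE),
                     se = stats::sd(.data$coherence, na.rm = TRUE) /
                       sqrt(sum(!is.na(.data$coherence))),
                     .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$window, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$se,
                                      ymax = .data$mean + .data$se),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Window size (content words)",
                  y = "Mean coherence",
                  title = "Narrative coherence by window size") +
    ggplot2::theme_minimal()
}

#' Standardize-and-sum composite scores across prompts
#'
#' Z-scores each measure within prompt across participants and sums the
#' z-scores across prompts, yielding one composite per participant and
#' measure. Requires at least two participants per prompt (standardization
#' is undefined otherwise).
#'
#' @param scores Long tibble of per-document scores: `participant_id`,
#'   `prompt_id`, `measure`, `value`.
#' @return Tibble: `participant_id`, `measure`, `composite`.
#' @export
composite_scores <- function(scores) {
  stopifnot(all(c("participant_id", "prompt_id", "measure", "value")
                %in% names(scores)))
  n_part <- scores |>
    dplyr::group_by(.data$prompt_id, .data$measure) |>
    dplyr::summarise(n = dplyr::n_distinct(.data$participant_id),
                     .groups = "drop")
  if (any(n_part$n < 2L)) {
    stop("standardization undefined with a single participant",
         call. = FALSE)
  }
  scores |>
    dplyr::group_by(.data$prompt_id, .data$measure) |>
    dplyr::mutate(z = {
      s <- stats::sd(.data$value, na.rm = TRUE)
      if (!is.finite(s) || s == 0) {
        rep(0, dplyr::n())
      } else {
        (.data$value - mean(.data$value, na.rm = TRUE)) / s
      }
    }) |>
    dplyr::group_by(.data$participant_id, .data$measure) |>
    dplyr::summarise(composite = sum(.data$z, na.rm = TRUE),
                     .groups = "drop")
}

#' First-half versus second-half narrative typicality
#'
#' Splits every document at the midpoint of its lemma sequence and scores
#' each half with [narrative_typicality()] against the corpus of the
#' *same* halves of all other documents; the contrast indexes whether
#' atypicality grows as a narrative unfolds.
#'
#' @inheritParams narrative_typicality
#' @return Tibble: `participant_id`, `prompt_id`, `half` (`"first"` /
#'   `"second"`), `typicality`.
#' @export
split_half_typicality <- function(docs) {
  docs <- docs[order(docs$participant_id, docs$prompt_id, docs$position), ]
  halved <- docs |>
    dplyr::group_by(.data$participant_id, .data$prompt_id) |>
    dplyr::mutate(half = ifelse(dplyr::row_number() <=
                                  dplyr::n() %/% 2, "first", "second")) |>
    dplyr::ungroup()
  purrr::map_dfr(c("first", "second"), function(h) {
    sub <- halved[halved$half == h, ]
    narrative_typicality(sub) |>
      dplyr::mutate(half = h, .before = "typicality")
  })
}
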