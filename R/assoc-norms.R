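#' Normalize raw free-association responses
#'
#' Cleans one-word free-association responses the way the color-association
#' preprocessing does: lowercases, then marks as invalid (with a reason)
#' responses that are skipped/empty, single letters, color names, or absent
#' from the spell-check lexicon (non-words and misspellings are removed, not
#' repaired). Surviving responses are lemmatized to their dictionary form
#' via a pluggable lemmatizer.
#'
#' @param trials Raw trial tibble with columns `participant_id`, `cue_id`,
#'   `response` (free text) and `rt_ms`.
#' @param lexicon Character vector of known words (nonempty).
#' @param color_names Character vector of color names to exclude.
#' @param lemmatizer Function mapping a character vector of words to their
#'   dictionary forms; defaults to [default_lemmatizer()] bound to
#'   `lexicon`.
#' @return A trial-record tibble: `participant_id`, `cue_id`,
#'   `response_raw`, `response_lemma` (`NA` when invalid), `rt_ms`, `valid`,
#'   `exclusion_reason` (one of `none`, `nonword`, `color_name`,
#'   `single_letter`, `skipped`).
#' @examples
#' trials <- tibble::tibble(participant_id = "p1", cue_id = "c1",
#'                          response = "chores", rt_ms = 1500)
#' normalize_responses(trials, lexicon = c("chore", "chores"),
#'                     color_names = "blue")
#' @export
normalize_responses <- function(trials, lexicon, color_names = character(0),
                                lemmatizer = NULL) {
  if (length(lexicon) == 0L) {
    stop("`lexicon` must be nonempty", call. = FALSE)
  }
  lexicon <- tolower(lexicon)
  color_names <- tolower(color_names)
  if (is.null(lemmatizer)) {
    lemmatizer <- function(w) default_lemmatizer(w, lexicon)
  }
  raw <- trials$response
  resp <- tolower(trimws(ifelse(is.na(raw), "", raw)))
  reason <- dplyr::case_when(
    resp == "" ~ "skipped",
    nchar(resp) == 1L ~ "single_letter",
    resp %in% color_names ~ "color_name",
    !(resp %in% lexicon) ~ "nonword",
    .default = "none"
  )
  lemma <- rep(NA_character_, length(resp))
  ok <- reason == "none"
  lemma[ok] <- lemmatizer(resp[ok])
  tibble::tibble(
    participant_id = trials$participant_id,
    cue_id = trials$cue_id,
    response_raw = raw,
    response_lemma = lemma,
    rt_ms = trials$rt_ms,
    valid = ok & !is.na(lemma) & lemma != "",
    exclusion_reason = reason
  )
}

#' Rule-based English lemmatizer validated against a lexicon
#'
#' A light suffix stripper implementing the pluggable lemmatizer contract
#' (text to dictionary form): candidate reductions (`chores` → `chore`,
#' `stories` → `story`, `going` → `go`, `running` → `run`, `boxes` → `box`)
#' are tried in priority order and the first candidate present in the
#' lexicon wins; if none is, the word is returned unchanged. Users with a
#' full morphological lemmatizer can pass their own function instead.
#'
#' @param words Character vector of lowercase words.
#' @param lexicon Character vector of known dictionary forms.
#' @return Character vector of lemmas, same length as `words`.
#' @examples
#' default_lemmatizer(c("chores", "going"), c("chore", "go"))
#' @export
default_lemmatizer <- function(words, lexicon) {
  lex <- tolower(lexicon)
  vapply(words, function(w) {
    cands <- character(0)
    n <- nchar(w)
    if (grepl("ies$", w) && n > 4) cands <- c(cands, sub("ies$", "y", w))
    if (grepl("(x|s|z|ch|sh)es$", w)) cands <- c(cands, sub("es$", "", w))
    if (grepl("es$", w) && n > 3) cands <- c(cands, sub("s$", "", w))
    if (grepl("s$", w) && !grepl("ss$", w) && n > 2) {
      cands <- c(cands, sub("s$", "", w))
    }
    if (grepl("ing$", w) && n > 4) {
      stem <- sub("ing$", "", w)
      # doubled final consonant (running -> run), silent e (making -> make)
      cands <- c(cands, stem,
                 if (grepl("([b-df-hj-np-tv-z])\\1$", stem))
                   sub(".$", "", stem),
                 paste0(stem, "e"))
    }
    if (grepl("ed$", w) && n > 3) {
      stem <- sub("ed$", "", w)
      cands <- c(cands, stem, paste0(stem, "e"),
                 if (grepl("([b-df-hj-np-tv-z])\\1$", stem))
                   sub(".$", "", stem))
    }
    hit <- cands[cands %in% lex]
    if (length(hit) > 0) hit[1] else w
  }, character(1), USE.NAMES = FALSE)
}

#' Build per-cue association typicality norms
#'
#' For each cue, counts distinct (participant, lemma) endorsements — a
#' participant is counted once per lemma per cue — and computes typicality
#' as the proportion of that cue's respondents endorsing the association:
#' `count / n_respondents`, where `n_respondents` is the number of
#' participants with at least one valid response to the cue. An association
#' endorsed by exactly one participant is flagged idiosyncratic. Cues with
#' zero valid trials are dropped with a warning.
#'
#' @param trials Trial-record tibble from [normalize_responses()] (or any
#'   tibble with `participant_id`, `cue_id`, `response_lemma`, `valid`).
#' @return A norms tibble: `cue_id`, `lemma`, `count`, `n_respondents`,
#'   `typicality`, `idiosyncratic`, sorted by cue and decreasing count.
#' @export
build_typicality_norms <- function(trials) {
  lemma_col <- if ("response_lemma" %in% names(trials)) "response_lemma"
               else "response"
  all_cues <- unique(trials$cue_id)
  valid <- trials[trials$valid & !is.na(trials[[lemma_col]]), ]
  dropped <- setdiff(all_cues, unique(valid$cue_id))
  if (length(dropped) > 0) {
    warning("excluding ", length(dropped), " cue(s) with no valid trials",
            call. = FALSE)
  }
  valid |>
    dplyr::distinct(.data$cue_id, .data$participant_id,
                    lemma = .data[[lemma_col]]) |>
    dplyr::group_by(.data$cue_id) |>
    dplyr::mutate(n_respondents = dplyr::n_distinct(.data$participant_id)) |>
    dplyr::group_by(.data$cue_id, .data$lemma, .data$n_respondents) |>
    dplyr::summarise(count = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(typicality = .data$count / .data$n_respondents,
                  idiosyncratic = .data$count == 1L) |>
    dplyr::select(dplyr::all_of(c("cue_id", "lemma", "count",
                                  "n_respondents", "typicality",
                                  "idiosyncratic"))) |>
    dplyr::arrange(.data$cue_id, dplyr::desc(.data$count), .data$lemma)
}

#' Filter out participants with too few valid trials
#'
#' Drops all trials of participants with fewer than `min_valid` valid
#' trials (strictly fewer: a participant at exactly the threshold is
#' retained). The default threshold of 10 implements the
#' standard "less than 10 valid responses" exclusion rule.
#'
#' @param trials Trial-record tibble with `participant_id` and `valid`.
#' @param min_valid Minimum number of valid trials to retain a participant.
#' @return A list with `trials` (retained rows) and `exclusions` (tibble:
#'   `participant_id`, `n_valid` for every dropped participant).
#' @export
filter_participants <- function(trials, min_valid = 10L) {
  stopifnot(min_valid >= 1L)
  counts <- trials |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(n_valid = sum(.data$valid), .groups = "drop")
  dropped <- counts[counts$n_valid < min_valid, ]
  list(
    trials = trials[!trials$participant_id %in% dropped$participant_id, ],
    exclusions = dropped
  )
}

#' Smoothed typicality for a response unseen in the norms
#'
#' Responses absent from a cue's candidate set (possible on held-out data)
#' receive typicality `1 / (n_respondents + 1)` and are appended to the
#' candidate set at likelihood time, avoiding zero-probability trials.
#'
#' @param n_respondents Number of respondents behind the cue's norms.
#' @return The smoothed typicality.
#' @export
smoothed_typicality <- function(n_respondents) {
  1 / (n_respondents + 1)
}
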