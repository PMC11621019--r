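# Plain-text interchange formats: TSV tables with provenance headers,
# one-token-per-line word lists, and word2vec text embeddings.

write_tsv_with_header <- function(df, path, seed = NULL,
                                  config_hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(paste0("# seed: ", seed), con)
  if (!is.null(config_hash)) {
    writeLines(paste0("# config_hash: ", config_hash), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_plain <- function(path) {
  tibble::as_tibble(utils::read.delim(path, sep = "\t", comment.char = "#",
                                      stringsAsFactors = FALSE))
}

#' Read and write trial tables as TSV
#'
#' Trial tables are exchanged as TSV with columns `participant_id`,
#' `cue_id`, `response`, `rt_ms`, `valid` (0/1). Provenance (seed, config
#' hash) is embedded in `#` header comments.
#'
#' @param trials Trial tibble.
#' @param path File path.
#' @param seed,config_hash Optional provenance values for the header.
#' @return The written path (invisibly) / the read tibble.
#' @export
write_trials_tsv <- function(trials, path, seed = NULL,
                             config_hash = NULL) {
  out <- trials
  if ("valid" %in% names(out)) out$valid <- as.integer(out$valid)
  write_tsv_with_header(out, path, seed = seed, config_hash = config_hash)
}

#' @rdname write_trials_tsv
#' @export
read_trials_tsv <- function(path) {
  df <- read_tsv_plain(path)
  if ("valid" %in% names(df)) df$valid <- df$valid == 1
  df
}

#' Read and write norms tables as TSV
#'
#' Norms are exchanged as TSV with columns `cue_id`, `lemma`, `count`,
#' `typicality`, `idiosyncratic` (plus any extra columns present); the
#' written file round-trips identically.
#'
#' @param norms Norms tibble.
#' @inheritParams write_trials_tsv
#' @return The written path (invisibly) / the read tibble.
#' @export
write_norms_tsv <- function(norms, path, seed = NULL, config_hash = NULL) {
  out <- norms
  if ("idiosyncratic" %in% names(out)) {
    out$idiosyncratic <- as.integer(out$idiosyncratic)
  }
  write_tsv_with_header(out, path, seed = seed, config_hash = config_hash)
}

#' @rdname write_norms_tsv
#' @export
read_norms_tsv <- function(path) {
  df <- read_tsv_plain(path)
  if ("idiosyncratic" %in% names(df)) {
    df$idiosyncratic <- df$idiosyncratic == 1
  }
  df
}

#' Read a plain-text word list
#'
#' One token per line; blank lines and `#` comments are ignored.
#'
#' @param path File path.
#' @return Character vector of tokens.
#' @export
read_word_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[x != "" & !startsWith(x, "#")]
}

#' Read and write embeddings in word2vec text format
#'
#' The word2vec text format is a header line `"N dim"` followed by one line
#' per token: `token v1 v2 ... vdim`.
#'
#' @param embeddings Numeric matrix with one row per token and token
#'   rownames.
#' @param path File path.
#' @return `write_word2vec()` returns `path` invisibly; `read_word2vec()`
#'   returns the embedding matrix.
#' @export
write_word2vec <- function(embeddings, path) {
  stopifnot(is.matrix(embeddings), !is.null(rownames(embeddings)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(nrow(embeddings), ncol(embeddings)), con)
  apply_fmt <- apply(embeddings, 1, function(v)
    paste(format(v, scientific = FALSE, trim = TRUE, digits = 8),
          collapse = " "))
  writeLines(paste(rownames(embeddings), apply_fmt), con)
  invisible(path)
}

#' @rdname write_word2vec
#' @export
read_word2vec <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  n <- hdr[1]
  d <- hdr[2]
  parts <- strsplit(trimws(lines[1 + seq_len(n)]), "\\s+")
  tokens <- vapply(parts, `[[`, character(1), 1)
  vals <- vapply(parts, function(p) as.numeric(p[-1]), numeric(d))
  emb <- t(vals)
  rownames(emb) <- tokens
  emb
}

#' Read and write long-format narrative documents as TSV
#'
#' Documents are exchanged as TSV with columns `participant_id`,
#' `prompt_id`, `text` (whole document) or, in long form, `position`,
#' `lemma`.
#'
#' @param docs Long-format docs tibble (`participant_id`, `prompt_id`,
#'   `position`, `lemma`).
#' @inheritParams write_trials_tsv
#' @return The written path (invisibly) / the read tibble.
#' @export
write_docs_tsv <- function(docs, path, seed = NULL, config_hash = NULL) {
  write_tsv_with_header(docs, path, seed = seed, config_hash = config_hash)
}

#' @rdname write_docs_tsv
#' @export
read_docs_tsv <- function(path) {
  read_tsv_plain(path)
}
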