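#' Anatomical text categories
#'
#' The detector is conditioned on five anatomical text categories.  The two
#' regions of interest are the lower udder (LU) and the area around the
#' anus (AA); the rear udder (RU), hind legs and hind quarters act as
#' intermediate auxiliary categories whose descriptions chain the ROIs into
#' a continuous spatial structure (LU - hind legs - hind quarters,
#' the latter containing RU and AA).
#'
#' @name text_bank
NULL

TEXT_CATEGORIES <- c("LU", "AA", "RU", "hind_legs", "hind_quarters")

#' Construct a text-bank entry
#'
#' @param category One of `"LU"`, `"AA"`, `"RU"`, `"hind_legs"`,
#'   `"hind_quarters"`.
#' @param description Free-text description establishing the category's
#'   spatial relations to the others.
#' @param is_roi Whether the category is a temperature-extraction target.
#' @return A list of class `text_entry`.
#' @export
text_entry <- function(category, description, is_roi = FALSE) {
  if (!category %in% TEXT_CATEGORIES)
    stop(sprintf("unknown category '%s'", category), call. = FALSE)
  if (!is.character(description) || length(description) != 1L ||
      !nzchar(trimws(description)))
    stop("`description` must be a non-empty string", call. = FALSE)
  structure(list(category = category, description = description,
                 is_roi = isTRUE(is_roi)),
            class = "text_entry")
}

validate_text_bank <- function(entries) {
  cats <- vapply(entries, `[[`, character(1), "category")
  if (anyDuplicated(cats))
    stop("duplicate category in text bank: ",
         paste(unique(cats[duplicated(cats)]), collapse = ", "),
         call. = FALSE)
  if (sum(vapply(entries, `[[`, logical(1), "is_roi")) < 1L)
    stop("text bank must flag at least one ROI category", call. = FALSE)
  structure(entries, class = "text_bank")
}

#' Load a text bank
#'
#' Reads a JSON array of `{category, description, is_roi}` records.  With
#' no path, returns the packaged default bank: the five anatomical
#' categories with LU and AA flagged as ROIs.
#'
#' @param path Path to a JSON bank, or `NULL` for the default.
#' @return A list of `text_entry` objects with class `text_bank`.
#' @export
load_text_bank <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "textbank_default.json",
                        package = "thermoroi", mustWork = TRUE)
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  if (!is.list(raw) || length(raw) < 1L)
    stop("text bank file must be a non-empty JSON array", call. = FALSE)
  entries <- lapply(raw, function(r) {
    if (is.null(r$category) || is.null(r$description))
      stop("each bank record needs `category` and `description`",
           call. = FALSE)
    text_entry(r$category, r$description, isTRUE(r$is_roi))
  })
  validate_text_bank(entries)
}

#' Save a text bank to JSON
#'
#' @param bank A `text_bank`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_text_bank <- function(bank, path) {
  recs <- lapply(bank, function(e)
    list(category = e$category, description = e$description,
         is_roi = e$is_roi))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Restrict a bank to a subset of categories
#'
#' Used for the reduced text configurations (e.g. the two-text ROI-only
#' bank).
#'
#' @param bank A `text_bank`.
#' @param categories Character vector of categories to keep.
#' @return A `text_bank` with only the requested categories.
#' @export
subset_text_bank <- function(bank, categories) {
  keep <- vapply(bank, function(e) e$category %in% categories, logical(1))
  validate_text_bank(bank[keep])
}

# deterministic 31-bit polynomial string hash
string_hash <- function(s, seed = 0L) {
  m <- 2147483647
  h <- (as.numeric(seed) * 2654435761) %% m
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% m
  h
}

# deterministic pseudo-normal vector from an integer state (LCG + qnorm);
# avoids touching the global RNG
hash_normal <- function(state, n) {
  a <- 1103515245; c <- 12345; m <- 2^31
  x <- state %% m
  u <- numeric(n)
  for (i in seq_len(n)) {
    x <- (a * x + c) %% m
    u[i] <- (x + 0.5) / m
  }
  stats::qnorm(u)
}

tokenize_text <- function(s) {
  toks <- strsplit(tolower(s), "[^a-z0-9]+")[[1]]
  toks[nzchar(toks)]
}

#' Encode a text entry into deterministic token features
#'
#' A seeded hashing bag-of-words encoder: each token of the description is
#' hashed (together with the seed) into a pseudo-random unit-variance
#' vector, and the pooled sentence vector is the token mean, L2-normalized.
#' Identical (text, dim, seed) triples give bit-identical features.  The
#' encoder is a deterministic stand-in; any pretrained sentence encoder
#' producing a D-vector per entry can be plugged into the detector in its
#' place.
#'
#' @param entry A `text_entry`.
#' @param dim Embedding dimension (>= 8; default 64).
#' @param seed Integer seed mixed into the token hashes.
#' @return A list of class `text_features` with `tokens` (L x D matrix)
#'   and `pooled` (unit-norm D-vector).
#' @export
encode_text <- function(entry, dim = 64L, seed = 0L) {
  if (dim < 8) stop("`dim` must be >= 8", call. = FALSE)
  toks <- tokenize_text(entry$description)
  if (length(toks) == 0L)
    stop("empty description cannot be encoded", call. = FALSE)
  tokens <- t(vapply(toks, function(tk)
    hash_normal(string_hash(tk, seed), dim), numeric(dim)))
  rownames(tokens) <- NULL
  pooled <- pool_tokens(tokens)
  nrm <- sqrt(sum(pooled^2))
  if (nrm > 0) pooled <- pooled / nrm
  structure(list(tokens = tokens, pooled = pooled), class = "text_features")
}

#' Pool token features into a sentence vector
#'
#' Arithmetic mean along the token axis.
#'
#' @param tokens L x D matrix of token features (L >= 1).
#' @return D-vector of column means.
#' @export
pool_tokens <- function(tokens) {
  if (!is.matrix(tokens) || nrow(tokens) < 1L)
    stop("`tokens` must be a matrix with at least one row", call. = FALSE)
  colMeans(tokens)
}

#' Encode every bank entry
#'
#' @param bank A `text_bank`.
#' @param dim,seed Passed to [encode_text()].
#' @return D x K matrix of pooled unit-norm embeddings, columns named by
#'   category.
#' @export
encode_text_bank <- function(bank, dim = 64L, seed = 0L) {
  emb <- vapply(bank, function(e) encode_text(e, dim, seed)$pooled,
                numeric(dim))
  colnames(emb) <- vapply(bank, `[[`, character(1), "category")
  emb
}
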