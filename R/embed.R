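ENCODINGS <- list(
  # standard one-hot: one active channel per real position
  onehot = list(A = c(1, 0, 0, 0), C = c(0, 1, 0, 0),
                G = c(0, 0, 1, 0), T = c(0, 0, 0, 1)),
  # compact 3-channel binary code (every base nonzero, so padding stays
  # distinguishable); qualitative alternative to one-hot
  compact3 = list(A = c(1, 0, 0), C = c(0, 1, 0),
                  G = c(0, 0, 1), T = c(1, 1, 0))
)

#' One-hot encode a pool into a binary matrix
#'
#' Each sequence becomes a row of `pad_len * channels` binary entries:
#' position blocks in sequence order, zero-padded beyond the sequence end.
#' The default is standard 4-channel one-hot (exactly one active channel per
#' real position); `encoding = "compact3"` is a 3-channel binary code kept
#' behind a flag for parity with triplet-style encodings. U is encoded as T.
#'
#' @param pool A [seq_pool()].
#' @param pad_len Padded length (default 50); sequences longer than this are
#'   an error (all offenders are listed).
#' @param encoding `"onehot"` or `"compact3"`.
#' @return An `encoded_pool`: the binary matrix with attributes `pad_len`,
#'   `encoding`, `channels`, `lengths`, `ids` and `sequences`.
#' @export
encode_pool <- function(pool, pad_len = 50, encoding = c("onehot", "compact3")) {
  encoding <- match.arg(encoding)
  code <- ENCODINGS[[encoding]]
  ch <- length(code[[1]])
  too_long <- nchar(pool$sequence) > pad_len
  if (any(too_long)) {
    abort(sprintf("%d sequence(s) exceed pad_len=%d: %s",
                  sum(too_long), pad_len,
                  paste(head(pool$id[too_long], 10), collapse = ", ")))
  }
  seqs <- norm_dna(pool$sequence)
  mat <- matrix(0, nrow = nrow(pool), ncol = pad_len * ch,
                dimnames = list(pool$id, NULL))
  for (i in seq_len(nrow(pool))) {
    if (nchar(seqs[i]) == 0) next
    chars <- strsplit(seqs[i], "")[[1]]
    for (j in seq_along(chars)) {
      v <- code[[chars[j]]]
      if (is.null(v)) abort(sprintf("unencodable character '%s' in '%s'",
                                    chars[j], pool$id[i]))
      mat[i, ((j - 1) * ch + 1):(j * ch)] <- v
    }
  }
  structure(mat, class = c("encoded_pool", "matrix", "array"),
            pad_len = pad_len, encoding = encoding, channels = ch,
            lengths = nchar(seqs), ids = pool$id, sequences = pool$sequence)
}

#' Decode an encoded pool back to sequences
#'
#' Inverse of [encode_pool()]; uses the stored per-row lengths to strip the
#' zero padding, so encode-decode is exact.
#'
#' @param encoded An `encoded_pool`.
#' @return Character vector of (U-to-T normalized) sequences.
#' @export
decode_pool <- function(encoded) {
  code <- ENCODINGS[[attr(encoded, "encoding")]]
  ch <- attr(encoded, "channels")
  lens <- attr(encoded, "lengths")
  keys <- vapply(code, paste, "", collapse = "")
  vapply(seq_len(nrow(encoded)), function(i) {
    L <- lens[i]
    if (L == 0) return("")
    paste(vapply(seq_len(L), function(j) {
      block <- encoded[i, ((j - 1) * ch + 1):(j * ch)]
      names(keys)[match(paste(block, collapse = ""), keys)]
    }, character(1)), collapse = "")
  }, character(1))
}

#' PCA embedding engine (always-available fit/transform adapter)
#'
#' The embedding step is defined against a fit/transform contract:
#' `fit(matrix)` returns a model, `transform(model, matrix)` returns n x 2
#' coordinates, and transforming the training rows reproduces the fitted
#' coordinates. `pca_engine()` implements the contract with
#' [stats::prcomp()] (first two principal components). A t-SNE-style engine
#' with the same contract can be supplied by the user; the embedding
#' internals themselves are out of scope here.
#'
#' @return A list with elements `fit` and `transform`.
#' @export
pca_engine <- function() {
  list(
    fit = function(m) prcomp(m, center = TRUE, scale. = FALSE, rank. = 2),
    transform = function(model, m) {
      co <- predict(model, newdata = m)[, 1:2, drop = FALSE]
      unname(co)
    })
}

#' Embed selection rounds into a shared 2-D sequence space
#'
#' Merges and collapses the pools of all rounds, encodes the unique
#' sequences ([encode_pool()]), fits ONE embedding model on the merged
#' matrix, and transforms each round's rows through that single model — so
#' coordinates are comparable across rounds and a sequence present in two
#' rounds lands on the same point. Named marker sequences (the seed, known
#' aptamers) can be flagged in the output.
#'
#' @param pools List of [seq_pool()]s with round tags.
#' @param pad_len,encoding Passed to [encode_pool()].
#' @param engine An embedding engine (see [pca_engine()], the default).
#'   If a supplied engine fails to fit, the PCA engine is used instead with
#'   a downgrade message.
#' @param markers Optional named character vector `c(label = sequence)`.
#' @param params Free-form list recorded in the result (e.g. perplexity for
#'   an external t-SNE engine).
#' @return An `embedding` tibble: `id`, `sequence`, `round`, `x`, `y`,
#'   `marker`; attributes `params` and `fitted_on`.
#' @export
embed_rounds <- function(pools, pad_len = 50, encoding = "onehot",
                         engine = pca_engine(), markers = NULL,
                         params = list(perplexity = 50, metric = "cosine",
                                       init = "pca")) {
  merged <- collapse_pool(
    restamp(bind_rows(lapply(pools, as_tibble)), pools[[1]]))
  enc_merged <- encode_pool(merged, pad_len = pad_len, encoding = encoding)
  model <- tryCatch(engine$fit(unclass(enc_merged)), error = function(e) {
    inform(sprintf(
      "embedding engine failed (%s); downgrading to the PCA engine",
      conditionMessage(e)))
    engine <<- pca_engine()
    engine$fit(unclass(enc_merged))
  })
  out <- purrr::map_dfr(pools, function(pool) {
    pool <- collapse_pool(pool)
    if (nrow(pool) == 0) return(NULL)
    enc <- encode_pool(pool, pad_len = pad_len, encoding = encoding)
    co <- engine$transform(model, unclass(enc))
    tibble(id = pool$id, sequence = pool$sequence,
           round = pool_round(pool), x = co[, 1], y = co[, 2])
  })
  out$marker <- NA_character_
  if (!is.null(markers)) {
    mk <- norm_dna(markers)
    idx <- match(norm_dna(out$sequence), mk)
    out$marker <- names(markers)[idx]
  }
  structure(out, class = c("embedding", class(tibble())),
            params = params,
            fitted_on = sprintf("merged rounds %s",
                                paste(vapply(pools, pool_round, 0L),
                                      collapse = "+")))
}
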