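# Position-specific fixed-order Markov models over stem-bulge-gap windows.
#
# A model of order D over a window of W columns stores, for every window
# position i in (D+1)..W and every length-D context s, the count N(sigma, s, i)
# of training segments showing symbol sigma at position i after context s.
# Conditional probabilities use add-alpha smoothing over the emission
# alphabet: P(sigma | s, i) = (N + alpha) / (sum_sigma' N + alpha * K).

# context id at position i from a code matrix; most recent symbol is the
# low-order digit, so id = 1 + sum_k (code(x[i-k]) - 1) * K^(k-1)
ctx_ids <- function(M, i, D, K) {
  ctx <- rep(1, nrow(M)); mult <- 1
  for (k in seq_len(D)) {
    ctx <- ctx + (M[, i - k] - 1) * mult
    mult <- mult * K
  }
  ctx
}

seg_code_matrix <- function(segments, W, alphabet, what = "segment") {
  stopifnot(is.character(segments), length(segments) >= 1L)
  bad <- which(nchar(segments) != W)
  if (length(bad))
    stop(sprintf("%s %d has length %d, expected %d",
                 what, bad[1], nchar(segments[bad[1]]), W))
  codes <- match(unlist(strsplit(segments, "")), alphabet)
  M <- matrix(codes, nrow = length(segments), ncol = W, byrow = TRUE)
  if (anyNA(M)) {
    bad <- which(rowSums(is.na(M)) > 0L)[1]
    stop(sprintf("%s %d contains symbols outside the alphabet {%s}",
                 what, bad, paste(alphabet, collapse = "")))
  }
  M
}

new_fom <- function(counts, D, W, alpha, n_seq, emit_alphabet, ctx_alphabet, type) {
  structure(list(type = type, D = as.integer(D), W = as.integer(W),
                 alpha = alpha, n_seq = as.integer(n_seq),
                 emit_alphabet = emit_alphabet, ctx_alphabet = ctx_alphabet,
                 counts = counts,
                 totals = apply(counts, c(2L, 3L), sum)),
            class = "fom_model")
}

#' @export
print.fom_model <- function(x, ...) {
  cat(sprintf("<fom_model:%s> order D=%d, window W=%d, alpha=%g, %d training segments\n",
              x$type, x$D, x$W, x$alpha, x$n_seq))
  invisible(x)
}

#' Train a position-specific fixed-order Markov model
#'
#' Tallies, for every window position `i` in `(D+1):W` and every length-`D`
#' context, how often each symbol follows that context at that position in
#' the training segments. The first `D` positions of a window carry no
#' counts: the initial-context probability is fixed at 1, so they contribute
#' nothing to any score.
#'
#' @param segments character vector of training windows, each exactly `W`
#'   symbols over `alphabet`.
#' @param D Markov order (context length), >= 1. Default 3.
#' @param W window width in columns. Default 24.
#' @param alpha add-alpha pseudocount (> 0) applied over the emission
#'   alphabet; reduces to maximum likelihood as `alpha` tends to 0.
#' @param alphabet symbol alphabet (default [SBG_ALPHABET]).
#' @return object of class `"fom_model"` holding the raw counts.
#' @export
train_fom <- function(segments, D = 3L, W = 24L, alpha = 1,
                      alphabet = SBG_ALPHABET) {
  stopifnot(D >= 1L, W > D, alpha > 0)
  K <- length(alphabet)
  if (K^D > 2e6) stop("context space too large (K^D > 2e6)")
  nctx <- as.integer(K^D)
  M <- seg_code_matrix(segments, W, alphabet)
  counts <- array(0, dim = c(K, nctx, W))
  for (i in (D + 1L):W) {
    ctx <- ctx_ids(M, i, D, K)
    counts[, , i] <- unclass(table(factor(M[, i], levels = seq_len(K)),
                                   factor(ctx, levels = seq_len(nctx))))
  }
  new_fom(counts, D, W, alpha, nrow(M), emit_alphabet = alphabet,
          ctx_alphabet = alphabet, type = "emission")
}

#' Smoothed conditional probabilities of a model
#'
#' @param m a `"fom_model"`.
#' @return array `[emission symbol, context, position]` of
#'   `(N + alpha) / (total + alpha * K)`; each `(context, position)` slice
#'   sums to 1 over emissions.
#' @export
fom_probabilities <- function(m) {
  stopifnot(inherits(m, "fom_model"))
  K <- length(m$emit_alphabet)
  tot <- aperm(array(m$totals, dim = c(dim(m$totals), K)), c(3L, 1L, 2L))
  (m$counts + m$alpha) / (tot + m$alpha * K)
}

# shared scoring core: sum over positions of log P(emit | ctx, i)
.fom_logscore <- function(m, v, emit_codes) {
  D <- m$D; W <- m$W
  Kc <- length(m$ctx_alphabet); Ke <- length(m$emit_alphabet)
  pos <- (D + 1L):W
  ctx <- rep(1, length(pos)); mult <- 1
  for (k in seq_len(D)) {
    ctx <- ctx + (v[pos - k] - 1) * mult
    mult <- mult * Kc
  }
  n <- m$counts[cbind(emit_codes, ctx, pos)]
  tot <- m$totals[cbind(ctx, pos)]
  sum(log((n + m$alpha) / (tot + m$alpha * Ke)))
}

.segment_codes <- function(m, segment) {
  if (!is.character(segment) || length(segment) != 1L)
    stop("segment must be a single string")
  if (nchar(segment) != m$W)
    stop(sprintf("segment length %d != model window %d", nchar(segment), m$W))
  v <- match(strsplit(segment, "")[[1]], m$ctx_alphabet)
  if (anyNA(v))
    stop(sprintf("segment contains symbols outside the alphabet {%s}",
                 paste(m$ctx_alphabet, collapse = "")))
  v
}

#' Log-probability of a window under a model
#'
#' `sum_{i = D+1}^{W} log P(x_i | x_{i-D..i-1}, i)` in natural log; the first
#' `D` symbols contribute `log 1 = 0`.
#'
#' @param m an emission-type `"fom_model"` from [train_fom()].
#' @param segment a window of exactly `W` symbols.
#' @return log-probability (nats), always <= 0.
#' @export
sequence_log_prob <- function(m, segment) {
  stopifnot(inherits(m, "fom_model"))
  if (m$type != "emission")
    stop("sequence_log_prob expects an emission model; see strand_call() for strand models")
  v <- .segment_codes(m, segment)
  .fom_logscore(m, v, emit_codes = v[(m$D + 1L):m$W])
}

#' Log-odds score of a window: true model vs false model
#'
#' @param true_m,false_m emission models sharing `D`, `W` and alphabet.
#' @param segment window of `W` symbols.
#' @return `sequence_log_prob(true_m, segment) - sequence_log_prob(false_m,
#'   segment)` (nats).
#' @export
fom_score <- function(true_m, false_m, segment) {
  if (true_m$D != false_m$D || true_m$W != false_m$W ||
      !identical(true_m$ctx_alphabet, false_m$ctx_alphabet))
    stop("true and false models must share order, window and alphabet")
  sequence_log_prob(true_m, segment) - sequence_log_prob(false_m, segment)
}

#' Train the strand model
#'
#' Same indexing as [train_fom()], but the emissions are the strand labels
#' `5p`, `3p`, `both`: `N(st, s, i)` counts labeled training windows whose
#' stem-bulge-gap context at position `i` equals `s`.
#'
#' @param segments character vector of training windows (length `W`).
#' @param labels strand label per segment, in [STRAND_LEVELS].
#' @inheritParams train_fom
#' @return a strand-type `"fom_model"`.
#' @export
train_strand_model <- function(segments, labels, D = 3L, W = 24L, alpha = 1,
                               alphabet = SBG_ALPHABET) {
  stopifnot(D >= 1L, W > D, alpha > 0, length(labels) == length(segments))
  lab <- match(labels, STRAND_LEVELS)
  if (anyNA(lab))
    stop(sprintf("labels must be one of %s", paste(STRAND_LEVELS, collapse = ", ")))
  K <- length(alphabet); nctx <- as.integer(K^D)
  M <- seg_code_matrix(segments, W, alphabet)
  counts <- array(0, dim = c(length(STRAND_LEVELS), nctx, W))
  for (i in (D + 1L):W) {
    ctx <- ctx_ids(M, i, D, K)
    counts[, , i] <- unclass(table(factor(lab, levels = seq_along(STRAND_LEVELS)),
                                   factor(ctx, levels = seq_len(nctx))))
  }
  new_fom(counts, D, W, alpha, nrow(M), emit_alphabet = STRAND_LEVELS,
          ctx_alphabet = alphabet, type = "strand")
}

#' Call the mature-miRNA strand of a window
#'
#' For each strand `st`, `L(st) = sum_i log P(st | x_{i-D..i-1}, i)`; the
#' strand with the maximum log-score wins, with ties broken in the fixed
#' order 5p > 3p > both.
#'
#' @param sp a strand-type `"fom_model"` from [train_strand_model()].
#' @param segment window of `W` symbols.
#' @return list with `strand` and the named per-strand log-scores `scores`.
#' @export
strand_call <- function(sp, segment) {
  stopifnot(inherits(sp, "fom_model"))
  if (sp$type != "strand") stop("strand_call expects a strand model")
  v <- .segment_codes(sp, segment)
  npos <- sp$W - sp$D
  L <- vapply(seq_along(STRAND_LEVELS), function(st)
    .fom_logscore(sp, v, emit_codes = rep(st, npos)), numeric(1))
  names(L) <- STRAND_LEVELS
  list(strand = STRAND_LEVELS[which.max(L)], scores = L)
}

#' Save / load a fixed-order Markov model
#'
#' Models round-trip losslessly through a versioned JSON schema; counts are
#' stored sparsely (non-zero entries only).
#'
#' @param m a `"fom_model"`.
#' @param path file path.
#' @export
save_fom <- function(m, path) {
  stopifnot(inherits(m, "fom_model"))
  nz <- which(m$counts > 0, arr.ind = TRUE)
  jsonlite::write_json(
    list(schema_version = 1L, type = m$type, D = m$D, W = m$W,
         alpha = m$alpha, n_seq = m$n_seq,
         emit_alphabet = m$emit_alphabet, ctx_alphabet = m$ctx_alphabet,
         counts = data.frame(emit = nz[, 1L], ctx = nz[, 2L], pos = nz[, 3L],
                             n = m$counts[nz])),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_fom
#' @export
load_fom <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$schema_version) || x$schema_version != 1L)
    stop(sprintf("%s: unsupported model schema version '%s'",
                 path, x$schema_version %||% "missing"))
  K <- length(x$emit_alphabet)
  nctx <- as.integer(length(x$ctx_alphabet)^x$D)
  counts <- array(0, dim = c(K, nctx, x$W))
  if (length(x$counts) && nrow(x$counts))
    counts[cbind(x$counts$emit, x$counts$ctx, x$counts$pos)] <- x$counts$n
  new_fom(counts, x$D, x$W, x$alpha, x$n_seq,
          emit_alphabet = x$emit_alphabet, ctx_alphabet = x$ctx_alphabet,
          type = x$type)
}
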