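#' Stem-bulge-gap alphabet
#'
#' The six column symbols of the stem-bulge-gap notation: `|` CG-class pair,
#' `!` AU-class pair, `:` GU-class pair, `o` hairpin-loop column, `x`
#' symmetric bulge column, `-` asymmetric gap column.
#'
#' @export
SBG_ALPHABET <- c("|", "!", ":", "o", "x", "-")

#' Strand labels
#'
#' Arm labels for the mature miRNA, in tie-break order: `5p` beats `3p`
#' beats `both` when strand log-scores are equal.
#'
#' @export
STRAND_LEVELS <- c("5p", "3p", "both")

.PAIR_CLASS <- c(CG = "|", GC = "|", AU = "!", UA = "!", GU = ":", UG = ":")
.PAIR_SYMBOLS <- c("|", "!", ":")

#' Parse a dot-bracket string into a base-pair table
#'
#' Stack-based bracket matching. Pairs are non-crossing by construction of
#' the notation.
#'
#' @param dotbracket string over `(`, `)`, `.`.
#' @return object of class `"pair_table"`: list with `pairs` (two-column
#'   integer matrix `i < j`, 1-based), `unpaired` (integer positions) and `n`.
#' @examples
#' parse_pairs("((..))")
#' @export
parse_pairs <- function(dotbracket) {
  stopifnot(is.character(dotbracket), length(dotbracket) == 1L)
  chars <- strsplit(dotbracket, "")[[1]]
  n <- length(chars)
  stack <- integer(0)
  pi <- integer(0); pj <- integer(0)
  for (k in seq_len(n)) {
    c <- chars[k]
    if (c == "(") {
      stack <- c(stack, k)
    } else if (c == ")") {
      if (!length(stack))
        stop(sprintf("unbalanced ')' at position %d", k))
      pi <- c(pi, stack[length(stack)]); pj <- c(pj, k)
      stack <- stack[-length(stack)]
    } else if (c != ".") {
      stop(sprintf("invalid structure character '%s' at position %d", c, k))
    }
  }
  if (length(stack))
    stop(sprintf("unmatched '(' at position %d", stack[1]))
  pair_table(cbind(i = pi, j = pj), n)
}

pair_table <- function(pairs, n) {
  pairs <- matrix(as.integer(pairs), ncol = 2L,
                  dimnames = list(NULL, c("i", "j")))
  pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
  structure(list(pairs = pairs,
                 unpaired = setdiff(seq_len(n), as.integer(pairs)),
                 n = as.integer(n)),
            class = "pair_table")
}

#' @export
print.pair_table <- function(x, ...) {
  cat(sprintf("<pair_table> %d nt, %d pairs, %d unpaired\n",
              x$n, nrow(x$pairs), length(x$unpaired)))
  invisible(x)
}

#' Reduce a structure to its main stem
#'
#' The main stem is the root-to-hairpin-loop path of the structure tree that
#' carries the most base pairs ("longest stem" counted in pairs, not
#' nucleotide span). All pairs on discarded side branches are demoted to
#' unpaired positions, so branch bases fold into the surrounding loops,
#' bulges and gaps. Ties between equally long arms are broken towards the
#' 5'-most arm.
#'
#' @param pt a `"pair_table"` from [parse_pairs()].
#' @return a `"pair_table"` containing only the main-stem pairs.
#' @export
select_main_stem <- function(pt) {
  stopifnot(inherits(pt, "pair_table"))
  P <- pt$pairs
  if (!nrow(P)) stop("no stem: structure contains no base pairs")
  # E[r, s] TRUE when pair r strictly encloses pair s
  E <- outer(P[, 1L], P[, 1L], "<") & outer(P[, 2L], P[, 2L], ">")
  leaves <- which(rowSums(E) == 0L)          # innermost pairs (hairpin loops)
  depth <- colSums(E)[leaves] + 1L           # pairs on the path down to each loop
  cand <- leaves[depth == max(depth)]
  best <- cand[which.min(P[cand, 1L])]       # 5'-most arm on ties
  keep <- c(which(E[, best]), best)
  pair_table(P[keep, , drop = FALSE], pt$n)
}

#' Encode a hairpin in stem-bulge-gap notation
#'
#' Converts a hairpin record into the six-symbol column string, ordered from
#' the hairpin loop towards the tail, together with per-column maps back to
#' the 5'-arm and 3'-arm nucleotide positions. The main stem is selected
#' first (see [select_main_stem()]); a hairpin loop of L unpaired bases is
#' folded at its midpoint into `ceiling(L/2)` `o` columns (an odd middle base
#' gets its own column, mapped on the 5' side); each internal region with
#' `a` unpaired bases 5' and `b` bases 3' becomes `min(a, b)` symmetric `x`
#' columns followed by `abs(a - b)` asymmetric `-` columns, loop side first.
#'
#' @param h a [hairpin_record()].
#' @param include_tails encode single-stranded tails outside the outermost
#'   pair as a terminal asymmetric region (default) instead of trimming them.
#' @return object of class `"sbg"`: list with `hairpin_id`, `symbols`
#'   (single string), `five_map` and `three_map` (integer vectors, `NA`
#'   where a column has no base on that arm).
#' @examples
#' h <- hairpin_record("h", "GGGGAAAACCCC", "((((....))))", mfe = -6)
#' encode_sbg(h)$symbols   # "oo||||"
#' @export
encode_sbg <- function(h, include_tails = TRUE) {
  stopifnot(inherits(h, "hairpin_record"))
  pt <- select_main_stem(parse_pairs(h$dotbracket))
  P <- pt$pairs[order(pt$pairs[, 1L], decreasing = TRUE), , drop = FALSE]  # innermost first
  seqc <- strsplit(h$sequence, "")[[1]]
  sym <- character(0); five <- integer(0); three <- integer(0)
  add <- function(s, f, t) {
    sym <<- c(sym, s)
    five <<- c(five, as.integer(f)); three <<- c(three, as.integer(t))
  }
  emit_region <- function(i, j, a, b) {
    mn <- min(a, b)
    for (k in seq_len(mn)) add("x", i - k, j + k)
    if (a > b) for (k in seq_len(a - b)) add("-", i - mn - k, NA)
    else if (b > a) for (k in seq_len(b - a)) add("-", NA, j + mn + k)
  }
  # hairpin loop, folded at its midpoint
  i1 <- P[1L, 1L]; j1 <- P[1L, 2L]
  L <- j1 - i1 - 1L; half <- L %/% 2L
  if (L %% 2L == 1L) add("o", i1 + half + 1L, NA)
  if (half > 0L) for (k in half:1L) add("o", i1 + k, j1 - k)
  # main stem with internal bulges/gaps
  m <- nrow(P)
  for (t in seq_len(m)) {
    i <- P[t, 1L]; j <- P[t, 2L]
    cls <- .PAIR_CLASS[paste0(seqc[i], seqc[j])]
    if (is.na(cls))
      stop(sprintf("record '%s': main-stem pair (%d,%d) %s-%s is not a CG/AU/GU class pair",
                   h$id, i, j, seqc[i], seqc[j]))
    add(unname(cls), i, j)
    if (t < m)
      emit_region(i, j, a = i - P[t + 1L, 1L] - 1L, b = P[t + 1L, 2L] - j - 1L)
  }
  if (include_tails)
    emit_region(P[m, 1L], P[m, 2L], a = P[m, 1L] - 1L, b = pt$n - P[m, 2L])
  structure(list(hairpin_id = h$id, symbols = paste(sym, collapse = ""),
                 five_map = five, three_map = three),
            class = "sbg")
}

#' @export
print.sbg <- function(x, ...) {
  cat(sprintf("<sbg> %s: %s (%d columns, loop->tail)\n",
              x$hairpin_id, x$symbols, nchar(x$symbols)))
  invisible(x)
}

sbg_length <- function(sbg) nchar(sbg$symbols)

sbg_codes <- function(sbg) match(strsplit(sbg$symbols, "")[[1]], SBG_ALPHABET)

#' Map an SBG window back to precursor coordinates
#'
#' Returns the minimal 1-based inclusive sequence interval covering every
#' nucleotide mapped by the window's columns on the requested arm.
#'
#' @param sbg an `"sbg"` object from [encode_sbg()].
#' @param start_col first column of the window (1-based, loop->tail order).
#' @param width window width in columns (>= 1).
#' @param arm `"5p"`, `"3p"` or `"both"`.
#' @return for one arm, an integer `c(start, end)`; for `"both"`, a named
#'   list with both intervals.
#' @export
map_window_to_sequence <- function(sbg, start_col, width, arm = c("5p", "3p", "both")) {
  arm <- match.arg(arm)
  stopifnot(inherits(sbg, "sbg"))
  C <- sbg_length(sbg)
  if (width < 1L) stop("window width must be >= 1")
  if (start_col < 1L || start_col + width - 1L > C)
    stop(sprintf("window [%d, %d] outside columns [1, %d]",
                 start_col, start_col + width - 1L, C))
  cols <- start_col:(start_col + width - 1L)
  one <- function(map, which_arm) {
    v <- map[cols]; v <- v[!is.na(v)]
    if (!length(v))
      stop(sprintf("window has no mapped position on the %s arm", which_arm))
    c(start = min(v), end = max(v))
  }
  switch(arm,
         "5p" = one(sbg$five_map, "5p"),
         "3p" = one(sbg$three_map, "3p"),
         "both" = list("5p" = one(sbg$five_map, "5p"),
                       "3p" = one(sbg$three_map, "3p")))
}

#' Dump SBG strings as plain text
#'
#' One record per line: `id TAB symbols`. Debugging aid; there is no
#' standard interchange format for this notation.
#'
#' @param sbgs list of `"sbg"` objects (or a single one).
#' @param path output path.
#' @export
write_sbg <- function(sbgs, path) {
  if (inherits(sbgs, "sbg")) sbgs <- list(sbgs)
  writeLines(vapply(sbgs, function(s) paste(s$hairpin_id, s$symbols, sep = "\t"),
                    character(1)), path)
  invisible(path)
}
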