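# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use naive string/loop logic, not the package's indexing.

# recount-and-multiply log-probability of `seg` under the smoothed
# position-specific order-D model defined by `train_segs`
naive_fom_logprob <- function(train_segs, seg, D, alpha,
                              alphabet = SBG_ALPHABET) {
  W <- nchar(seg)
  K <- length(alphabet)
  lp <- 0
  for (i in (D + 1):W) {
    ctx <- substr(seg, i - D, i - 1)
    sym <- substr(seg, i, i)
    num <- 0; tot <- 0
    for (tr in train_segs) {
      if (substr(tr, i - D, i - 1) == ctx) {
        tot <- tot + 1
        if (substr(tr, i, i) == sym) num <- num + 1
      }
    }
    lp <- lp + log((num + alpha) / (tot + alpha * K))
  }
  lp
}

# explicit tree walk: enumerate every root-to-leaf chain of nested pairs,
# keep the one with most pairs (tie: 5'-most leaf); returns sorted i-column
oracle_main_stem <- function(dotbracket) {
  chars <- strsplit(dotbracket, "")[[1]]
  stack <- integer(0); pi <- integer(0); pj <- integer(0)
  for (k in seq_along(chars)) {
    if (chars[k] == "(") stack <- c(stack, k)
    else if (chars[k] == ")") {
      pi <- c(pi, stack[length(stack)]); pj <- c(pj, k)
      stack <- stack[-length(stack)]
    }
  }
  m <- length(pi)
  if (!m) stop("no pairs")
  # direct parent: the enclosing pair with the largest i
  parent <- rep(NA_integer_, m)
  for (a in seq_len(m)) {
    enc <- which(pi < pi[a] & pj > pj[a])
    if (length(enc)) parent[a] <- enc[which.max(pi[enc])]
  }
  children <- lapply(seq_len(m), function(a) which(parent == a))
  paths <- list()
  walk <- function(path, node) {
    path <- c(path, node)
    ch <- children[[node]]
    if (!length(ch)) paths[[length(paths) + 1L]] <<- path
    else for (c in ch) walk(path, c)
  }
  for (r in which(is.na(parent))) walk(integer(0), r)
  lens <- lengths(paths)
  cand <- paths[lens == max(lens)]
  leaf_i <- vapply(cand, function(p) pi[p[length(p)]], integer(1))
  best <- cand[[which.min(leaf_i)]]
  idx <- sort(pi[best], index.return = TRUE)$ix
  cbind(i = pi[best][idx], j = pj[best][idx])
}

# all dot-bracket structures of length 1..nmax with 1..max_pairs pairs,
# built by unique leftmost decomposition: s = "." t  |  "(" u ")" v
enumerate_structures <- function(nmax, max_pairs = 4L) {
  S <- vector("list", nmax + 1L)
  empty <- replicate(max_pairs + 1L, character(0), simplify = FALSE)
  S[[1]] <- empty; S[[1]][[1]] <- ""
  for (len in seq_len(nmax)) {
    S[[len + 1L]] <- empty
    for (k in 0:max_pairs) {
      out <- paste0(".", S[[len]][[k + 1L]])
      if (!length(S[[len]][[k + 1L]])) out <- character(0)
      if (k >= 1L && len >= 2L) {
        for (m in 0:(len - 2L)) for (j in 0:(k - 1L)) {
          u <- S[[m + 1L]][[j + 1L]]
          v <- S[[len - 2L - m + 1L]][[k - 1L - j + 1L]]
          if (length(u) && length(v))
            out <- c(out, paste0("(", rep(u, each = length(v)), ")", v))
        }
      }
      S[[len + 1L]][[k + 1L]] <- out
    }
  }
  unlist(lapply(2:(nmax + 1L), function(l)
    unlist(S[[l]][2:(max_pairs + 1L)])), use.names = FALSE)
}

# literal restatement of the first-peak/valley rule, scanning offsets directly
oracle_peak <- function(v, valley_len = 5L) {
  n <- length(v)
  s <- 1L
  while (s <= n) {
    e <- s
    while (e < n && v[e + 1L] == v[s]) e <- e + 1L
    leftv <- if (s > 1L) v[s - 1L] else -Inf
    rightv <- if (e < n) v[e + 1L] else -Inf
    if ((s > 1L || e < n) && v[s] > leftv && v[s] > rightv) {
      lower <- 0L; t <- e + 1L
      while (t <= n && v[t] < v[s]) { lower <- lower + 1L; t <- t + 1L }
      if (lower >= valley_len) return(s)
    }
    s <- e + 1L
  }
  which.max(v)
}

# Mann-Whitney pair statistic (ties count 1/2)
mw_auc <- function(scores, truth) {
  pos <- scores[truth]; neg <- scores[!truth]
  mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
}

# random toy corpus over a small alphabet for oracle comparisons
rand_corpus <- function(W, n, alphabet = SBG_ALPHABET) {
  vapply(seq_len(n), function(i)
    paste(sample(alphabet, W, replace = TRUE), collapse = ""), character(1))
}
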