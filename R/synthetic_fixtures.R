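# Seeded generators for synthetic hairpins, stem-bulge-gap corpora and
# planted-signal datasets. These stand in for curated precursor/pseudo-hairpin
# collections so every stage of the pipeline is testable without downloads.
# Geometry defaults emulate animal pre-miRNAs: a single long stem (26-34
# pairs, ~55-80 nt overall), a 4-8 nt hairpin loop, occasional 1-column
# bulges, and a ~24 nt mature region on one arm. The pseudo-MFE is a
# stacking-free surrogate, -(1.5 nCG + 1.0 nAU + 0.5 nGU) kcal/mol, chosen
# deterministic and monotone in pair stability rather than thermodynamically
# realistic.

#' Specification of a synthetic hairpin generator
#'
#' @param stem_pairs integer range (min, max) of main-stem base pairs.
#' @param loop_len integer range of hairpin-loop length in nt.
#' @param bulge_rate per-column probability of inserting a bulge column
#'   between stem pairs (outside any planted window).
#' @param pair_mix named proportions of CG/AU/GU pair classes for background
#'   stem columns; must sum to 1.
#' @param planted `NULL` or a [planted_spec()] describing a window whose
#'   symbol composition follows a "true" positional signature, with a mature
#'   annotation covering its columns.
#' @return list of class `"hairpin_spec"`.
#' @export
hairpin_spec <- function(stem_pairs = c(26L, 34L), loop_len = c(4L, 8L),
                         bulge_rate = 0.08,
                         pair_mix = c(CG = 1/3, AU = 1/3, GU = 1/3),
                         planted = NULL) {
  stopifnot(length(stem_pairs) == 2L, stem_pairs[1] <= stem_pairs[2],
            stem_pairs[1] >= 1L,
            length(loop_len) == 2L, loop_len[1] <= loop_len[2], loop_len[1] >= 0L,
            bulge_rate >= 0, bulge_rate <= 1)
  if (!setequal(names(pair_mix), c("CG", "AU", "GU")) ||
      abs(sum(pair_mix) - 1) > 1e-8)
    stop("pair_mix must be named proportions over CG, AU, GU summing to 1")
  if (!is.null(planted)) stopifnot(inherits(planted, "planted_spec"))
  structure(list(stem_pairs = as.integer(stem_pairs),
                 loop_len = as.integer(loop_len),
                 bulge_rate = bulge_rate, pair_mix = pair_mix,
                 planted = planted),
            class = "hairpin_spec")
}

#' Planted-window specification
#'
#' Describes a window of stem columns whose pair-class composition follows a
#' position-specific signature, together with the arm that carries the
#' mature annotation.
#'
#' @param offset first column of the planted window (1-based, loop->tail);
#'   must lie beyond the loop columns.
#' @param width window width in columns.
#' @param arm `"5p"`, `"3p"` or `"both"`.
#' @param schedule `3 x width` matrix of per-position CG/AU/GU probabilities
#'   (rows named `CG`, `AU`, `GU`, columns summing to 1); `NULL` uses the
#'   built-in [arm_schedule()] for `arm`.
#' @return list of class `"planted_spec"`.
#' @export
planted_spec <- function(offset = 5L, width = 24L, arm = "5p", schedule = NULL) {
  stopifnot(offset >= 1L, width >= 1L, arm %in% STRAND_LEVELS)
  if (is.null(schedule)) schedule <- arm_schedule(arm, width)
  stopifnot(is.matrix(schedule), nrow(schedule) == 3L, ncol(schedule) == width,
            all(rownames(schedule) == c("CG", "AU", "GU")),
            all(abs(colSums(schedule) - 1) < 1e-8))
  structure(list(offset = as.integer(offset), width = as.integer(width),
                 arm = arm, schedule = schedule),
            class = "planted_spec")
}

#' Built-in positional pair-class signatures per arm
#'
#' Odd window positions carry an arm-independent, deliberately aperiodic
#' dominant-class pattern: it separates true windows from the uniform
#' background and, because the pattern has no shift symmetry, from shifted
#' copies of themselves (position-specific offset signal). Even positions
#' carry one arm-specific dominant class (CG for 5p, AU for 3p, GU for
#' both), giving the strand model its cue without diluting the shared
#' signal. Dominant classes get probability 0.95, the other two 0.025 each.
#'
#' @param arm `"5p"`, `"3p"` or `"both"`.
#' @param width window width; the odd-position pattern is recycled.
#' @return `3 x width` probability matrix (rows `CG`, `AU`, `GU`).
#' @export
arm_schedule <- function(arm, width = 24L) {
  stopifnot(arm %in% STRAND_LEVELS, width >= 1L)
  classes <- c("CG", "AU", "GU")
  signal <- c("CG", "AU", "GU", "CG", "CG", "AU",
              "AU", "GU", "CG", "GU", "AU", "CG")
  armdom <- switch(arm, "5p" = "CG", "3p" = "AU", "both" = "GU")
  sched <- matrix(0.025, nrow = 3L, ncol = width,
                  dimnames = list(classes, NULL))
  for (p in seq_len(width)) {
    dom <- if (p %% 2L == 1L) signal[(ceiling(p / 2) - 1L) %% 12L + 1L] else armdom
    sched[dom, p] <- 0.95
  }
  sched
}

.pair_bases <- list(CG = c("C", "G"), AU = c("A", "U"), GU = c("G", "U"))
.rna_bases <- c("A", "C", "G", "U")

#' Generate one synthetic hairpin
#'
#' Builds sequence and dot-bracket jointly, column by column from the loop
#' outwards: a random loop, then stem pair columns (classes drawn from the
#' planted schedule inside the planted window, from the background mix
#' outside) interleaved with bulge columns at `bulge_rate`. The pseudo-MFE
#' is `-(1.5 nCG + 1.0 nAU + 0.5 nGU)` kcal/mol. When a window is planted,
#' the mature annotation is derived from the record's own stem-bulge-gap
#' encoding so that it covers exactly the planted columns on the labeled
#' arm(s).
#'
#' @param spec a [hairpin_spec()].
#' @param seed optional integer seed (same seed, same record).
#' @param id record identifier.
#' @return a [hairpin_record()]; planted records carry attributes
#'   `planted_offset` and `planted_arm`.
#' @export
generate_hairpin <- function(spec, seed = NULL, id = "synth") {
  stopifnot(inherits(spec, "hairpin_spec"))
  if (!is.null(seed)) set.seed(seed)
  pick <- function(r) if (r[1] == r[2]) r[1] else sample(r[1]:r[2], 1L)
  n_pairs <- pick(spec$stem_pairs)
  L <- pick(spec$loop_len)
  loop_cols <- ceiling(L / 2)
  pl <- spec$planted
  if (!is.null(pl) && pl$offset <= loop_cols)
    stop(sprintf("planted window at column %d would overlap the %d loop column(s)",
                 pl$offset, loop_cols))
  # column plan beyond the loop, loop->tail
  plan_type <- character(0); plan_class <- character(0); plan_side <- character(0)
  col <- loop_cols; placed <- 0L
  while (placed < n_pairs) {
    col <- col + 1L
    in_plant <- !is.null(pl) && col >= pl$offset && col <= pl$offset + pl$width - 1L
    if (in_plant) {
      cls <- sample(c("CG", "AU", "GU"), 1L,
                    prob = pl$schedule[, col - pl$offset + 1L])
      plan_type <- c(plan_type, "pair"); plan_class <- c(plan_class, cls)
      plan_side <- c(plan_side, NA); placed <- placed + 1L
    } else if (placed > 0L && stats::runif(1) < spec$bulge_rate) {
      bt <- sample(c("x", "-"), 1L)
      plan_type <- c(plan_type, bt); plan_class <- c(plan_class, NA)
      plan_side <- c(plan_side, if (bt == "-") sample(c("5", "3"), 1L) else NA)
    } else {
      cls <- sample(c("CG", "AU", "GU"), 1L, prob = spec$pair_mix)
      plan_type <- c(plan_type, "pair"); plan_class <- c(plan_class, cls)
      plan_side <- c(plan_side, NA); placed <- placed + 1L
    }
  }
  if (!is.null(pl) && col < pl$offset + pl$width - 1L)
    stop("spec admits fewer stem columns than the planted window requires")
  # realize arms, loop->tail
  five_seq <- character(0); three_seq <- character(0)
  five_db <- character(0); three_db <- character(0)
  for (e in seq_along(plan_type)) {
    if (plan_type[e] == "pair") {
      b <- .pair_bases[[plan_class[e]]]
      if (sample(c(TRUE, FALSE), 1L)) b <- rev(b)
      five_seq <- c(five_seq, b[1]); three_seq <- c(three_seq, b[2])
      five_db <- c(five_db, "("); three_db <- c(three_db, ")")
    } else if (plan_type[e] == "x") {
      five_seq <- c(five_seq, sample(.rna_bases, 1L))
      three_seq <- c(three_seq, sample(.rna_bases, 1L))
      five_db <- c(five_db, "."); three_db <- c(three_db, ".")
    } else if (plan_side[e] == "5") {
      five_seq <- c(five_seq, sample(.rna_bases, 1L))
      five_db <- c(five_db, ".")
    } else {
      three_seq <- c(three_seq, sample(.rna_bases, 1L))
      three_db <- c(three_db, ".")
    }
  }
  loop_seq <- sample(.rna_bases, L, replace = TRUE)
  sequence <- paste(c(rev(five_seq), loop_seq, three_seq), collapse = "")
  dotbracket <- paste(c(rev(five_db), rep(".", L), three_db), collapse = "")
  n_cls <- table(factor(plan_class[plan_type == "pair"],
                        levels = c("CG", "AU", "GU")))
  mfe <- -(1.5 * n_cls[["CG"]] + 1.0 * n_cls[["AU"]] + 0.5 * n_cls[["GU"]])
  rec <- hairpin_record(id, sequence, dotbracket, mfe = mfe)
  if (!is.null(pl)) {
    sbg <- encode_sbg(rec)
    plant_cols <- pl$offset:(pl$offset + pl$width - 1L)
    stopifnot(all(strsplit(sbg$symbols, "")[[1]][plant_cols] %in% .PAIR_SYMBOLS))
    arms <- if (pl$arm == "both") c("5p", "3p") else pl$arm
    mature <- do.call(rbind, lapply(arms, function(a) {
      iv <- map_window_to_sequence(sbg, pl$offset, pl$width, a)
      data.frame(start = iv["start"], end = iv["end"], arm = a,
                 stringsAsFactors = FALSE)
    }))
    rec <- hairpin_record(id, sequence, dotbracket, mfe = mfe, mature = mature)
    attr(rec, "planted_offset") <- pl$offset
    attr(rec, "planted_arm") <- pl$arm
  }
  rec
}

#' Generate a labeled synthetic dataset
#'
#' Positives carry a planted window at a common column offset, with the arm
#' drawn per record from `arm_probs` and the matching [arm_schedule()];
#' negatives are background hairpins of the same geometry with no planted
#' signal. Records are written FASTA/Vienna/annotation-table compatible (see
#' [write_vienna()], [write_annotations()]) so fixtures can exercise the
#' file readers.
#'
#' @param n_pos,n_neg class sizes.
#' @param seed integer seed for the whole dataset.
#' @param pos_spec,neg_spec [hairpin_spec()]s; `pos_spec` must be planted.
#' @param arm_probs named sampling weights over `5p`, `3p`, `both`.
#' @return list with `positives` and `negatives` (lists of records).
#' @export
generate_dataset <- function(n_pos, n_neg, seed = NULL,
                             pos_spec = hairpin_spec(planted = planted_spec()),
                             neg_spec = hairpin_spec(),
                             arm_probs = c("5p" = 0.4, "3p" = 0.4, "both" = 0.2)) {
  stopifnot(n_pos >= 1L, n_neg >= 1L, !is.null(pos_spec$planted),
            setequal(names(arm_probs), STRAND_LEVELS))
  if (!is.null(seed)) set.seed(seed)
  positives <- lapply(seq_len(n_pos), function(r) {
    arm <- sample(names(arm_probs), 1L, prob = arm_probs)
    sp <- pos_spec
    sp$planted <- planted_spec(pos_spec$planted$offset, pos_spec$planted$width,
                               arm = arm)
    generate_hairpin(sp, id = sprintf("pos%04d", r))
  })
  negatives <- lapply(seq_len(n_neg), function(r)
    generate_hairpin(neg_spec, id = sprintf("neg%04d", r)))
  list(positives = positives, negatives = negatives)
}

#' Position-specific Markov chain over the SBG alphabet
#'
#' Defines the sampling distribution for synthetic window corpora: an
#' initial distribution over length-`D` contexts and, for every position
#' `(D+1):W`, a conditional distribution of the next symbol given the
#' context. Context ids use the same encoding as the trained models (most
#' recent symbol = low-order digit).
#'
#' @param D context length.
#' @param W window width.
#' @param init probability vector over the `K^D` context ids for the first
#'   `D` symbols.
#' @param trans `K x K^D x W` array; `trans[, s, i]` is the distribution of
#'   the symbol at position `i` given context `s` (used for `i > D`). Every
#'   used column must sum to 1.
#' @param alphabet symbol alphabet.
#' @return list of class `"sbg_chain"`.
#' @export
sbg_chain <- function(D, W, init, trans, alphabet = SBG_ALPHABET) {
  K <- length(alphabet); nctx <- as.integer(K^D)
  stopifnot(D >= 1L, W > D, length(init) == nctx,
            abs(sum(init) - 1) < 1e-8, all(init >= 0),
            identical(dim(trans), c(K, nctx, as.integer(W))))
  sums <- apply(trans[, , (D + 1L):W, drop = FALSE], c(2L, 3L), sum)
  if (any(abs(sums - 1) > 1e-8) || any(trans < 0))
    stop("non-normalized chain rows: every trans[, s, i] must be a distribution")
  structure(list(D = as.integer(D), W = as.integer(W), init = init,
                 trans = trans, alphabet = alphabet),
            class = "sbg_chain")
}

#' Sample windows from a position-specific chain
#'
#' @param chain an [sbg_chain()].
#' @param n number of windows.
#' @param seed optional seed.
#' @return character vector of `n` windows of width `W`.
#' @export
sample_chain <- function(chain, n, seed = NULL) {
  stopifnot(inherits(chain, "sbg_chain"), n >= 1L)
  if (!is.null(seed)) set.seed(seed)
  K <- length(chain$alphabet); D <- chain$D; W <- chain$W
  M <- matrix(0L, nrow = n, ncol = W)
  ctx <- sample.int(length(chain$init), n, replace = TRUE, prob = chain$init)
  # decompose initial context: low-order digit is the most recent symbol x_D
  rem <- ctx - 1L
  for (k in D:1L) {       # k-th most recent symbol sits at digit k-1
    M[, D - k + 1L] <- (rem %/% K^(k - 1L)) %% K + 1L
  }
  for (i in (D + 1L):W) {
    for (s in unique(ctx)) {
      idx <- which(ctx == s)
      M[idx, i] <- sample.int(K, length(idx), replace = TRUE,
                              prob = chain$trans[, s, i])
    }
    ctx <- ((ctx - 1L) %% as.integer(K^(D - 1L))) * K + (M[, i] - 1L) + 1L
  }
  apply(M, 1L, function(v) paste(chain$alphabet[v], collapse = ""))
}

#' Labeled SBG window corpus from two chains
#'
#' @param true_chain,false_chain [sbg_chain()]s sharing `W` and alphabet.
#' @param n_per_class windows per class.
#' @param seed optional seed.
#' @return list with `segments` (character) and `is_true` (logical).
#' @export
generate_sbg_corpus <- function(true_chain, false_chain, n_per_class,
                                seed = NULL) {
  stopifnot(true_chain$W == false_chain$W,
            identical(true_chain$alphabet, false_chain$alphabet))
  if (!is.null(seed)) set.seed(seed)
  segs <- c(sample_chain(true_chain, n_per_class),
            sample_chain(false_chain, n_per_class))
  list(segments = segs,
       is_true = rep(c(TRUE, FALSE), each = n_per_class))
}

#' Convenience chains
#'
#' `constant_chain()` emits one symbol with probability 1 everywhere;
#' `iid_chain()` emits symbols independently from a fixed distribution `p`
#' at every position (its marginals equal `p`);
#' `deterministic_recovery_chain()` builds a chain with deterministic,
#' position- and context-dependent transitions over a two-symbol support,
#' with a pseudo-random preferred-symbol table (fixed by `table_seed`) and a
#' uniform initial distribution over the support contexts. Deterministic
#' rows make parameter-recovery error reflect smoothing bias rather than
#' sampling noise.
#'
#' @param symbol emitted symbol for `constant_chain()`.
#' @param p named probability vector over `alphabet` for `iid_chain()`.
#' @param support two symbols spanning the recovery chain.
#' @param table_seed seed fixing the preferred-symbol table (part of the
#'   chain definition, independent of sampling seeds).
#' @param D,W,alphabet as in [sbg_chain()].
#' @return an [sbg_chain()].
#' @export
constant_chain <- function(symbol = "|", D = 3L, W = 24L,
                           alphabet = SBG_ALPHABET) {
  K <- length(alphabet); nctx <- as.integer(K^D)
  s <- match(symbol, alphabet)
  if (is.na(s)) stop("symbol not in alphabet")
  trans <- array(0, dim = c(K, nctx, W)); trans[s, , ] <- 1
  init <- numeric(nctx)
  id <- 1L + sum((s - 1L) * K^(0:(D - 1L)))
  init[id] <- 1
  sbg_chain(D, W, init, trans, alphabet)
}

#' @rdname constant_chain
#' @export
iid_chain <- function(p, D = 3L, W = 24L, alphabet = SBG_ALPHABET) {
  K <- length(alphabet); nctx <- as.integer(K^D)
  stopifnot(length(p) == K, abs(sum(p) - 1) < 1e-8)
  trans <- array(rep(p, nctx * W), dim = c(K, nctx, W))
  init <- numeric(nctx)
  for (id in seq_len(nctx)) {
    rem <- id - 1L; pr <- 1
    for (k in seq_len(D)) { pr <- pr * p[rem %% K + 1L]; rem <- rem %/% K }
    init[id] <- pr
  }
  sbg_chain(D, W, init, trans, alphabet)
}

#' @rdname constant_chain
#' @export
deterministic_recovery_chain <- function(D = 3L, W = 24L,
                                         support = c("|", "o"),
                                         table_seed = 7L,
                                         alphabet = SBG_ALPHABET) {
  K <- length(alphabet); nctx <- as.integer(K^D)
  sup <- match(support, alphabet)
  stopifnot(length(sup) == 2L, !anyNA(sup))
  # all context ids over the support symbols
  grid <- as.matrix(expand.grid(rep(list(sup), D)))
  sup_ctx <- 1L + as.vector((grid - 1L) %*% K^(0:(D - 1L)))
  trans <- array(0, dim = c(K, nctx, W))
  trans[sup[1], , ] <- 0.5; trans[sup[2], , ] <- 0.5   # unreachable rows
  old <- .Random.seed_safe()
  set.seed(table_seed)
  for (i in (D + 1L):W) for (s in sup_ctx) {
    pref <- sample(sup, 1L)
    trans[, s, i] <- 0; trans[pref, s, i] <- 1
  }
  .Random.seed_restore(old)
  init <- numeric(nctx); init[sup_ctx] <- 1 / length(sup_ctx)
  sbg_chain(D, W, init, trans, alphabet)
}

.Random.seed_safe <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  else rm(".Random.seed", envir = globalenv())
}
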