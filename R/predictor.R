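# End-to-end training and prediction: window extraction, loop->tail scanning,
# combined scoring, first-peak/valley selection, threshold decision, and
# mature-region / strand reporting.

#' Configuration for training and scanning
#'
#' Defaults are the predictor's operating point: order `D = 3`, 24-column
#' windows sliding with step 1 from loop to tail, pseudocount `alpha = 1`,
#' combined score `plus = fom + 50 * feature`, first peak followed by a
#' valley of at least 5 offsets, decision threshold 11 (in nats, tied to the
#' natural-log convention of [sequence_log_prob()]).
#'
#' @param D Markov order (>= 1).
#' @param W window width in columns (> `D`).
#' @param alpha pseudocount (> 0).
#' @param feature_weight weight of the logistic feature score in the
#'   combined score.
#' @param valley_len minimum valley length after a peak (>= 1).
#' @param threshold decision threshold on the combined score ("reached" is
#'   inclusive: `plus >= threshold` is a positive call).
#' @param step sliding step in columns (>= 1).
#' @param seed optional integer seed recorded with the configuration.
#' @return list of class `"fom_config"`.
#' @export
fom_config <- function(D = 3L, W = 24L, alpha = 1, feature_weight = 50,
                       valley_len = 5L, threshold = 11, step = 1L, seed = NULL) {
  stopifnot(D >= 1L, W > D, alpha > 0, valley_len >= 1L, step >= 1L,
            is.numeric(feature_weight), is.numeric(threshold))
  structure(list(D = as.integer(D), W = as.integer(W), alpha = alpha,
                 feature_weight = feature_weight,
                 valley_len = as.integer(valley_len),
                 threshold = threshold, step = as.integer(step), seed = seed),
            class = "fom_config")
}

#' Extract training windows from annotated hairpins
#'
#' Mirrors the asymmetry of the training design: each positive precursor
#' contributes the single `W`-column window that maximizes column overlap
#' with its annotated mature interval(s) (ties broken loop-proximally),
#' labeled `5p`, `3p` or `both` by the arms the annotations occupy; each
#' negative contributes every `W`-column window at the configured step.
#' Hairpins encoding to fewer than `W` columns are skipped with a warning
#' and counted.
#'
#' @param positives list of annotated [hairpin_record()]s.
#' @param negatives list of [hairpin_record()]s (no annotation needed).
#' @param cfg a [fom_config()].
#' @return list with `true_segments`, `strand_labels`, `false_segments`,
#'   `n_skipped_pos`, `n_skipped_neg`.
#' @export
extract_training_windows <- function(positives, negatives, cfg = fom_config()) {
  W <- cfg$W
  true_segments <- character(0); strand_labels <- character(0)
  n_skipped_pos <- 0L
  for (h in positives) {
    if (is.null(h$mature) || !nrow(h$mature))
      stop(sprintf("positive record '%s' has no mature annotation", h$id))
    sbg <- encode_sbg(h)
    C <- sbg_length(sbg)
    if (C < W) {
      warning(sprintf("skipping '%s': %d SBG columns < window %d", h$id, C, W))
      n_skipped_pos <- n_skipped_pos + 1L
      next
    }
    cov <- rep(FALSE, C)
    for (r in seq_len(nrow(h$mature))) {
      map <- if (h$mature$arm[r] == "5p") sbg$five_map else sbg$three_map
      cov <- cov | (!is.na(map) & map >= h$mature$start[r] & map <= h$mature$end[r])
    }
    cs <- cumsum(cov)
    ov <- cs[W:C] - c(0, cs)[1:(C - W + 1L)]
    off <- which.max(ov)                       # first max = loop-proximal
    true_segments <- c(true_segments, substr(sbg$symbols, off, off + W - 1L))
    arms <- sort(unique(h$mature$arm))
    strand_labels <- c(strand_labels,
                       if (length(arms) == 2L) "both" else arms)
  }
  false_segments <- character(0)
  n_skipped_neg <- 0L
  for (h in negatives) {
    sbg <- encode_sbg(h)
    C <- sbg_length(sbg)
    if (C < W) {
      warning(sprintf("skipping '%s': %d SBG columns < window %d", h$id, C, W))
      n_skipped_neg <- n_skipped_neg + 1L
      next
    }
    offs <- seq(1L, C - W + 1L, by = cfg$step)
    false_segments <- c(false_segments,
                        substring(sbg$symbols, offs, offs + W - 1L))
  }
  list(true_segments = true_segments, strand_labels = strand_labels,
       false_segments = false_segments,
       n_skipped_pos = n_skipped_pos, n_skipped_neg = n_skipped_neg)
}

#' Scan a hairpin and build its score profile
#'
#' Slides a `W`-column window from the loop towards the tail, scoring each
#' offset with the true/false log-odds ([fom_score()]). The logistic feature
#' score depends only on the whole molecule, so it is computed once and
#' shifts the entire combined profile: `plus = fom + feature_weight *
#' feature`.
#'
#' @param true_m,false_m trained emission models.
#' @param coeffs [feature_coefficients()].
#' @param h a [hairpin_record()].
#' @param cfg a [fom_config()].
#' @return object of class `"scan_profile"`: `offsets` (start columns,
#'   loop->tail), `fom`, `feature` (scalar), `plus`, and the `sbg` encoding.
#' @export
scan_hairpin <- function(true_m, false_m, coeffs, h, cfg = fom_config()) {
  sbg <- encode_sbg(h)
  C <- sbg_length(sbg)
  if (C < cfg$W)
    stop(sprintf("hairpin '%s' too short: %d SBG columns < window %d",
                 h$id, C, cfg$W))
  feat <- feature_score(compute_mfe_features(h), coeffs)
  offs <- seq(1L, C - cfg$W + 1L, by = cfg$step)
  wins <- substring(sbg$symbols, offs, offs + cfg$W - 1L)
  fom <- vapply(wins, function(w) fom_score(true_m, false_m, w),
                numeric(1), USE.NAMES = FALSE)
  structure(list(hairpin_id = h$id, offsets = offs, fom = fom,
                 feature = feat, plus = fom + cfg$feature_weight * feat,
                 sbg = sbg),
            class = "scan_profile")
}

#' @export
print.scan_profile <- function(x, ...) {
  cat(sprintf("<scan_profile> %s: %d offsets, feature %.4f, plus in [%.2f, %.2f]\n",
              x$hairpin_id, length(x$offsets), x$feature,
              min(x$plus), max(x$plus)))
  invisible(x)
}

#' Select the signal offset from a score profile
#'
#' Scanning loop->tail on the plateau-collapsed profile, a peak is a local
#' maximum followed by at least `valley_len` consecutive offsets with
#' strictly lower scores before any score >= the peak reappears. The first
#' qualifying peak wins; within a plateau the first offset is reported. When
#' no peak qualifies (short or monotone profiles) the global maximum is
#' returned as a fallback, flagged with `from_peak = FALSE`.
#'
#' @param plus numeric score profile (one value per offset, loop->tail).
#' @param valley_len minimum valley length.
#' @return list with `offset_index` (1-based index into the profile) and
#'   `from_peak`.
#' @export
select_peak <- function(plus, valley_len = 5L) {
  stopifnot(is.numeric(plus), length(plus) >= 1L, valley_len >= 1L)
  r <- rle(plus)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  nr <- length(r$values)
  for (q in seq_len(nr)) {
    if (nr == 1L) break
    leftok  <- q == 1L  || r$values[q - 1L] < r$values[q]
    rightok <- q == nr  || r$values[q + 1L] < r$values[q]
    if (!(leftok && rightok)) next
    lower <- 0L; ok <- FALSE
    if (ends[q] < length(plus)) {
      for (t in (ends[q] + 1L):length(plus)) {
        if (plus[t] < r$values[q]) {
          lower <- lower + 1L
          if (lower >= valley_len) { ok <- TRUE; break }
        } else break
      }
    }
    if (ok) return(list(offset_index = starts[q], from_peak = TRUE))
  }
  list(offset_index = which.max(plus), from_peak = FALSE)
}

#' Predict one hairpin
#'
#' Scans the hairpin, selects the signal window with [select_peak()], and
#' calls the record positive when the combined score reaches the threshold
#' (inclusive). For positives, the strand is called on the best window and
#' the mature interval(s) are mapped back to precursor coordinates on the
#' called arm(s).
#'
#' @param model a `"mirfom_model"` from [train_pipeline()] (or an equivalent
#'   list with `true_model`, `false_model`, `strand_model`, `coeffs`,
#'   `config`, `threshold`).
#' @param h a [hairpin_record()].
#' @param threshold decision threshold; defaults to the model's.
#' @return object of class `"mirna_prediction"`.
#' @export
predict_hairpin <- function(model, h, threshold = NULL) {
  cfg <- model$config
  thr <- threshold %||% model$threshold
  prof <- scan_hairpin(model$true_model, model$false_model, model$coeffs, h, cfg)
  pk <- select_peak(prof$plus, cfg$valley_len)
  i <- pk$offset_index
  off <- prof$offsets[i]
  res <- list(hairpin_id = h$id, is_mirna = prof$plus[i] >= thr,
              best_offset = off, fom = prof$fom[i], feature = prof$feature,
              plus = prof$plus[i], from_peak = pk$from_peak,
              threshold = thr, strand = NA_character_,
              strand_scores = NULL, intervals = NULL)
  if (res$is_mirna) {
    win <- substr(prof$sbg$symbols, off, off + cfg$W - 1L)
    sc <- strand_call(model$strand_model, win)
    res$strand <- sc$strand
    res$strand_scores <- sc$scores
    res$intervals <- if (sc$strand == "both") {
      map_window_to_sequence(prof$sbg, off, cfg$W, "both")
    } else {
      stats::setNames(list(map_window_to_sequence(prof$sbg, off, cfg$W, sc$strand)),
                      sc$strand)
    }
  }
  structure(res, class = "mirna_prediction")
}

#' @export
print.mirna_prediction <- function(x, ...) {
  cat(sprintf("<mirna_prediction> %s: %s (plus %.3f vs threshold %.3f)\n",
              x$hairpin_id, if (x$is_mirna) "pre-miRNA" else "not a pre-miRNA",
              x$plus, x$threshold))
  if (x$is_mirna) {
    cat(sprintf("  best window at column %d%s, strand %s\n", x$best_offset,
                if (x$from_peak) "" else " (global-max fallback)", x$strand))
    for (arm in names(x$intervals))
      cat(sprintf("  mature %s: %d-%d\n", arm,
                  x$intervals[[arm]]["start"], x$intervals[[arm]]["end"]))
  }
  invisible(x)
}

#' Predict a batch of hairpins
#'
#' Per-record failures (hairpins too short to scan, degenerate features) are
#' caught and reported as rows with `status = "error"`; the batch continues.
#'
#' @inheritParams predict_hairpin
#' @param records list of [hairpin_record()]s.
#' @return data frame with one row per record and called arm: `id`,
#'   `status`, `message`, `is_mirna`, `fom`, `feature`, `plus`, `offset`,
#'   `strand`, `arm`, `start`, `end`.
#' @export
predict_hairpins <- function(model, records, threshold = NULL) {
  rows <- lapply(records, function(h) {
    p <- tryCatch(predict_hairpin(model, h, threshold), error = identity)
    if (inherits(p, "error"))
      return(data.frame(id = h$id, status = "error",
                        message = conditionMessage(p), is_mirna = NA,
                        fom = NA_real_, feature = NA_real_, plus = NA_real_,
                        offset = NA_integer_, strand = NA_character_,
                        arm = NA_character_, start = NA_integer_,
                        end = NA_integer_, stringsAsFactors = FALSE))
    base <- data.frame(id = p$hairpin_id, status = "ok", message = "",
                       is_mirna = p$is_mirna, fom = p$fom,
                       feature = p$feature, plus = p$plus,
                       offset = p$best_offset, strand = p$strand,
                       arm = NA_character_, start = NA_integer_,
                       end = NA_integer_, stringsAsFactors = FALSE)
    if (!p$is_mirna || is.null(p$intervals)) return(base)
    do.call(rbind, lapply(names(p$intervals), function(arm) {
      row <- base
      row$arm <- arm
      row$start <- p$intervals[[arm]]["start"]
      row$end <- p$intervals[[arm]]["end"]
      row
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Train the full predictor
#'
#' Trains the true, false and strand models from [extract_training_windows()],
#' scans every usable training hairpin for its best combined score, and picks
#' the decision threshold maximizing training accuracy. Candidate cuts are
#' the midpoints between adjacent distinct scores (plus one cut below the
#' minimum and one above the maximum); ties are resolved towards the larger
#' cut, favoring specificity.
#'
#' @inheritParams extract_training_windows
#' @param coeffs [feature_coefficients()] for the logistic feature score.
#' @return object of class `"mirfom_model"`: the three models, coefficients,
#'   configuration, chosen `threshold`, a `train_report` (confusion metrics
#'   at the chosen cut) and the training score vectors.
#' @export
train_pipeline <- function(positives, negatives, cfg = fom_config(),
                           coeffs = feature_coefficients()) {
  if (!length(positives) || !length(negatives))
    stop("both classes must be non-empty")
  tw <- extract_training_windows(positives, negatives, cfg)
  if (!length(tw$true_segments)) stop("no usable positive hairpins")
  if (!length(tw$false_segments)) stop("no usable negative hairpins")
  true_m <- train_fom(tw$true_segments, cfg$D, cfg$W, cfg$alpha)
  false_m <- train_fom(tw$false_segments, cfg$D, cfg$W, cfg$alpha)
  strand_m <- train_strand_model(tw$true_segments, tw$strand_labels,
                                 cfg$D, cfg$W, cfg$alpha)
  best_plus <- function(h) {
    prof <- scan_hairpin(true_m, false_m, coeffs, h, cfg)
    prof$plus[select_peak(prof$plus, cfg$valley_len)$offset_index]
  }
  score_class <- function(records) {
    vapply(records, function(h)
      tryCatch(best_plus(h), error = function(e) NA_real_), numeric(1))
  }
  pos_scores <- score_class(positives)
  neg_scores <- score_class(negatives)
  n_failed <- sum(is.na(pos_scores)) + sum(is.na(neg_scores))
  if (n_failed)
    warning(sprintf("%d training hairpin(s) could not be scored and were excluded",
                    n_failed))
  ps <- pos_scores[!is.na(pos_scores)]; ns <- neg_scores[!is.na(neg_scores)]
  s <- sort(unique(c(ps, ns)))
  cand <- if (length(s) == 1L) s else
    c(s[1L] - 1, (s[-length(s)] + s[-1L]) / 2, s[length(s)] + 1)
  acc <- vapply(cand, function(cut)
    (sum(ps >= cut) + sum(ns < cut)) / (length(ps) + length(ns)), numeric(1))
  thr <- max(cand[acc == max(acc)])
  report <- confusion_metrics(truth = c(rep(TRUE, length(ps)), rep(FALSE, length(ns))),
                              calls = c(ps, ns) >= thr)
  structure(list(true_model = true_m, false_model = false_m,
                 strand_model = strand_m, coeffs = coeffs, config = cfg,
                 threshold = thr, train_report = report,
                 train_scores = list(pos = pos_scores, neg = neg_scores),
                 n_skipped = c(pos = tw$n_skipped_pos, neg = tw$n_skipped_neg)),
            class = "mirfom_model")
}

#' @export
print.mirfom_model <- function(x, ...) {
  cat(sprintf("<mirfom_model> D=%d W=%d alpha=%g, threshold %.3f\n",
              x$config$D, x$config$W, x$config$alpha, x$threshold))
  r <- x$train_report
  cat(sprintf("  training: sen %.3f, spe %.3f, acc %.3f (%d pos, %d neg)\n",
              r$sen, r$spe, r$acc, r$tp + r$fn, r$tn + r$fp))
  invisible(x)
}

#' Save / load a trained predictor
#'
#' Writes the three component models plus configuration, coefficients and
#' threshold into a directory of versioned JSON files.
#'
#' @param model a `"mirfom_model"`.
#' @param dir directory path (created if missing).
#' @export
save_mirfom_model <- function(model, dir) {
  stopifnot(inherits(model, "mirfom_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  save_fom(model$true_model, file.path(dir, "true_model.json"))
  save_fom(model$false_model, file.path(dir, "false_model.json"))
  save_fom(model$strand_model, file.path(dir, "strand_model.json"))
  jsonlite::write_json(
    list(schema_version = 1L,
         config = unclass(model$config), coeffs = unclass(model$coeffs),
         threshold = model$threshold),
    file.path(dir, "predictor.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_mirfom_model
#' @export
load_mirfom_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "predictor.json"),
                              simplifyVector = TRUE)
  if (is.null(meta$schema_version) || meta$schema_version != 1L)
    stop(sprintf("%s: unsupported predictor schema", dir))
  cfg <- do.call(fom_config, meta$config[setdiff(names(meta$config), "seed")])
  structure(list(true_model = load_fom(file.path(dir, "true_model.json")),
                 false_model = load_fom(file.path(dir, "false_model.json")),
                 strand_model = load_fom(file.path(dir, "strand_model.json")),
                 coeffs = do.call(feature_coefficients, as.list(meta$coeffs)),
                 config = cfg, threshold = meta$threshold,
                 train_report = NULL, train_scores = NULL,
                 n_skipped = NULL),
            class = "mirfom_model")
}

#' Write batch predictions
#'
#' `write_predictions()` writes the full table as TSV (1-based inclusive
#' coordinates); `write_mature_bed()` writes the called mature regions in
#' BED format (0-based half-open), one line per called arm.
#'
#' @param pred prediction data frame from [predict_hairpins()].
#' @param path output path.
#' @export
write_predictions <- function(pred, path) {
  utils::write.table(pred, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_predictions
#' @export
write_mature_bed <- function(pred, path) {
  rows <- pred[!is.na(pred$start) & pred$is_mirna %in% TRUE, , drop = FALSE]
  bed <- data.frame(chrom = rows$id, start = rows$start - 1L, end = rows$end,
                    name = paste(rows$id, rows$arm, sep = "_"),
                    score = round(rows$plus, 3), strand = ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
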