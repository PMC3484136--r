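make_models <- function(seed = 50, n = 40) {
  ds <- generate_dataset(n, n, seed = seed)
  list(ds = ds, model = train_pipeline(ds$positives, ds$negatives))
}

test_that("positive training extracts the annotation-covering window", {
  set.seed(51)
  sp <- hairpin_spec(planted = planted_spec(offset = 5, arm = "5p"))
  h <- generate_hairpin(sp, id = "p1")
  tw <- extract_training_windows(list(h), list(generate_hairpin(hairpin_spec(), id = "n1")))
  expect_equal(length(tw$true_segments), 1)
  expect_equal(tw$strand_labels, "5p")
  sbg <- encode_sbg(h)
  expect_equal(tw$true_segments, substr(sbg$symbols, 5, 28))
  # annotations on both arms -> label both
  hb <- generate_hairpin(hairpin_spec(planted = planted_spec(arm = "both")), id = "pb")
  twb <- extract_training_windows(list(hb), list(generate_hairpin(hairpin_spec(), id = "n2")))
  expect_equal(twb$strand_labels, "both")
  # positive without annotation -> error
  bare <- generate_hairpin(hairpin_spec(), id = "nn")
  expect_error(extract_training_windows(list(bare), list(bare)), "no mature annotation")
})

test_that("negatives contribute every window at the configured step", {
  set.seed(52)
  h <- generate_hairpin(hairpin_spec(), id = "n")
  C <- nchar(encode_sbg(h)$symbols)
  sp <- hairpin_spec(planted = planted_spec())
  pos <- generate_hairpin(sp, id = "p")
  tw <- extract_training_windows(list(pos), list(h))
  expect_equal(length(tw$false_segments), C - 24 + 1)
  tw2 <- extract_training_windows(list(pos), list(h), fom_config(step = 2))
  expect_equal(length(tw2$false_segments), length(seq(1, C - 23, by = 2)))
})

test_that("too-short hairpins are skipped with a warning and counted", {
  tiny <- hairpin_record("tiny", "GGGGAAAACCCC", "((((....))))", mfe = -6)
  sp <- hairpin_spec(planted = planted_spec())
  set.seed(53)
  pos <- generate_hairpin(sp, id = "p")
  expect_warning(tw <- extract_training_windows(list(pos), list(tiny)), "too short|columns")
  expect_equal(tw$n_skipped_neg, 1)
  expect_equal(length(tw$false_segments), 0)
})

test_that("scan profiles have the right shape and decompose as fom + weight * feature", {
  mm <- make_models()
  h <- mm$ds$positives[[1]]
  cfg <- fom_config()
  prof <- scan_hairpin(mm$model$true_model, mm$model$false_model,
                       mm$model$coeffs, h, cfg)
  C <- nchar(encode_sbg(h)$symbols)
  expect_equal(length(prof$offsets), C - 23)
  expect_equal(prof$plus, prof$fom + 50 * prof$feature)
  # per-offset fom equals an independent rescoring of each window
  sbg <- encode_sbg(h)
  for (k in seq_along(prof$offsets)) {
    w <- substr(sbg$symbols, prof$offsets[k], prof$offsets[k] + 23)
    expect_equal(prof$fom[k], fom_score(mm$model$true_model, mm$model$false_model, w))
  }
  # identical models: flat profile at 50 * feature
  flat <- scan_hairpin(mm$model$true_model, mm$model$true_model,
                       mm$model$coeffs, h, cfg)
  expect_equal(flat$plus, rep(50 * flat$feature, length(flat$offsets)))
  expect_error(scan_hairpin(mm$model$true_model, mm$model$false_model, mm$model$coeffs,
                            hairpin_record("t", "GGGGAAAACCCC", "((((....))))", -6), cfg),
               "too short")
})

test_that("select_peak applies the first-peak / valley rule", {
  # peak at the second offset, followed by six strictly lower scores
  p <- select_peak(c(1, 3, 2, 2, 2, 2, 2, 1), valley_len = 5)
  expect_equal(p$offset_index, 2)
  expect_true(p$from_peak)
  # strictly increasing: no qualifying peak, global-max fallback = last
  p2 <- select_peak(as.numeric(1:8), valley_len = 5)
  expect_equal(p2$offset_index, 8)
  expect_false(p2$from_peak)
  # flat plateau: fallback to the first offset
  p3 <- select_peak(c(5, 5, 5), valley_len = 5)
  expect_equal(p3$offset_index, 1)
  expect_false(p3$from_peak)
  # an equal value interrupting the valley disqualifies the peak
  p4 <- select_peak(c(9, 8, 8, 9, 1, 1, 1, 1, 1, 1), valley_len = 5)
  expect_equal(p4$offset_index, 4)
  expect_true(p4$from_peak)
})

test_that("select_peak agrees with the literal rule restatement on random profiles", {
  set.seed(54)
  for (rep in 1:200) {
    len <- sample(1:50, 1)
    v <- as.numeric(sample(0:5, len, replace = TRUE))
    vl <- sample(1:6, 1)
    expect_identical(select_peak(v, vl)$offset_index, oracle_peak(v, vl))
  }
})

test_that("the decision threshold is inclusive and monotone", {
  mm <- make_models()
  h <- mm$ds$positives[[1]]
  p0 <- predict_hairpin(mm$model, h)
  # reached-the-threshold boundary: plus == threshold is a positive call
  at <- predict_hairpin(mm$model, h, threshold = p0$plus)
  expect_true(at$is_mirna)
  above <- predict_hairpin(mm$model, h, threshold = p0$plus + 1e-9)
  expect_false(above$is_mirna)
  # raising the threshold never converts a negative into a positive
  thr <- sort(c(p0$plus - 1, p0$plus, p0$plus + 1, p0$plus + 10))
  calls <- vapply(thr, function(t) predict_hairpin(mm$model, h, t)$is_mirna,
                  logical(1))
  expect_true(all(diff(as.integer(calls)) <= 0))
})

test_that("positive calls report mature intervals on the called arm(s)", {
  mm <- make_models(seed = 55)
  hits <- 0
  for (h in mm$ds$positives[1:10]) {
    p <- predict_hairpin(mm$model, h)
    expect_true(p$is_mirna)
    expect_equal(sort(names(p$intervals)),
                 sort(if (p$strand == "both") c("5p", "3p") else p$strand))
    n <- nchar(h$sequence)
    for (iv in p$intervals) {
      expect_gte(iv["start"], 1)
      expect_lte(iv["end"], n)
    }
    if (p$best_offset == attr(h, "planted_offset")) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("batch prediction isolates per-record failures", {
  mm <- make_models(seed = 56, n = 20)
  tiny <- hairpin_record("tiny", "GGGGAAAACCCC", "((((....))))", mfe = -6)
  records <- c(mm$ds$positives[1:3], list(tiny), mm$ds$negatives[1:3])
  pred <- predict_hairpins(mm$model, records)
  expect_equal(sum(pred$status == "error"), 1)
  expect_match(pred$message[pred$status == "error"], "too short")
  expect_equal(length(unique(pred$id)), 7)
  # TSV and BED outputs
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".bed")
  write_predictions(pred, f1)
  back <- utils::read.delim(f1)
  expect_equal(nrow(back), nrow(pred))
  write_mature_bed(pred, f2)
  bed <- utils::read.delim(f2, header = FALSE)
  called <- pred[pred$is_mirna %in% TRUE & !is.na(pred$start), ]
  expect_equal(nrow(bed), nrow(called))
  expect_equal(bed$V2, called$start - 1L)   # 0-based half-open
  expect_equal(bed$V3, called$end)
})

test_that("train_pipeline separates separable classes and reports metrics", {
  mm <- make_models(seed = 57)
  expect_equal(mm$model$train_report$acc, 1)
  expect_gt(min(mm$model$train_scores$pos, na.rm = TRUE), mm$model$threshold)
  expect_lt(max(mm$model$train_scores$neg, na.rm = TRUE), mm$model$threshold)
})

test_that("with one record per class the threshold lies strictly between their scores", {
  set.seed(58)
  pos <- generate_hairpin(hairpin_spec(planted = planted_spec()), id = "p")
  neg <- generate_hairpin(hairpin_spec(), id = "n")
  model <- suppressWarnings(train_pipeline(list(pos), list(neg)))
  s <- sort(c(model$train_scores$pos, model$train_scores$neg))
  expect_true(s[1] < model$threshold && model$threshold < s[2])
})

test_that("swapping class labels swaps sensitivity and specificity", {
  mm <- make_models(seed = 59, n = 15)
  ps <- mm$model$train_scores$pos; ns <- mm$model$train_scores$neg
  thr <- mm$model$threshold
  m1 <- confusion_metrics(c(rep(TRUE, length(ps)), rep(FALSE, length(ns))),
                          c(ps, ns) >= thr)
  m2 <- confusion_metrics(c(rep(FALSE, length(ps)), rep(TRUE, length(ns))),
                          c(ps, ns) < thr)
  expect_equal(m1$sen, m2$spe)
  expect_equal(m1$spe, m2$sen)
})

test_that("a trained predictor round-trips through its model directory", {
  mm <- make_models(seed = 60, n = 15)
  dir <- withr::local_tempdir()
  save_mirfom_model(mm$model, dir)
  back <- load_mirfom_model(dir)
  h <- mm$ds$positives[[1]]
  p1 <- predict_hairpin(mm$model, h)
  p2 <- predict_hairpin(back, h)
  expect_identical(p1$plus, p2$plus)
  expect_identical(p1$strand, p2$strand)
  expect_identical(p1$intervals, p2$intervals)
})
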