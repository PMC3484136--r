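test_that("parse_pairs matches brackets and reports offenders", {
  pt <- parse_pairs("((..))")
  expect_equal(pt$pairs, cbind(i = c(1L, 2L), j = c(6L, 5L)))
  expect_equal(pt$unpaired, c(3L, 4L))
  expect_equal(nrow(parse_pairs("....")$pairs), 0)
  expect_error(parse_pairs("(()"), "position 1")
  expect_error(parse_pairs("())"), "position 3")
})

test_that("select_main_stem keeps the pair-richest root-to-loop path", {
  # single stem: identity
  pt <- parse_pairs("((((....))))")
  expect_equal(select_main_stem(pt)$pairs, pt$pairs)

  # two-armed multiloop: arm A 5 pairs, arm B 3 pairs, 2 closing pairs
  db <- paste0("((", "(((((...)))))", "(((...)))", "))")
  ms <- select_main_stem(parse_pairs(db))
  expect_equal(nrow(ms$pairs), 7)           # 2 closing + 5 from arm A
  expect_equal(length(ms$unpaired), nchar(db) - 14)
  # arm B's 6 paired bases are now unpaired
  expect_true(all(c(16, 17, 18, 22, 23, 24) %in% ms$unpaired))

  # tie: both arms 4 pairs -> keep the 5'-most arm
  db2 <- paste0("((", "((((...))))", "((((...))))", "))")
  ms2 <- select_main_stem(parse_pairs(db2))
  expect_equal(nrow(ms2$pairs), 6)
  expect_true(all(ms2$pairs[, 1] <= 6))     # closing + 5' arm opens

  expect_error(select_main_stem(parse_pairs("....")), "no stem")
})

test_that("select_main_stem agrees with exhaustive path search on small structures", {
  structures <- enumerate_structures(10L, max_pairs = 4L)
  for (db in structures) {
    got <- unname(select_main_stem(parse_pairs(db))$pairs)
    want <- unname(oracle_main_stem(db))
    expect_identical(got, want)
  }
})

test_that("encode_sbg reproduces the hand-derived encodings", {
  h1 <- hairpin_record("h1", "GGGGAAAACCCC", "((((....))))", mfe = -6)
  expect_equal(encode_sbg(h1)$symbols, "oo||||")
  h2 <- hairpin_record("h2", "GAGCAAAAGCUC", "((((....))))", mfe = -5)
  expect_equal(encode_sbg(h2)$symbols, "oo||!|")
  # single 5' bulge base: one '-' column, no 'x'
  h3 <- hairpin_record("h3", "GGGAGAAACCCC", "(((.(...))))", mfe = -4)
  s3 <- encode_sbg(h3)$symbols
  expect_equal(lengths(regmatches(s3, gregexpr("-", s3, fixed = TRUE))), 1)
  expect_equal(lengths(regmatches(s3, gregexpr("x", s3, fixed = TRUE))), 0)
  expect_equal(s3, "oo|-|||")
  # symmetric internal loop: 'x' columns, both maps set
  h4 <- hairpin_record("h4", "GGAGGAAAACCACC", "((.((....)).))", mfe = -4)
  expect_equal(encode_sbg(h4)$symbols, "oo||x||")
  # terminal tail encoded as asymmetric region
  h5 <- hairpin_record("h5", "AAGGGGAAAACCCC", "..((((....))))", mfe = -6)
  expect_equal(encode_sbg(h5)$symbols, "oo||||--")
  expect_equal(encode_sbg(h5, include_tails = FALSE)$symbols, "oo||||")
})

test_that("coordinate maps are ordered and conserve every nucleotide", {
  h <- hairpin_record("h", "GGGGAAAACCCC", "((((....))))", mfe = -6)
  s <- encode_sbg(h)
  expect_equal(s$five_map, 6:1)
  expect_equal(s$three_map, 7:12)
  # odd loop: middle base gets its own column, counted once
  ho <- hairpin_record("ho", "GGGGAAAAACCCC", "((((.....))))", mfe = -6)
  so <- encode_sbg(ho)
  expect_equal(substr(so$symbols, 1, 3), "ooo")
  expect_identical(sort(c(so$five_map, so$three_map)), 1:13)
})

test_that("map_window_to_sequence returns minimal covering intervals", {
  h <- hairpin_record("h", "GGGGAAAACCCC", "((((....))))", mfe = -6)
  s <- encode_sbg(h)
  # the 4 pair columns map to 5' positions 4..1 and 3' positions 9..12
  expect_equal(map_window_to_sequence(s, 3, 4, "5p"), c(start = 1, end = 4))
  expect_equal(map_window_to_sequence(s, 3, 4, "3p"), c(start = 9, end = 12))
  # full window also covers the loop share
  expect_equal(map_window_to_sequence(s, 1, 6, "5p"), c(start = 1, end = 6))
  both <- map_window_to_sequence(s, 3, 4, "both")
  expect_equal(both[["5p"]], c(start = 1, end = 4))
  expect_equal(both[["3p"]], c(start = 9, end = 12))
  expect_error(map_window_to_sequence(s, 1, 0, "5p"), "width")
  expect_error(map_window_to_sequence(s, 5, 9, "5p"), "outside")
  # a 5'-tail '-' column has no base on the 3' arm
  h5 <- hairpin_record("h5", "AAGGGGAAAACCCC", "..((((....))))", mfe = -6)
  s5 <- encode_sbg(h5)
  expect_equal(map_window_to_sequence(s5, 7, 2, "5p"), c(start = 1, end = 2))
  expect_error(map_window_to_sequence(s5, 7, 2, "3p"), "no mapped position")
})

test_that("encoding invariants hold over random fixtures", {
  set.seed(20)
  for (rep in 1:30) {
    h <- generate_hairpin(hairpin_spec(bulge_rate = 0.15), id = "p")
    s <- encode_sbg(h)
    n <- nchar(h$sequence)
    # conservation: every base in exactly one column map
    expect_identical(sort(c(s$five_map, s$three_map)), seq_len(n))
    # maps diverge from the loop
    expect_true(all(diff(s$five_map[!is.na(s$five_map)]) < 0))
    expect_true(all(diff(s$three_map[!is.na(s$three_map)]) > 0))
    # per-symbol map arity
    sy <- strsplit(s$symbols, "")[[1]]
    has5 <- !is.na(s$five_map); has3 <- !is.na(s$three_map)
    expect_true(all(has5[sy %in% c("|", "!", ":", "x")]))
    expect_true(all(has3[sy %in% c("|", "!", ":", "x")]))
    expect_true(all(xor(has5[sy == "-"], has3[sy == "-"])))
    expect_true(all(has5[sy == "o"] | has3[sy == "o"]))
    # column-count identity
    pt <- select_main_stem(parse_pairs(h$dotbracket))
    P <- pt$pairs[order(pt$pairs[, 1], decreasing = TRUE), , drop = FALSE]
    L <- P[1, 2] - P[1, 1] - 1
    regions <- 0
    if (nrow(P) > 1)
      for (t in 1:(nrow(P) - 1))
        regions <- regions + max(P[t, 1] - P[t + 1, 1] - 1,
                                 P[t + 1, 2] - P[t, 2] - 1)
    m <- nrow(P)
    tails <- max(P[m, 1] - 1, n - P[m, 2])
    expect_equal(nchar(s$symbols),
                 unname(m + ceiling(L / 2) + regions + tails))
    # determinism
    expect_identical(encode_sbg(h)$symbols, s$symbols)
  }
})

test_that("perfect hairpins encode as loop columns then pair columns", {
  set.seed(21)
  for (rep in 1:10) {
    h <- generate_hairpin(hairpin_spec(bulge_rate = 0), id = "p")
    expect_match(encode_sbg(h)$symbols, "^o+[|!:]+$")
  }
})

test_that("non-canonical main-stem pairs are a validation error", {
  h <- hairpin_record("h", "GAGGAAAACCAC", "((((....))))", mfe = -4)
  expect_error(encode_sbg(h), "not a CG/AU/GU")
})
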