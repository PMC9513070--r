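# Direct-repeat detection: planted-duplication recovery, brute-force
# equivalence, significance filtering, and delimitation conventions.

test_that("a planted 93-nt duplication is recovered exactly", {
  fx <- plant_repeat_fixture(tsd = 93, seed = 41)
  reps <- find_flanking_repeats(fx$seq, fx$anchor, search_radius = 5000)
  top <- reps[1, ]
  expect_equal(top$length, 93)
  expect_equal(top$mismatches, 0)
  expect_equal(c(top$left_start0, top$left_end0), fx$left)
  expect_equal(c(top$right_start0, top$right_end0), fx$right)
  expect_identical(top$seq_left, top$seq_right)
})

test_that("anchor outside the sequence is rejected", {
  fx <- plant_repeat_fixture(seed = 42)
  expect_error(find_flanking_repeats(fx$seq, c(-5, 100), 1000), "anchor")
  expect_error(find_flanking_repeats(fx$seq, c(100, nchar(fx$seq) + 10),
                                     1000), "anchor")
  expect_error(find_flanking_repeats(fx$seq, c(5000, 6000), 0), "radius")
})

test_that("seed-and-extend equals brute-force enumeration on small windows", {
  skip_on_cran()
  n_agree <- 0
  for (seed in 1:100) {
    set.seed(seed)
    W <- 150 + (seed %% 4) * 50
    tsd <- 12 + (seed %% 40)
    Lw0 <- random_dna_str(W); Rw0 <- random_dna_str(W)
    # plant an exact pair at varying offsets
    rep_seq <- random_dna_str(tsd)
    pl <- 1 + (seed * 13) %% (W - tsd)
    pr <- 1 + (seed * 29) %% (W - tsd)
    Lw <- paste0(substr(Lw0, 1, pl - 1), rep_seq,
                 substr(Lw0, pl + tsd, W))
    Rw <- paste0(substr(Rw0, 1, pr - 1), rep_seq,
                 substr(Rw0, pr + tsd, W))
    got <- icecensus:::.scan_window_pair(Lw, Rw, min_len = 12, rate = 0,
                                         seed_k = 8, pen = 3)
    want <- brute_force_repeats(Lw, Rw, min_len = 12, rate = 0, pen = 3)
    got <- got[order(got$left_start0, got$right_start0), , drop = FALSE]
    want <- want[order(want$left_start0, want$right_start0), , drop = FALSE]
    agree <- nrow(got) == nrow(want) &&
      all(got$left_start0 == want$left_start0) &&
      all(got$right_start0 == want$right_start0) &&
      all(got$length == want$length)
    expect_true(agree, label = sprintf("seed %d equivalence", seed))
    n_agree <- n_agree + agree
  }
  expect_equal(n_agree, 100)
})

test_that("raising min_len never adds repeats", {
  for (seed in 43:47) {
    fx <- plant_repeat_fixture(tsd = 30, seed = seed)
    r10 <- find_flanking_repeats(fx$seq, fx$anchor, 4000, min_len = 10)
    r20 <- find_flanking_repeats(fx$seq, fx$anchor, 4000, min_len = 20)
    expect_lte(nrow(r20), nrow(r10))
    key <- function(r) paste(r$left_start0, r$right_start0, r$length)
    expect_true(all(key(r20) %in% key(r10)))
  }
})

test_that("significance filter empties random windows and spares anchors", {
  # seeded random windows with no planted repeat: nothing significant
  for (seed in 1:20) {
    set.seed(seed * 7)
    seq <- random_dna_str(12000)
    reps <- find_flanking_repeats(seq, c(5000, 7000), search_radius = 2500,
                                  min_len = 10)
    reps <- filter_repeats(reps, features = NULL, alpha = 1e-3)
    expect_equal(nrow(reps), 0,
                 label = sprintf("seed %d random window", seed * 7))
  }
  # a short (sub-significance) repeat survives only with tRNA anchoring
  fx <- plant_repeat_fixture(tsd = 10, body = 4000, seed = 48)
  reps <- find_flanking_repeats(fx$seq, fx$anchor, 3000, min_len = 10)
  feats_no <- feature_row("x", "CDS", 10, 100, "+", "p")
  kept_no <- filter_repeats(reps, feats_no, alpha = 1e-3)
  expect_false(any(kept_no$left_start0 == fx$left[1] &
                     kept_no$length == 10))
  feats_yes <- feature_row("t", "tRNA", fx$left[2] - 76, fx$left[2], "+",
                           "tRNA-Arg")
  kept_yes <- filter_repeats(reps, feats_yes, alpha = 1e-3)
  hit <- kept_yes[kept_yes$left_start0 == fx$left[1] &
                    kept_yes$length == 10, ]
  expect_equal(nrow(hit), 1)
  expect_true(hit$att_anchored)
})

test_that("delimitation conventions differ by exactly the repeat lengths", {
  fx <- plant_repeat_fixture(tsd = 40, seed = 49)
  reps <- find_flanking_repeats(fx$seq, fx$anchor, 5000)
  top <- reps[1, ]
  b_one <- delineate_element(fx$anchor, top, "include_one_repeat")
  b_ex <- delineate_element(fx$anchor, top, "exclude_repeats")
  b_both <- delineate_element(fx$anchor, top, "include_both")
  expect_equal(b_both$span - b_ex$span, 2 * top$length)
  expect_equal(b_one$span - b_ex$span, top$length)
  expect_true(b_one$bounds[1] <= fx$anchor[1] &&
                b_one$bounds[2] >= fx$anchor[2])
  # a repeat that does not flank the anchor is rejected
  bad <- top; bad$left_end0 <- fx$anchor[1] + 600
  expect_error(delineate_element(fx$anchor, bad), "flank")
})

test_that("excising default bounds restores the pre-insertion site", {
  run <- mini_run(2)
  pop <- run$pop; res <- run$res
  el <- res$elements[!is.na(res$elements$start0), , drop = FALSE]
  expect_gt(nrow(el), 0)
  for (i in seq_len(nrow(el))) {
    e <- el[i, ]
    tr <- pop$truth[pop$truth$start0 == e$start0 &
                      pop$truth$strain == e$strain, , drop = FALSE]
    expect_equal(nrow(tr), 1)
    expect_equal(e$end0, tr$end0)
  }
})
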