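# Synthetic population generator: element specs, planting mechanics,
# identity-targeted mutation, decay, and truth-table guarantees.

test_that("element specs enforce class/role consistency", {
  expect_s3_class(element_spec("a", "AICE", c("integrase_tyr", "rep", "traB"),
                               20, "tRNA", "tRNA-Leu", "s1", "f01"),
                  "ElementSpec")
  expect_error(element_spec("a", "AICE", c("rep", "traB"), 20, "tRNA",
                            "tRNA-Leu", "s1"), "inconsistent")
  expect_error(element_spec("a", "ICE", c("integrase_tyr", "relaxase"),
                            20, "tRNA", "x", "s1"), "inconsistent")
  expect_error(element_spec("a", "IME",
                            c("relaxase", "coupling", "virb4"),
                            20, "tRNA", "x", "s1"), "inconsistent")
  expect_error(element_spec("a", "AICE", c("integrase_tyr", "rep", "traB"),
                            1, "tRNA", "x", "s1"))
})

test_that("decay re-derives the element class from surviving roles", {
  a <- element_spec("a", "AICE", c("integrase_tyr", "rep", "traB"), 20,
                    "tRNA", "tRNA-Leu", "s1", "f01")
  expect_equal(decay_element(a, "rep")$element_class, "DAICE")
  ice <- element_spec("i", "ICE",
                      c("integrase_tyr", "relaxase", "coupling", "virb4"),
                      93, "tRNA", "tRNA-Thr", "s1")
  expect_equal(decay_element(ice, "integrase_tyr")$element_class, "DICE")
  expect_equal(decay_element(a, c("traB", "rep", "integrase_tyr"))$element_class,
               "remnant")
  # truncated integrase counts as non-functional
  expect_equal(decay_element(a, "rep", truncate_fraction = 0.3)$element_class,
               "DAICE")
  expect_error(decay_element(a, "virb4"), "subset")
})

test_that("mutate_to_identity hits the target identity band", {
  set.seed(11)
  s <- random_dna_str(1)  # warm rng
  p <- paste(sample(c("A","C","D","E","F","G","H","I","K","L","M","N",
                      "P","Q","R","S","T","V","W","Y"), 400, TRUE),
             collapse = "")
  expect_identical(mutate_to_identity(p, 100), p)
  m95 <- mutate_to_identity(p, 95, seed = 5)
  id95 <- global_identity(p, m95)
  expect_true(abs(id95 - 95) <= 0.5)
  # direct position count for the substitution-only case
  a <- strsplit(p, "")[[1]]; b <- strsplit(m95, "")[[1]]
  expect_true(sum(a == b) >= 377 && sum(a == b) <= 383)
  m39 <- mutate_to_identity(substr(p, 1, 300), 39, seed = 6)
  expect_true(abs(global_identity(substr(p, 1, 300), m39) - 39) <= 0.5)
  expect_error(mutate_to_identity("MKLVMKLVMKLV", 90), "20 aa")
})

test_that("plant_element duplicates the target site as flanking repeats", {
  set.seed(21)
  bg <- random_dna_str(30000)
  feats <- feature_row("t1", "tRNA", 14924, 15000, "+", "tRNA-Thr")
  g <- genome_record("s1", "chr", bg, feats, character(0))
  for (tsd in c(93L, 2L)) {
    spec <- element_spec("ice01", "ICE",
                         c("integrase_tyr", "relaxase", "coupling", "virb4"),
                         tsd, "tRNA", "tRNA-Thr", "s1",
                         cargo = cargo_spec(5, 1))
    out <- plant_element(g, spec, 15000)
    tr <- out$truth
    seq2 <- out$record$seq
    left <- substr(seq2, tr$tsd_left_start0 + 1, tr$tsd_left_start0 + tsd)
    right <- substr(seq2, tr$tsd_right_start0 + 1, tr$tsd_right_start0 + tsd)
    expect_identical(left, right)
    expect_identical(left, substr(bg, 15000 - tsd + 1, 15000))
    expect_equal(nchar(left), tsd)
    # insertion inverse: the bounds interior equals the inserted element
    body <- substr(seq2, tr$tsd_left_start0 + tsd + 1, tr$end0)
    expect_identical(body, out$element_seq)
    # excision of the bounds restores the pre-insertion sequence
    excised <- paste0(substr(seq2, 1, tr$start0),
                      substr(seq2, tr$end0 + 1, nchar(seq2)))
    expect_identical(excised, bg)
    # downstream feature coordinates are only shifted, never lost
    expect_true(all(c("t1") %in% out$record$features$id))
  }
  # planting inside an existing element is rejected
  spec <- element_spec("a1", "AICE", c("integrase_tyr", "rep", "traB"),
                       20, "tRNA", "tRNA-Thr", "s1", "f01",
                       cargo = cargo_spec(5, 2))
  out <- plant_element(g, spec, 15000)
  expect_error(plant_element(out$record, spec, 16000), "existing planted")
})

test_that("composition is seed-invariant and sequences are not", {
  bp1 <- random_blueprint(2, seed = 101)
  bp2 <- random_blueprint(2, seed = 202)
  p1 <- generate_population(bp1)
  p2 <- generate_population(bp2)
  expect_identical(table(p1$truth$class), table(p2$truth$class))
  expect_identical(p1$truth$site_name, p2$truth$site_name)
  expect_false(identical(p1$genomes[[1]]$seq, p2$genomes[[1]]$seq))
  # identical seed => byte-identical output
  p1b <- generate_population(random_blueprint(2, seed = 101))
  expect_identical(p1$genomes[[1]]$seq, p1b$genomes[[1]]$seq)
  expect_identical(p1$truth, p1b$truth)
})

test_that("truth records verify against the emitted sequences and round-trip", {
  run <- mini_run(3)
  pop <- run$pop
  for (i in seq_len(nrow(pop$truth))) {
    tr <- pop$truth[i, ]
    g <- pop$genomes[[paste0(tr$strain, "/", tr$replicon)]]
    if (tr$tsd_len > 0) {
      left <- substr(g$seq, tr$tsd_left_start0 + 1,
                     tr$tsd_left_start0 + tr$tsd_len)
      right <- substr(g$seq, tr$tsd_right_start0 + 1,
                      tr$tsd_right_start0 + tr$tsd_len)
      expect_identical(left, right)
      expect_identical(left, tr$tsd_seq)
    }
    ids <- c(unlist(lapply(strsplit(tr$roles, ";")[[1]], function(x)
      strsplit(x, "=")[[1]][2])),
      strsplit(tr$cargo_ids, ",")[[1]])
    ids <- ids[nzchar(ids)]
    f <- g$features[g$features$id %in% ids, , drop = FALSE]
    expect_equal(nrow(f), length(ids))
    expect_true(all(f$start0 >= tr$start0 & f$end0 <= tr$end0))
  }
  tf <- tempfile(fileext = ".tsv")
  write_truth_table(pop$truth, tf)
  rt <- read_truth_table(tf)
  expect_equal(rt, pop$truth, tolerance = 0)
})

test_that("empty blueprints yield background-only genomes", {
  bp <- random_blueprint(1, seed = 7, chromosome_length = 80000L)
  bp$instances <- bp$instances[0, , drop = FALSE]
  pop <- generate_population(bp)
  expect_equal(nrow(pop$truth), 0)
  expect_true(all(vapply(pop$genomes, function(g) nchar(g$seq), 0) == 80000))
})
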