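# Cargo extraction, pseudogene statistics and functional categorisation.

test_that("pseudogene statistics count the sub-threshold fraction", {
  cargo <- data.frame(protein_length = c(rep(100L, 223), rep(200L, 222)))
  ps <- pseudogene_stats(cargo, 150, background_fraction = 0.07)
  expect_equal(ps$n_cargo, 445)
  expect_equal(ps$n_short, 223)
  expect_equal(round(ps$fraction_short, 3), 0.501)
  expect_equal(ps$ratio, ps$fraction_short / 0.07)
  # invariance to row order
  ps2 <- pseudogene_stats(cargo[sample(nrow(cargo)), , drop = FALSE], 150)
  expect_equal(ps2$n_short, ps$n_short)
  # all long
  expect_equal(pseudogene_stats(data.frame(protein_length = c(200L, 300L)),
                                150)$fraction_short, 0)
  # empty set flagged undefined
  e <- pseudogene_stats(data.frame(protein_length = integer(0)), 150)
  expect_true(e$undefined)
  expect_true(is.na(e$fraction_short))
  expect_error(pseudogene_stats(cargo, 0))
})

test_that("signature-only elements yield empty cargo", {
  set.seed(71)
  feats <- rbind(feature_row("g1", "CDS", 100, 1300, "+",
                             "site-specific tyrosine recombinase (integrase)"),
                 feature_row("g2", "CDS", 1500, 2600, "+",
                             "conjugal transfer protein TraB"))
  prots <- stats::setNames(c(random_protein(399), random_protein(366)),
                           c("g1", "g2"))
  el <- data.frame(element_id = "e1", start0 = 0L, end0 = 3000L)
  out <- extract_cargo(el, feats, prots, signature_ids = c("g1", "g2"))
  expect_equal(nrow(out), 0)
  # a cargo gene inside the bounds is kept; outside is not
  feats2 <- rbind(feats,
                  feature_row("g3", "CDS", 2700, 2950, "+", "hypothetical protein"),
                  feature_row("g4", "CDS", 3100, 3400, "+", "hypothetical protein"))
  prots2 <- c(prots, stats::setNames(c(random_protein(82), random_protein(99)),
                                     c("g3", "g4")))
  out2 <- extract_cargo(el, feats2, prots2, signature_ids = c("g1", "g2"))
  expect_equal(out2$gene_id, "g3")
  expect_true(out2$is_short)
})

test_that("deduplication collapses identical proteins across elements", {
  set.seed(72)
  p <- random_protein(200)
  prots <- stats::setNames(c(p, p, random_protein(200)),
                           c("a1", "a2", "b1"))
  cargo <- data.frame(gene_id = c("a1", "a2", "b1"),
                      element_id = c("e1", "e2", "e2"),
                      protein_length = 200L, product = "hypothetical protein",
                      is_short = FALSE, stringsAsFactors = FALSE)
  dd <- dedup_cargo(cargo, prots)
  expect_equal(nrow(dd), 2)
  expect_setequal(dd$gene_id, c("a1", "b1"))
})

test_that("keyword categorisation follows the priority rules", {
  cargo <- data.frame(
    gene_id = paste0("g", 1:5), element_id = "e",
    protein_length = c(300L, 250L, 200L, 100L, 180L),
    product = c("aminoglycoside phosphotransferase",
                "DNA repair protein RadA",
                "completely novel protein of unknown function",
                "phage portal protein",            # short: filtered out
                "type II restriction endonuclease"),
    is_short = c(FALSE, FALSE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  res <- categorize_cargo(cargo)
  expect_equal(res$cargo$category[res$cargo$gene_id == "g1"], "resistance")
  expect_equal(res$cargo$category[res$cargo$gene_id == "g2"], "DNA metabolism")
  expect_equal(res$cargo$category[res$cargo$gene_id == "g3"], "hypothetical")
  expect_equal(res$cargo$category[res$cargo$gene_id == "g5"], "phage")
  # counts conserve the length-filtered cargo set
  expect_equal(sum(res$counts), nrow(res$cargo))
  expect_false("g4" %in% res$cargo$gene_id)
  # unknown category in the map is rejected
  bad <- data.frame(pattern = "x", category = "nonsense")
  expect_error(categorize_cargo(cargo, bad), "unknown category")
})

test_that("generator cargo pools round-trip through extraction", {
  run <- mini_run(4)
  pop <- run$pop; res <- run$res
  proteome <- do.call(c, unname(lapply(pop$genomes, `[[`, "proteins")))
  for (cls in c("AICE", "IME")) {
    tr <- pop$truth[pop$truth$class == cls, , drop = FALSE]
    if (!nrow(tr)) next
    truth_ids <- unlist(strsplit(tr$cargo_ids, ","))
    got <- res$cargo[res$cargo$element_class == cls, , drop = FALSE]
    expect_setequal(got$gene_id, truth_ids)
    # short fraction matches the blueprint pool exactly
    truth_short <- sum(nchar(proteome[truth_ids]) < 150)
    expect_equal(sum(got$is_short), truth_short)
  }
})
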