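# Candidate grouping, the classification rule table, extrachromosomal
# filtering and insertion-site assignment.

test_that("classification rule table is exhaustively correct", {
  roles6 <- c("integrase_tyr", "relaxase", "coupling", "virb4", "traB", "rep")
  for (mask in 0:63) {
    r <- roles6[as.logical(intToBits(mask)[1:6])]
    got <- classify_from_roles(r, repeat_present = TRUE,
                               int_functional = TRUE)
    # expected class spelled out independently from the module rules
    has_int <- "integrase_tyr" %in% r
    expected <-
      if ("traB" %in% r && "virb4" %in% r) "ambiguous"
      else if ("traB" %in% r) {
        if ("rep" %in% r && has_int) "AICE" else "DAICE"
      } else if ("virb4" %in% r) {
        if (has_int && "relaxase" %in% r && "coupling" %in% r) "ICE"
        else "DICE"
      } else if ("relaxase" %in% r) "IME"
      else "remnant"
    expect_identical(got, expected,
                     label = paste("roles:", paste(r, collapse = "+")))
  }
  # serine integrase is equivalent to tyrosine integrase
  expect_identical(classify_from_roles(c("integrase_ser", "relaxase",
                                         "coupling")), "IME")
  # canonical class examples
  expect_identical(classify_from_roles(c("integrase_tyr", "relaxase",
                                         "coupling", "virb4")), "ICE")
  expect_identical(classify_from_roles(c("traB", "integrase_tyr")), "DAICE")
  # interrupted integrase downgrades AICE to DAICE
  expect_identical(classify_from_roles(c("traB", "rep", "integrase_tyr"),
                                       int_functional = FALSE), "DAICE")
  # no transfer role, no repeat
  expect_identical(classify_from_roles("integrase_tyr",
                                       repeat_present = FALSE),
                   "unclassified")
})

make_hits <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(protein_id = r[[1]], replicon = "s/chr",
               start0 = as.integer(r[[2]]), end0 = as.integer(r[[2]]) + 1000L,
               strand = "+", role = r[[3]], score = 100, method = "profile",
               query_coverage = 1, flags = "", stringsAsFactors = FALSE)))
}

test_that("hits chain into candidates and split at transfer terminators", {
  h <- make_hits(list("a", 1000, "integrase_tyr"),
                 list("b", 8000, "relaxase"),
                 list("c", 15000, "virb4"))
  cands <- group_hits(h)
  expect_length(cands, 1)
  expect_setequal(cands[[1]]$roles_present,
                  c("integrase_tyr", "relaxase", "virb4"))
  # traB 200 kb from virb4: two candidates
  h2 <- make_hits(list("a", 1000, "traB"), list("b", 201000, "virb4"))
  expect_length(group_hits(h2), 2)
  # tandem AICEs: each traB closes its own candidate
  h3 <- make_hits(list("i1", 1000, "integrase_tyr"),
                  list("t1", 12000, "traB"),
                  list("i2", 14000, "integrase_tyr"),
                  list("t2", 26000, "traB"))
  cands3 <- group_hits(h3)
  expect_length(cands3, 3 - 1)
  expect_setequal(cands3[[1]]$hits$protein_id, c("i1", "t1"))
  expect_setequal(cands3[[2]]$hits$protein_id, c("i2", "t2"))
  # an IME ends at a coupling protein not followed by virb4
  h4 <- make_hits(list("i", 1000, "integrase_ser"),
                  list("r", 9000, "relaxase"),
                  list("c", 11000, "coupling"),
                  list("x", 30000, "integrase_tyr"),
                  list("t", 40000, "traB"))
  cands4 <- group_hits(h4)
  expect_length(cands4, 2)
  expect_setequal(cands4[[1]]$hits$protein_id, c("i", "r", "c"))
})

test_that("extrachromosomal traB without repeats is discarded", {
  set.seed(51)
  gs <- list(
    genome_record("s1", "chr", random_dna_str(1000), feature_row("x", "CDS", 1, 100),
                  stats::setNames("M", "x"), role = "chromosome"),
    genome_record("s1", "p1", random_dna_str(1000), feature_row("y", "CDS", 1, 100),
                  stats::setNames("M", "y"), role = "plasmid"))
  el <- data.frame(
    element_id = c("e1", "e2", "e3"), strain = "s1",
    replicon = c("chr", "p1", "p1"),
    element_class = c("AICE", "DAICE", "ICE"),
    repeat_length = c(30L, NA, NA),
    roles_present = c("integrase_tyr,rep,traB", "traB",
                      "coupling,integrase_tyr,relaxase,virb4"),
    flags = "", stringsAsFactors = FALSE)
  fl <- filter_extrachromosomal(el, gs)
  expect_equal(fl$kept$element_id, c("e1", "e3"))
  expect_equal(fl$discarded$element_id, "e2")
  expect_match(fl$discarded$flags, "plasmid_borne")
  # the kept plasmid ICE is flagged but not discarded
  expect_match(fl$kept$flags[fl$kept$element_id == "e3"], "plasmid_borne")
  expect_equal(nrow(fl$kept) + nrow(fl$discarded), nrow(el))
})

test_that("insertion sites follow the tRNA > CDS > intergenic hierarchy", {
  feats <- rbind(feature_row("t", "tRNA", 1000, 1076, "+", "tRNA-Thr"),
                 feature_row("c", "CDS", 5000, 6200, "+", "rlmN 23S rRNA methyltransferase"),
                 feature_row("b", "CDS", 9000, 9900, "+", "hypothetical protein"))
  el <- function(l0, l1) data.frame(rep_left_start0 = l0, rep_left_end0 = l1,
                                    rep_right_start0 = 20000,
                                    rep_right_end0 = 20000 + (l1 - l0))
  s1 <- assign_insertion_site(el(1030, 1070), feats)
  expect_equal(s1$kind, "tRNA"); expect_equal(s1$name, "tRNA-Thr")
  s2 <- assign_insertion_site(el(5500, 5540), feats)
  expect_equal(s2$kind, "CDS"); expect_match(s2$name, "rlmN")
  s3 <- assign_insertion_site(el(3000, 3040), feats)
  expect_equal(s3$kind, "intergenic"); expect_equal(s3$name, "-")
  # accretion: outermost left copy carries the site identity
  s4 <- assign_insertion_site(el(3000, 3040), feats,
                              outer_left = c(1030, 1070))
  expect_equal(s4$kind, "tRNA")
})
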