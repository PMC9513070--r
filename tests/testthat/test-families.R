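# Global identity, single-linkage family clustering and neighbor joining.

test_that("global identity matches hand-computed alignments", {
  expect_equal(global_identity("MKLV", "MKIV"), 75)
  expect_equal(global_identity("MKLVAE", "MKLVAE"), 100)
  expect_error(global_identity("", "MK"), "non-empty")
  # cross-check against the Biostrings aligner on mutated pairs
  set.seed(61)
  for (idt in c(90, 70, 50)) {
    a <- random_protein(200)
    b <- mutate_to_identity(a, idt)
    pa <- Biostrings::pairwiseAlignment(a, b,
                                        substitutionMatrix = "BLOSUM62",
                                        gapOpening = 10, gapExtension = 1,
                                        type = "global")
    # co-optimal alignments may differ in tie-breaking; identities agree
    # to within a fraction of a percent
    ref <- Biostrings::nmatch(pa) / Biostrings::nchar(pa) * 100
    expect_lt(abs(global_identity(a, b) - ref), 0.6)
  }
})

test_that("identity matrices are symmetric with unit diagonal", {
  set.seed(62)
  seqs <- stats::setNames(vapply(1:5, function(i) random_protein(80), ""),
                          paste0("s", 1:5))
  m <- identity_matrix(seqs)
  expect_equal(unname(diag(m)), rep(100, 5))
  expect_lt(max(abs(m - t(m))), 1e-9)
  expect_true(all(m >= 0 & m <= 100))
})

test_that("single-linkage clustering recovers a 19-block identity structure", {
  set.seed(63)
  base <- vapply(1:19, function(i) random_protein(300 + 10 * i), "")
  sizes <- c(4, 5, 3, 4, 6, 1, 3, 3, 1, 1, 5, 1, 3, 4, 1, 2, 2, 1, 1)
  seqs <- character(0)
  for (f in 1:19) {
    for (k in seq_len(sizes[f])) {
      s <- icecensus:::.mutate_npos(base[f],
                                    max(1, round(nchar(base[f]) * 0.01)))
      seqs[sprintf("f%02d_%d", f, k)] <- s
    }
  }
  m <- identity_matrix(seqs)
  fam <- cluster_families(m, threshold = 95)
  expect_equal(length(unique(fam$family_id)), 19)
  expect_equal(sum(tapply(fam$id, fam$family_id, length) == 1), 7)
  # members of one planted block share one family id
  for (f in sprintf("f%02d", 1:19)) {
    ids <- fam$family_id[startsWith(fam$id, f)]
    expect_equal(length(unique(ids)), 1)
  }
  # family count is non-increasing in threshold
  counts <- vapply(c(0, 50, 90, 95, 99.9),
                   function(th) length(unique(cluster_families(m, th)$family_id)),
                   0)
  expect_true(all(diff(counts) >= 0))
  expect_equal(counts[1], 1)   # threshold 0: one family
  # input-order invariance
  perm <- sample(length(seqs))
  fam2 <- cluster_families(m[perm, perm], threshold = 95)
  key1 <- split(fam$id, fam$family_id)
  key2 <- split(fam2$id, fam2$family_id)
  expect_setequal(
    unname(vapply(key1, function(x) paste(sort(x), collapse = "+"), "")),
    unname(vapply(key2, function(x) paste(sort(x), collapse = "+"), "")))
})

test_that("neighbor joining recovers additive trees exactly", {
  expect_error(nj_newick(matrix(0, 2, 2)), "3 taxa")
  # 4-taxon additive matrix built by hand from ((A:1,B:2):1,(C:3,D:1));
  d <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                       c("A", "B", "C", "D")))
  d["A", "B"] <- d["B", "A"] <- 3
  d["A", "C"] <- d["C", "A"] <- 5
  d["A", "D"] <- d["D", "A"] <- 3
  d["B", "C"] <- d["C", "B"] <- 6
  d["B", "D"] <- d["D", "B"] <- 4
  d["C", "D"] <- d["D", "C"] <- 4
  tr <- ape::read.tree(text = nj_newick(d))
  want <- ape::read.tree(text = "((A:1,B:2):1,C:3,D:1);")
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(want)), 0,
               ignore_attr = TRUE)
  got_d <- ape::cophenetic.phylo(tr)[c("A","B","C","D"), c("A","B","C","D")]
  expect_equal(unname(got_d), unname(d), tolerance = 1e-8)
})

test_that("neighbor joining matches the reference implementation on random trees", {
  skip_on_cran()
  set.seed(64)
  for (i in 1:50) {
    nt <- sample(4:12, 1)
    tr0 <- ape::rtree(nt, rooted = FALSE)
    d <- ape::cophenetic.phylo(tr0)
    mine <- ape::read.tree(text = nj_newick(d))
    expect_equal(ape::dist.topo(ape::unroot(mine), ape::unroot(tr0)), 0,
                 ignore_attr = TRUE, label = sprintf("tree %d topology", i))
  }
})

test_that("tree topology is invariant to taxon input order", {
  set.seed(65)
  tr0 <- ape::rtree(8, rooted = FALSE)
  d <- ape::cophenetic.phylo(tr0)
  t1 <- ape::read.tree(text = nj_newick(d))
  perm <- sample(8)
  t2 <- ape::read.tree(text = nj_newick(d[perm, perm]))
  expect_equal(ape::dist.topo(ape::unroot(t1), ape::unroot(t2)), 0,
               ignore_attr = TRUE)
})
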