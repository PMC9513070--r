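# Signature screening: profile construction, proteome scanning, similarity
# search, and HMMER domain-table import.

test_that("profile log-odds are positive at consensus columns", {
  s <- random_protein(120)
  prof <- build_profile(c(s, s), "traB")
  a <- strsplit(s, "")[[1]]
  for (j in seq(1, 120, by = 7))
    expect_gt(prof$scores[j, a[j]], 0)
  expect_error(build_profile(s, "traB"), "at least two")
  expect_error(build_profile(c(s, substr(s, 1, 50)), "traB"), "same length")
})

test_that("packaged TraB seeds score above threshold against their profile", {
  aln <- trab_seed_alignment()
  prof <- build_profile(aln, "traB")
  for (s in aln) {
    r <- icecensus:::cpp_profile_scan(s, prof$scores, icecensus:::AA20, 60L)
    expect_gt(r$score, prof$score_threshold)
  }
})

test_that("scan_proteome recovers mutated seeds and ignores background", {
  seeds <- signature_seeds()
  set.seed(31)
  prots <- c(rel85 = mutate_to_identity(seeds[["relaxase"]], 85),
             traB_trunc = substr(mutate_to_identity(seeds[["traB"]], 85),
                                 1, 139),
             bg1 = random_protein(350), bg2 = random_protein(500),
             bg3 = random_protein(200))
  profs <- default_profiles()
  hits <- scan_proteome(prots, profs)
  expect_setequal(hits$protein_id[hits$role == "relaxase"], "rel85")
  # a TraB truncated to 139 aa is still detected
  expect_true("traB_trunc" %in% hits$protein_id[hits$role == "traB"])
  expect_false(any(grepl("^bg", hits$protein_id)))
  expect_identical(scan_proteome(prots, list()), icecensus:::empty_hits())
  expect_error(scan_proteome(character(0), profs), "empty")
})

test_that("profile score decreases monotonically with identity decay", {
  seeds <- signature_seeds()
  prof <- default_profiles()[["rep"]]
  idents <- c(95, 85, 70, 55, 40)
  scores <- vapply(idents, function(idt) {
    m <- mutate_to_identity(seeds[["rep"]], idt, seed = idt)
    icecensus:::cpp_profile_scan(m, prof$scores, icecensus:::AA20, 60L)$score
  }, 0)
  expect_true(all(diff(scores) < 0))
})

test_that("similarity search honours identity and coverage cutoffs", {
  seeds <- signature_seeds()
  set.seed(32)
  target <- seeds[["relaxase"]]
  prots <- c(exact = target,
             m85 = mutate_to_identity(target, 85),
             bg = random_protein(340))
  hits <- similarity_search(c(relaxase = target), prots)
  expect_true(all(c("exact", "m85") %in% hits$protein_id))
  expect_false("bg" %in% hits$protein_id)
  ex <- hits[hits$protein_id == "exact", ]
  expect_equal(ex$score, 100)
  expect_equal(ex$query_coverage, 1)
  m <- hits[hits$protein_id == "m85", ]
  expect_true(m$score >= 80 && m$query_coverage >= 0.8)
  # random proteome: no hit at defaults
  set.seed(33)
  rnd <- stats::setNames(vapply(1:30, function(i) random_protein(300), ""),
                         paste0("r", 1:30))
  expect_equal(nrow(similarity_search(c(relaxase = target), rnd)), 0)
})

test_that("profile and similarity routes agree on roles where both detect", {
  run <- mini_run(1)
  cfg <- pipeline_config()
  profs <- default_profiles()
  ph <- scan_proteome(run$pop$genomes, profs, cfg)
  sh <- similarity_search(signature_seeds(), run$pop$genomes, config = cfg)
  both <- intersect(ph$protein_id, sh$protein_id)
  expect_gt(length(both), 0)
  for (pid in both)
    expect_identical(ph$role[ph$protein_id == pid],
                     sh$role[sh$protein_id == pid])
})

test_that("HMMER domain tables import with E-value filtering and role maps", {
  tf <- tempfile(fileext = ".domtbl")
  row <- function(t, q, qlen, iev, bits) {
    # tname tacc tlen qname qacc qlen fullE fullScore fullBias n of
    # cEvalue iEvalue domScore domBias hmmFrom hmmTo aliFrom aliTo
    # envFrom envTo acc description
    paste(t, "-", 400, q, "-", qlen, "1e-40", "120.0", "1.0", 1, 1,
          format(iev, scientific = TRUE), format(iev, scientific = TRUE),
          bits, "0.1", 10, qlen - 10L, 5, 390, 5, 390, "0.9", "desc")
  }
  writeLines(c("# comment line", "#",
               row("p1", "TraB_profile", 700, 1e-30, 300),
               row("p2", "TraB_profile", 700, 1e-12, 120),
               row("p3", "Int_profile", 380, 1e-9, 80),
               row("p4", "Int_profile", 380, 1e-3, 20),  # above cutoff
               row("p5", "Unknown_profile", 200, 1e-20, 90)), tf)
  rm2 <- c(TraB_profile = "traB", Int_profile = "integrase_tyr")
  expect_warning(h <- import_domtbl(tf, rm2, evalue_cutoff = 1e-6),
                 "no role mapping")
  expect_equal(nrow(h), 3)
  expect_setequal(h$protein_id, c("p1", "p2", "p3"))
  expect_setequal(unique(h$role), c("traB", "integrase_tyr"))
  expect_true(all(h$method == "imported"))
  # comments-only file
  tf2 <- tempfile(); writeLines(c("# only", "# comments"), tf2)
  expect_equal(nrow(import_domtbl(tf2)), 0)
  # malformed line errors with its number
  tf3 <- tempfile(); writeLines(c("# ok", "too few fields"), tf3)
  expect_error(import_domtbl(tf3), "line 2")
})
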