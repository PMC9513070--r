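# Independent oracles and small fixture builders shared across tests.

# Brute-force repeat oracle: enumerate every diagonal of the two windows and
# return, per diagonal, the best interval of length >= min_len whose
# mismatch count is within ceiling(rate * length), maximising
# score = matches - (1 + pen) * mismatches (ties: fewer mismatches, then
# leftmost). Written independently of the seed-and-extend implementation.
brute_force_repeats <- function(Lw, Rw, min_len, rate = 0, pen = 3) {
  la <- strsplit(Lw, "", fixed = TRUE)[[1]]
  ra <- strsplit(Rw, "", fixed = TRUE)[[1]]
  nl <- length(la); nr <- length(ra)
  out <- list()
  for (d in (-(nl - 1)):(nr - 1)) {
    i0 <- max(1L, 1L - d)
    j0 <- i0 + d
    len_d <- min(nl - i0 + 1L, nr - j0 + 1L)
    if (len_d < min_len) next
    m <- la[i0:(i0 + len_d - 1L)] == ra[j0:(j0 + len_d - 1L)]
    sc <- ifelse(m, 1, -pen)
    cs <- c(0, cumsum(sc)); cm <- c(0, cumsum(!m))
    best <- NULL
    for (a in 1:(len_d - min_len + 1L)) {
      for (b in (a + min_len - 1L):len_d) {
        L <- b - a + 1L
        mm <- cm[b + 1L] - cm[a]
        if (mm > ceiling(rate * L)) next
        score <- cs[b + 1L] - cs[a]
        key <- c(score, -mm, -a)
        if (is.null(best) || score > best$score ||
            (score == best$score && mm < best$mism)) {
          best <- list(a = a, b = b, score = score, mism = mm)
        }
      }
    }
    if (!is.null(best) && best$score > 0) {
      li <- i0 + best$a - 1L; rj <- j0 + best$a - 1L
      L <- best$b - best$a + 1L
      out[[length(out) + 1L]] <- data.frame(
        left_start0 = li - 1L, right_start0 = rj - 1L, length = L,
        mismatches = best$mism, score = best$score)
    }
  }
  do.call(rbind, out) %||% data.frame(left_start0 = integer(),
                                      right_start0 = integer(),
                                      length = integer(),
                                      mismatches = integer(),
                                      score = numeric())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# internal helpers reused by fixtures
random_protein <- icecensus:::random_protein
feature_row <- icecensus:::feature_row

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# A bare replicon with one planted direct-repeat pair around an "anchor"
# segment, returning the sequence and the planted coordinates. Sentinel
# bases at the four copy boundaries block chance single-base extensions so
# the planted pair is the exact optimum.
plant_repeat_fixture <- function(flank = 3000, tsd = 93, body = 8000,
                                 seed = 1) {
  set.seed(seed)
  left_bg <- paste0(substr(random_dna_str(flank), 1, flank - 3), "AAA")
  rep_seq <- random_dna_str(tsd)
  body_seq <- random_dna_str(body)
  body_seq <- paste0("GGG", substr(body_seq, 4, body - 3), "CCC")
  right_bg <- paste0("TTT", substr(random_dna_str(flank), 4, flank))
  seq <- paste0(left_bg, rep_seq, body_seq, rep_seq, right_bg)
  list(seq = seq,
       left = c(flank, flank + tsd),
       right = c(flank + tsd + body, flank + tsd + body + tsd),
       anchor = c(flank + tsd + 500, flank + tsd + body - 500))
}

# Exhaustive small-parsimony oracle: minimum number of state changes over
# all labelings of the internal nodes of an ape tree for one binary
# character at the tips.
brute_force_parsimony <- function(tree, states) {
  nt <- length(tree$tip.label)
  nn <- tree$Nnode
  tip_state <- states[tree$tip.label]
  best <- Inf
  for (mask in 0:(2^nn - 1)) {
    lab <- c(tip_state, as.integer(intToBits(mask))[1:nn])
    changes <- sum(lab[tree$edge[, 1]] != lab[tree$edge[, 2]])
    best <- min(best, changes)
  }
  best
}

# shared fixture cache (computed at most once per test session)
.fixture_env <- new.env(parent = emptyenv())

reference_run <- function() {
  if (!is.null(.fixture_env$ref)) return(.fixture_env$ref)
  bp <- reference_population(seed = 42)
  pop <- generate_population(bp)
  res <- run_full_pipeline(pop$genomes, tree = bp$cladogram)
  .fixture_env$ref <- list(bp = bp, pop = pop, res = res)
  .fixture_env$ref
}

mini_run <- function(index = 1) {
  key <- paste0("mini", index)
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  bp <- random_blueprint(index)
  pop <- generate_population(bp)
  res <- run_full_pipeline(pop$genomes, tree = bp$cladogram)
  .fixture_env[[key]] <- list(bp = bp, pop = pop, res = res)
  .fixture_env[[key]]
}
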