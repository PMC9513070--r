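# Direct-repeat (target-site duplication) detection around a candidate
# element anchor, and element delimitation from a repeat pair.
#
# Algorithm: exact k-mer seeds pair positions of the upstream and downstream
# search windows; every seeded diagonal is scanned for its best-scoring
# interval (match +1, mismatch -penalty) subject to the minimum length and
# the mismatch-rate bound. Ranking is by score, then fewer mismatches, then
# innermost pair, then leftmost: a mismatch-budget extension of a true
# target-site duplication therefore never outranks the exact duplication,
# and in accretion stacks each element is delimited by its own nearest
# attL/attR pair rather than by the outermost copies.

#' Find near-identical direct repeats flanking an anchor
#'
#' Searches for repeat pairs with one copy in the window of `search_radius`
#' bp upstream of the anchor and one copy in the window downstream, with at
#' most `max_mismatch_rate` mismatches per repeat length.
#'
#' @param sequence replicon nucleotide sequence (single string).
#' @param anchor integer vector `c(start0, end0)` (0-based half-open) of the
#'   region containing the candidate's signature hits.
#' @param search_radius window size (bp) on each side of the anchor.
#' @param min_len minimum repeat length reported.
#' @param max_mismatch_rate maximum mismatches per repeat length (a repeat of
#'   length L may carry up to `ceiling(L * rate)` mismatches).
#' @param seed_k exact seed length pairing window positions (diagonals
#'   without an exact `seed_k`-mer match are not scanned).
#' @param mismatch_penalty score penalty per mismatch used for ranking and
#'   interval optimisation (matches score +1).
#' @return data.frame of class `repeat_set`, one row per repeat: `left_start0`,
#'   `left_end0`, `right_start0`, `right_end0`, `length`, `mismatches`,
#'   `score`, `seq_left`, `seq_right`, ranked best-first. Attribute
#'   `n_pairs` records the number of window position pairs searched (used by
#'   the chance-significance filter).
#' @export
find_flanking_repeats <- function(sequence, anchor, search_radius = 5000,
                                  min_len = 10, max_mismatch_rate = 0.05,
                                  seed_k = 8, mismatch_penalty = 3) {
  n <- nchar(sequence)
  stopifnot(length(anchor) == 2L)
  if (anchor[1] < 0 || anchor[2] > n || anchor[1] >= anchor[2])
    stop("anchor outside sequence")
  if (search_radius <= 0) stop("search_radius must be positive")
  lw0 <- max(0L, as.integer(anchor[1] - search_radius))
  lw1 <- as.integer(anchor[1])
  rw0 <- as.integer(anchor[2])
  rw1 <- min(n, as.integer(anchor[2] + search_radius))
  Lw <- substr0(sequence, lw0, lw1)
  Rw <- substr0(sequence, rw0, rw1)
  res <- .scan_window_pair(Lw, Rw, min_len, max_mismatch_rate, seed_k,
                           mismatch_penalty)
  if (nrow(res)) {
    res$left_start0 <- res$left_start0 + lw0
    res$left_end0 <- res$left_end0 + lw0
    res$right_start0 <- res$right_start0 + rw0
    res$right_end0 <- res$right_end0 + rw0
    res <- rank_repeats(res, anchor)
  }
  attr(res, "n_pairs") <- as.numeric(nchar(Lw)) * nchar(Rw)
  class(res) <- c("repeat_set", class(res))
  res
}

# Core window-pair scan in window-local coordinates.
.scan_window_pair <- function(Lw, Rw, min_len, rate, seed_k, pen) {
  empty <- data.frame(left_start0 = integer(), left_end0 = integer(),
                      right_start0 = integer(), right_end0 = integer(),
                      length = integer(), mismatches = integer(),
                      score = numeric(), seq_left = character(),
                      seq_right = character(), stringsAsFactors = FALSE)
  nl <- nchar(Lw); nr <- nchar(Rw)
  if (nl < min_len || nr < min_len) return(empty)
  la <- strsplit(Lw, "", fixed = TRUE)[[1]]
  ra <- strsplit(Rw, "", fixed = TRUE)[[1]]
  k <- min(seed_k, min_len)
  # seed: exact k-mers shared between windows -> candidate diagonals
  lk <- substring(Lw, 1:(nl - k + 1L), k:nl)
  rk <- substring(Rw, 1:(nr - k + 1L), k:nr)
  rmap <- split(seq_along(rk), rk)
  diags <- integer(0)
  hit <- which(lk %in% names(rmap))
  for (i in hit) diags <- c(diags, rmap[[lk[i]]] - i)
  diags <- sort(unique(diags))
  rows <- list()
  for (d in diags) {
    i0 <- max(1L, 1L - d)            # first left index on this diagonal
    j0 <- i0 + d
    len_d <- min(nl - i0 + 1L, nr - j0 + 1L)
    if (len_d < min_len) next
    m <- la[i0:(i0 + len_d - 1L)] == ra[j0:(j0 + len_d - 1L)]
    best <- .best_interval(m, min_len, rate, pen)
    if (is.null(best)) next
    a <- best[1]; b <- best[2]     # 1-based inclusive within diagonal
    li <- i0 + a - 1L; rj <- j0 + a - 1L
    L <- b - a + 1L
    mm <- sum(!m[a:b])
    rows[[length(rows) + 1L]] <- data.frame(
      left_start0 = li - 1L, left_end0 = li - 1L + L,
      right_start0 = rj - 1L, right_end0 = rj - 1L + L,
      length = L, mismatches = mm, score = L - (1 + pen) * mm,
      seq_left = paste(la[li:(li + L - 1L)], collapse = ""),
      seq_right = paste(ra[rj:(rj + L - 1L)], collapse = ""),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

# Best qualifying interval on one diagonal: maximise score = matches -
# penalty * mismatches subject to length >= min_len and mismatches <=
# ceiling(rate * length). With a zero mismatch budget this reduces to the
# longest exact run; otherwise candidate segments (regions between
# positions where the prefix score reaches a new running minimum, i.e.
# Kadane reset points) are enumerated exhaustively.
.best_interval <- function(m, min_len, rate, pen) {
  n <- length(m)
  if (ceiling(rate * n) < 1) {
    r <- rle(m)
    ends <- cumsum(r$lengths)
    ok <- r$values & r$lengths >= min_len
    if (!any(ok)) return(NULL)
    i <- which(ok)[order(-r$lengths[ok])][1L]
    return(c(ends[i] - r$lengths[i] + 1L, ends[i]))
  }
  s <- ifelse(m, 1, -pen)
  cs <- cumsum(s)
  runmin <- cummin(c(0, cs))[-1L]
  resets <- which(cs <= runmin & cs <= 0)
  bounds <- unique(c(0L, resets, n))
  bounds <- sort(bounds)
  seg_len <- diff(bounds)
  cand <- which(seg_len >= min_len)
  best <- NULL; best_key <- NULL
  for (bi in cand) {
    a <- bounds[bi] + 1L; b <- bounds[bi + 1L]
    L <- b - a + 1L
    x <- s[a:b]; mmv <- !m[a:b]
    csx <- c(0, cumsum(x)); cmx <- c(0, cumsum(mmv))
    for (st in 1:(L - min_len + 1L)) {
      ens <- (st + min_len - 1L):L
      lens <- ens - st + 1L
      sc <- csx[ens + 1L] - csx[st]
      mc <- cmx[ens + 1L] - cmx[st]
      ok2 <- mc <= ceiling(rate * lens)
      if (!any(ok2)) next
      sc <- sc[ok2]; mc <- mc[ok2]; ens <- ens[ok2]
      o <- order(-sc, mc, ens)[1L]
      key <- c(sc[o], mc[o])
      if (is.null(best) || key[1] > best_key[1] ||
          (key[1] == best_key[1] && key[2] < best_key[2])) {
        best <- c(a + st - 1L, a + ens[o] - 1L)
        best_key <- key
      }
    }
  }
  best
}

#' Rank a repeat set relative to an anchor
#'
#' Orders repeats by score (descending), then fewer mismatches, then
#' innermost (smallest total distance between the repeat pair and the
#' anchor), then leftmost.
#' @param repeats repeat data.frame as returned by [find_flanking_repeats()].
#' @param anchor `c(start0, end0)` anchor interval.
#' @return the reordered data.frame.
#' @export
rank_repeats <- function(repeats, anchor) {
  if (!nrow(repeats)) return(repeats)
  inner <- (anchor[1] - repeats$left_end0) + (repeats$right_start0 - anchor[2])
  o <- order(-repeats$score, repeats$mismatches, inner, repeats$left_start0)
  out <- repeats[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter repeats by chance significance and tRNA anchoring
#'
#' A repeat is retained when the expected number of chance window pairs with
#' at least its identity (Poisson expectation over all window position
#' pairs, binomial match model) is at most `alpha`, or when one of its
#' copies overlaps the 3' `trna_tail` nt of an annotated tRNA (att-site
#' anchoring; such repeats gain flag `att_anchored`).
#'
#' @param repeats repeat data.frame (absolute coordinates).
#' @param features feature data.frame of the replicon (for tRNA anchoring);
#'   may be NULL.
#' @param n_pairs number of window position pairs searched (defaults to the
#'   `n_pairs` attribute of `repeats`).
#' @param alpha expectation threshold.
#' @param trna_tail anchoring tail length (nt).
#' @return the filtered data.frame with an added `att_anchored` logical.
#' @export
filter_repeats <- function(repeats, features = NULL, n_pairs = NULL,
                           alpha = 1e-3, trna_tail = 30) {
  if (!nrow(repeats)) {
    repeats$att_anchored <- logical(0)
    return(repeats)
  }
  if (is.null(n_pairs)) n_pairs <- attr(repeats, "n_pairs")
  ev <- mapply(repeat_chance_expectation, repeats$length, repeats$mismatches,
               MoreArgs = list(n_pairs = n_pairs))
  anchored <- rep(FALSE, nrow(repeats))
  if (!is.null(features) && nrow(features)) {
    trna <- features[features$type == "tRNA", , drop = FALSE]
    if (nrow(trna)) {
      t0 <- pmax(trna$start0, trna$end0 - trna_tail)
      t1 <- trna$end0
      ov <- function(a0, a1) {
        any(a0 < t1 & a1 > t0)
      }
      for (i in seq_len(nrow(repeats))) {
        anchored[i] <- ov(repeats$left_start0[i], repeats$left_end0[i]) ||
          ov(repeats$right_start0[i], repeats$right_end0[i])
      }
    }
  }
  keep <- (ev <= alpha) | anchored
  out <- repeats[keep, , drop = FALSE]
  out$att_anchored <- anchored[keep] & !(ev[keep] <= alpha)
  attr(out, "n_pairs") <- n_pairs
  rownames(out) <- NULL
  out
}

#' Expected number of chance repeat pairs of a given pattern
#'
#' Binomial model: two random windows of combined `n_pairs` position pairs;
#' the expectation of observing an alignment of length `len` with at most
#' `mism` mismatches at a fixed pair is `P(X >= len - mism)`,
#' `X ~ Binomial(len, p_match)`. The default per-base match probability of
#' 0.3 is deliberately conservative for protein-coding DNA, whose codon
#' bias raises the coincidence rate above the 0.25 of uniform random
#' sequence.
#' @param len repeat length (nt).
#' @param mism observed mismatches.
#' @param n_pairs number of window position pairs.
#' @param p_match per-base chance match probability.
#' @return expectation (numeric).
#' @export
repeat_chance_expectation <- function(len, mism, n_pairs, p_match = 0.3) {
  p <- stats::pbinom(len - mism - 1, size = len, prob = p_match,
                     lower.tail = FALSE)
  n_pairs * p
}

#' Delimit an element from its anchor and flanking repeat
#'
#' @param anchor `c(start0, end0)` interval containing the signature hits.
#' @param rep one-row repeat data.frame (or list) with `left_start0`,
#'   `left_end0`, `right_start0`, `right_end0`.
#' @param convention boundary convention: `"include_one_repeat"` (default;
#'   left repeat inside, right repeat outside, so that excising the bounds
#'   restores an intact integration site), `"exclude_repeats"` or
#'   `"include_both"`.
#' @return list of class `DelineatedElement` with `bounds` (`c(start0,
#'   end0)`), `anchor`, `repeat` and `span` (bp).
#' @export
delineate_element <- function(anchor, rep,
                              convention = c("include_one_repeat",
                                             "exclude_repeats",
                                             "include_both")) {
  convention <- match.arg(convention)
  if (rep$left_end0 > anchor[1] || rep$right_start0 < anchor[2])
    stop("repeat does not flank the anchor")
  bounds <- switch(convention,
    include_one_repeat = c(rep$left_start0, rep$right_start0),
    exclude_repeats = c(rep$left_end0, rep$right_start0),
    include_both = c(rep$left_start0, rep$right_end0))
  structure(list(anchor = anchor, bounds = as.integer(bounds),
                 rep = rep, span = as.integer(bounds[2] - bounds[1]),
                 convention = convention),
            class = "DelineatedElement")
}
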