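# Pairwise global identities, single-linkage family clustering at an
# identity threshold, and a neighbor-joining tree built from the identity
# matrix.

#' Global percent identity between two protein sequences
#'
#' Needleman-Wunsch global alignment with affine gaps (BLOSUM62, gap open
#' 10, extend 1 by default); identity is matches divided by total alignment
#' columns (gap columns included), times 100.
#'
#' @param a,b amino-acid sequences (non-empty).
#' @param gap_open,gap_ext affine gap penalties.
#' @return percent identity in `[0, 100]`.
#' @export
#' @examples
#' global_identity("MKLV", "MKIV")  # 75
global_identity <- function(a, b, gap_open = 10, gap_ext = 1) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  r <- cpp_global_align(a, b, blosum62(), gap_open, gap_ext)
  r$identity
}

#' Pairwise identity matrix over a protein set
#'
#' @param seqs named character vector of amino-acid sequences.
#' @param gap_open,gap_ext affine gap penalties.
#' @return symmetric percent-identity matrix (diagonal 100) with the input
#'   names as dimnames; class `IdentityMatrix`.
#' @export
identity_matrix <- function(seqs, gap_open = 10, gap_ext = 1) {
  stopifnot(length(seqs) >= 1, all(nzchar(seqs)))
  m <- cpp_identity_matrix(unname(seqs), blosum62(), gap_open, gap_ext)
  dimnames(m) <- list(names(seqs), names(seqs))
  class(m) <- c("IdentityMatrix", class(m))
  m
}

.check_identity_matrix <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (max(abs(m - t(m))) > 1e-9) stop("identity matrix must be symmetric")
  if (any(m < -1e-9 | m > 100 + 1e-9)) stop("identities must be in [0, 100]")
  invisible(m)
}

#' Cluster proteins into families by single-linkage identity
#'
#' Families are the connected components of the graph whose edges join
#' pairs with identity at or above the threshold. Family numbering is
#' deterministic: families are ordered by their first member in input
#' order.
#'
#' @param matrix symmetric percent-identity matrix (see
#'   [identity_matrix()]).
#' @param threshold percent identity (default 95).
#' @param seq_lengths optional named lengths used to pick the family
#'   representative (longest member; first member when absent).
#' @return data.frame with `id`, `family_id` (`fam01`, `fam02`, ...),
#'   `is_representative`, `is_singleton`.
#' @export
cluster_families <- function(matrix, threshold = 95, seq_lengths = NULL) {
  .check_identity_matrix(matrix)
  n <- nrow(matrix)
  ids <- rownames(matrix) %||% as.character(seq_len(n))
  comp <- integer(n)
  cur <- 0L
  adj <- matrix >= threshold - 1e-9
  for (i in seq_len(n)) {
    if (comp[i] != 0L) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  out <- data.frame(id = ids, family_id = sprintf("fam%02d", comp),
                    stringsAsFactors = FALSE)
  sizes <- table(comp)
  out$is_singleton <- as.integer(sizes[as.character(comp)]) == 1L
  out$is_representative <- FALSE
  for (k in unique(comp)) {
    mem <- which(comp == k)
    rep_i <- if (!is.null(seq_lengths))
      mem[which.max(seq_lengths[ids[mem]])] else mem[1]
    out$is_representative[rep_i] <- TRUE
  }
  out
}

#' Neighbor-joining tree from an identity matrix
#'
#' Distances are `(100 - identity) / 100`. Standard Saitou-Nei
#' agglomeration (Q criterion); negative branch lengths are clamped to
#' zero with the difference transferred to the sibling branch. The result
#' is an unrooted tree in newick format.
#'
#' @param matrix percent-identity matrix with at least 3 taxa.
#' @return newick string.
#' @export
neighbor_joining <- function(matrix) {
  .check_identity_matrix(matrix)
  d <- (100 - matrix) / 100
  dimnames(d) <- dimnames(matrix)
  nj_newick(d)
}

#' Neighbor joining on a distance matrix
#'
#' @param d symmetric distance matrix with dimnames; >= 3 taxa.
#' @return newick string (unrooted; trifurcating root).
#' @export
nj_newick <- function(d) {
  n <- nrow(d)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  labs <- rownames(d) %||% paste0("t", seq_len(n))
  # node representation: newick fragment per active node
  frag <- labs
  D <- unname(as.matrix(d))
  active <- seq_len(n)
  while (length(active) > 3L) {
    m <- length(active)
    Dm <- D[active, active, drop = FALSE]
    r <- rowSums(Dm)
    Q <- (m - 2) * Dm - outer(r, r, "+")
    diag(Q) <- Inf
    ij <- which(Q == min(Q), arr.ind = TRUE)[1, ]
    i <- ij[1]; j <- ij[2]
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    dij <- Dm[i, j]
    vi <- 0.5 * dij + (r[i] - r[j]) / (2 * (m - 2))
    vj <- dij - vi
    # clamp negatives, moving the excess to the sibling branch
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    ai <- active[i]; aj <- active[j]
    new_frag <- sprintf("(%s:%.10g,%s:%.10g)", frag[ai], vi, frag[aj], vj)
    # distances from the new node
    newd <- 0.5 * (Dm[i, ] + Dm[j, ] - dij)
    D <- rbind(cbind(D, 0), 0)
    k <- nrow(D)
    D[k, active] <- newd; D[active, k] <- newd
    D[k, k] <- 0
    frag <- c(frag, new_frag)
    active <- c(active[-c(i, j)], k)
    D[k, k] <- 0
  }
  # join the last three nodes on a trifurcating root
  a <- active[1]; b <- active[2]; c3 <- active[3]
  va <- 0.5 * (D[a, b] + D[a, c3] - D[b, c3])
  vb <- 0.5 * (D[a, b] + D[b, c3] - D[a, c3])
  vc <- 0.5 * (D[a, c3] + D[b, c3] - D[a, b])
  va <- max(va, 0); vb <- max(vb, 0); vc <- max(vc, 0)
  sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);", frag[a], va, frag[b], vb,
          frag[c3], vc)
}
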