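# Shared low-level helpers: alphabets, random sequence generation, reverse
# translation, and the scoring matrix used by the aligners.
#
# Coordinate convention: all internal coordinates are 0-based half-open
# [start0, end0); GFF3 import/export converts to/from 1-based inclusive.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Robinson & Robinson style background amino-acid frequencies, normalised.
AA_BACKGROUND <- c(
  A = 0.078, C = 0.019, D = 0.054, E = 0.063, F = 0.039, G = 0.074,
  H = 0.022, I = 0.052, K = 0.057, L = 0.090, M = 0.022, N = 0.045,
  P = 0.052, Q = 0.043, R = 0.051, S = 0.071, T = 0.058, V = 0.064,
  W = 0.013, Y = 0.032)
AA_BACKGROUND <- AA_BACKGROUND / sum(AA_BACKGROUND)

DNA4 <- c("A", "C", "G", "T")

# Synonymous codons per amino acid (standard code). Reverse translation
# samples among them so that shared amino-acid runs between unrelated genes
# do not produce identical nucleotide stretches (which would look like
# spurious direct repeats to the repeat finder).
CODONS <- list(
  A = c("GCT", "GCC", "GCA", "GCG"), C = c("TGT", "TGC"),
  D = c("GAT", "GAC"), E = c("GAA", "GAG"),
  F = c("TTT", "TTC"), G = c("GGT", "GGC", "GGA", "GGG"),
  H = c("CAT", "CAC"), I = c("ATT", "ATC", "ATA"),
  K = c("AAA", "AAG"), L = c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG"),
  M = "ATG", N = c("AAT", "AAC"),
  P = c("CCT", "CCC", "CCA", "CCG"), Q = c("CAA", "CAG"),
  R = c("CGT", "CGC", "CGA", "CGG", "AGA", "AGG"),
  S = c("TCT", "TCC", "TCA", "TCG", "AGT", "AGC"),
  T = c("ACT", "ACC", "ACA", "ACG"), V = c("GTT", "GTC", "GTA", "GTG"),
  W = "TGG", Y = c("TAT", "TAC"))

random_dna <- function(n) {
  paste(sample(DNA4, n, replace = TRUE), collapse = "")
}

random_protein <- function(n_aa) {
  paste(sample(AA20, n_aa, replace = TRUE, prob = AA_BACKGROUND),
        collapse = "")
}

# codon lookup matrix for vectorised sampling
.CODMAT <- local({
  m <- matrix("", nrow = length(CODONS), ncol = 6,
              dimnames = list(names(CODONS), NULL))
  for (a in names(CODONS)) m[a, seq_along(CODONS[[a]])] <- CODONS[[a]]
  m
})
.NCOD <- vapply(CODONS, length, 0L)

reverse_translate <- function(protein) {
  aa <- strsplit(protein, "", fixed = TRUE)[[1]]
  ai <- match(aa, names(CODONS))
  j <- 1L + as.integer(floor(stats::runif(length(aa)) * .NCOD[ai]))
  paste0(paste(.CODMAT[cbind(ai, j)], collapse = ""), "TAA")
}

gene_nt_length <- function(n_aa) 3L * (n_aa + 1L)

#' BLOSUM62 substitution matrix
#'
#' The BLOSUM62 scoring matrix as shipped with Biostrings, used by the
#' global and local protein aligners.
#' @return integer matrix with amino-acid dimnames.
#' @keywords internal
blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

# substring by 0-based half-open interval
substr0 <- function(x, start0, end0) substr(x, start0 + 1L, end0)

`%||%` <- function(a, b) if (is.null(a)) b else a

new_feature_df <- function() {
  data.frame(id = character(), type = character(), start0 = integer(),
             end0 = integer(), strand = character(), product = character(),
             stringsAsFactors = FALSE)
}

feature_row <- function(id, type, start0, end0, strand = "+", product = "") {
  data.frame(id = id, type = type, start0 = as.integer(start0),
             end0 = as.integer(end0), strand = strand, product = product,
             stringsAsFactors = FALSE)
}

#' Construct a genome record
#'
#' A `GenomeRecord` bundles one replicon: its nucleotide sequence, typed
#' features (CDS/tRNA) with 0-based half-open coordinates, the proteome keyed
#' by CDS id, and replicon metadata (topology and role).
#'
#' @param strain strain identifier.
#' @param replicon replicon identifier, unique within the strain.
#' @param seq nucleotide sequence as a single character string.
#' @param features data.frame with columns `id`, `type`, `start0`, `end0`,
#'   `strand`, `product`.
#' @param proteins named character vector of amino-acid sequences, names
#'   matching CDS feature ids.
#' @param topology `"linear"` or `"circular"`.
#' @param role `"chromosome"` or `"plasmid"`.
#' @return an object of class `GenomeRecord`.
#' @export
genome_record <- function(strain, replicon, seq, features, proteins,
                          topology = "linear", role = "chromosome") {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nrow(features)) {
    stopifnot(all(features$end0 <= nchar(seq)), all(features$start0 >= 0))
  }
  structure(list(strain = strain, replicon = replicon, seq = seq,
                 features = features, proteins = proteins,
                 topology = topology, role = role),
            class = "GenomeRecord")
}

#' @export
print.GenomeRecord <- function(x, ...) {
  cat(sprintf("<GenomeRecord %s/%s: %s %s, %d bp, %d features, %d proteins>\n",
              x$strain, x$replicon, x$topology, x$role, nchar(x$seq),
              nrow(x$features), length(x$proteins)))
  invisible(x)
}
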