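# Signature-protein screening: position-specific profile scoring, similarity
# search against canonical seed proteins, and import of precomputed HMMER
# domain tables. The two in-house detection routes are combined by union with
# a role-consistency check (two-way detection).

SIGNATURE_ROLES <- c("integrase_tyr", "integrase_ser", "relaxase", "coupling",
                     "virb4", "traB", "rep", "parM", "atp_gtp_binding")

#' Packaged canonical signature seed proteins
#'
#' One synthetic canonical amino-acid sequence per signature role
#' (tyrosine/serine integrase, relaxase, coupling protein, VirB4, TraB, Rep,
#' ParM, ATP/GTP-binding protein). These seeds anchor both the profile scorer
#' and the similarity search, and the synthetic-population generator derives
#' every planted signature protein from them by identity-targeted mutation.
#'
#' @return named character vector of amino-acid sequences (names are roles).
#' @export
signature_seeds <- function() {
  path <- system.file("extdata", "signature_seeds.faa", package = "icecensus")
  x <- Biostrings::readAAStringSet(path)
  seqs <- as.character(x)
  names(seqs) <- vapply(strsplit(names(x), " "), `[`, "", 1L)
  seqs
}

#' Packaged TraB seed alignment
#'
#' Four equal-length synthetic TraB variants (substitution-only, about 85%
#' pairwise identity) used as the default seed alignment for the TraB
#' profile.
#' @return named character vector of aligned amino-acid sequences.
#' @export
trab_seed_alignment <- function() {
  path <- system.file("extdata", "trab_seed_alignment.faa",
                      package = "icecensus")
  x <- Biostrings::readAAStringSet(path)
  seqs <- as.character(x)
  names(seqs) <- vapply(strsplit(names(x), " "), `[`, "", 1L)
  seqs
}

#' Build a position-specific scoring profile from a seed alignment
#'
#' Converts an aligned set of amino-acid sequences into a matrix of
#' per-column log-odds scores (bits) against the background residue
#' frequencies, with pseudocounts proportional to the background. Columns
#' with more than 50% gaps are dropped.
#'
#' @param seed_alignment character vector of aligned sequences (equal
#'   lengths; `-` for gaps). At least two sequences are required.
#' @param role role tag attached to hits produced with this profile.
#' @param score_threshold minimum anchored score (bits) for a hit.
#' @param pseudocount total pseudocount weight per column.
#' @return an object of class `ProfileMatrix`: list with `role`, `scores`
#'   (columns x 20 matrix of bits), `alphabet`, `score_threshold`,
#'   `consensus` (character string used for prescreening).
#' @export
#' @examples
#' prof <- build_profile(trab_seed_alignment(), "traB")
#' dim(prof$scores)
build_profile <- function(seed_alignment, role, score_threshold = 30,
                          pseudocount = 1) {
  if (length(seed_alignment) < 2L)
    stop("build_profile() needs at least two aligned sequences")
  lens <- nchar(seed_alignment)
  if (length(unique(lens)) != 1L)
    stop("aligned sequences must all have the same length")
  stopifnot(is.finite(score_threshold))
  mat <- do.call(rbind, strsplit(toupper(seed_alignment), "", fixed = TRUE))
  gap_frac <- colMeans(mat == "-" | mat == ".")
  keep <- gap_frac <= 0.5
  mat <- mat[, keep, drop = FALSE]
  ncolm <- ncol(mat)
  scores <- matrix(0, nrow = ncolm, ncol = length(AA20),
                   dimnames = list(NULL, AA20))
  n <- nrow(mat)
  for (j in seq_len(ncolm)) {
    col <- mat[, j]
    col <- col[col %in% AA20]
    cnt <- table(factor(col, levels = AA20))
    p <- (as.numeric(cnt) + pseudocount * AA_BACKGROUND) /
      (length(col) + pseudocount)
    scores[j, ] <- log2(p / AA_BACKGROUND)
  }
  consensus <- paste(AA20[max.col(scores)], collapse = "")
  structure(list(role = role, scores = scores, alphabet = AA20,
                 score_threshold = score_threshold, consensus = consensus),
            class = "ProfileMatrix")
}

#' Default profile set for all signature roles
#'
#' Builds one profile per signature role from the packaged seeds (each seed
#' is expanded into a small substitution-variant alignment with a fixed
#' internal seed so that profiles are reproducible).
#' @param score_threshold minimum anchored score in bits.
#' @return named list of `ProfileMatrix` objects.
#' @export
default_profiles <- function(score_threshold = 30) {
  seeds <- signature_seeds()
  profs <- vector("list", length(seeds))
  names(profs) <- names(seeds)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(73L)
  for (r in names(seeds)) {
    if (r == "traB") {
      aln <- trab_seed_alignment()
    } else {
      s <- seeds[[r]]
      aln <- c(s, vapply(1:3, function(i) .mutate_fraction(s, 0.15), ""))
    }
    profs[[r]] <- build_profile(aln, r, score_threshold = score_threshold)
  }
  profs
}

# substitution-only mutation of a fixed fraction of positions
.mutate_fraction <- function(protein, frac) {
  a <- strsplit(protein, "", fixed = TRUE)[[1]]
  n <- round(length(a) * frac)
  if (n > 0) {
    pos <- sample.int(length(a), n)
    a[pos] <- vapply(a[pos], function(x) sample(setdiff(AA20, x), 1L), "")
  }
  paste(a, collapse = "")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

empty_hits <- function() {
  data.frame(protein_id = character(), replicon = character(),
             start0 = integer(), end0 = integer(), strand = character(),
             role = character(), score = numeric(), method = character(),
             query_coverage = numeric(), flags = character(),
             stringsAsFactors = FALSE)
}

# locate gene coordinates for protein ids in a genome set
.protein_coords <- function(genomes, ids) {
  idx <- do.call(rbind, lapply(genomes, function(g) {
    f <- g$features[g$features$type == "CDS", , drop = FALSE]
    if (!nrow(f)) return(NULL)
    data.frame(protein_id = f$id,
               replicon = paste0(g$strain, "/", g$replicon),
               start0 = f$start0, end0 = f$end0, strand = f$strand,
               stringsAsFactors = FALSE)
  }))
  if (is.null(idx)) idx <- data.frame(protein_id = character(),
                                      replicon = character(),
                                      start0 = integer(), end0 = integer(),
                                      strand = character())
  idx[match(ids, idx$protein_id), , drop = FALSE]
}

#' Scan a proteome with signature profiles
#'
#' Slides each position-specific profile along each protein (ungapped
#' anchoring, free terminal overhangs, minimum overlap
#' `config$profile_min_overlap` columns) and reports the best anchored
#' placement per (protein, role) whenever its summed log-odds score reaches
#' the profile threshold. A fast shared-4-mer prescreen against the profile
#' consensus skips hopeless proteins. Output rows are ordered by replicon
#' then coordinate.
#'
#' @param proteins named character vector of amino-acid sequences, or a list
#'   of [genome_record()] objects (their proteomes are pooled and hits gain
#'   genomic coordinates).
#' @param profiles list of `ProfileMatrix` objects (see [build_profile()]).
#' @param config pipeline configuration, see [pipeline_config()].
#' @return data.frame of signature hits: `protein_id`, `replicon`, `start0`,
#'   `end0`, `strand`, `role`, `score` (bits), `method` = "profile",
#'   `query_coverage` (profile columns covered / total columns), `flags`.
#' @export
scan_proteome <- function(proteins, profiles,
                          config = pipeline_config()) {
  genomes <- NULL
  if (!is.character(proteins)) {
    genomes <- proteins
    proteins <- do.call(c, unname(lapply(genomes, `[[`, "proteins")))
  }
  if (length(proteins) == 0L) stop("empty proteome")
  if (length(profiles) == 0L) return(empty_hits())
  rows <- vector("list", length(profiles))
  for (pi in seq_along(profiles)) {
    prof <- profiles[[pi]]
    pre <- cpp_kmer_hits(unname(proteins), prof$consensus, 4L)
    cand <- which(pre >= (config$prescreen_min_kmers %||% 8L))
    if (!length(cand)) next
    out <- lapply(cand, function(i) {
      r <- cpp_profile_scan(proteins[[i]], prof$scores, AA20,
                            as.integer(config$profile_min_overlap))
      if (r$score >= prof$score_threshold) {
        data.frame(protein_id = names(proteins)[i], role = prof$role,
                   score = r$score,
                   query_coverage = r$overlap / nrow(prof$scores),
                   stringsAsFactors = FALSE)
      } else NULL
    })
    rows[[pi]] <- do.call(rbind, out)
  }
  hits <- do.call(rbind, rows)
  if (is.null(hits) || !nrow(hits)) return(empty_hits())
  hits$method <- "profile"
  hits$flags <- ""
  if (!is.null(genomes)) {
    co <- .protein_coords(genomes, hits$protein_id)
    hits$replicon <- co$replicon
    hits$start0 <- co$start0
    hits$end0 <- co$end0
    hits$strand <- co$strand
    hits <- hits[order(hits$replicon, hits$start0, hits$role), , drop = FALSE]
  } else {
    hits$replicon <- NA_character_
    hits$start0 <- NA_integer_
    hits$end0 <- NA_integer_
    hits$strand <- NA_character_
  }
  rownames(hits) <- NULL
  hits[, names(empty_hits())]
}

#' Similarity search of tagged query proteins against a proteome
#'
#' Local (Smith-Waterman, affine gaps, BLOSUM62) alignment of each query
#' against each proteome member passing a shared-4-mer prescreen; hits must
#' reach `min_identity` percent identity over the aligned columns and
#' `min_coverage` query coverage. The hit role is inherited from the query
#' tag (query names must be role tags or `role|label`).
#'
#' @param queries named character vector of query proteins; names carry the
#'   role tag.
#' @param proteome named character vector of target proteins, or a list of
#'   [genome_record()] objects.
#' @param min_identity percent identity cutoff.
#' @param min_coverage query coverage cutoff (fraction).
#' @param config pipeline configuration.
#' @return data.frame with the same columns as [scan_proteome()], `method` =
#'   "similarity", `score` = percent identity.
#' @export
similarity_search <- function(queries, proteome,
                              min_identity = 30, min_coverage = 0.80,
                              config = pipeline_config()) {
  genomes <- NULL
  if (!is.character(proteome)) {
    genomes <- proteome
    proteome <- do.call(c, unname(lapply(genomes, `[[`, "proteins")))
  }
  sub <- blosum62()
  rows <- list()
  for (qi in seq_along(queries)) {
    role <- strsplit(names(queries)[qi], "|", fixed = TRUE)[[1]][1]
    pre <- cpp_kmer_hits(unname(proteome), queries[[qi]], 4L)
    cand <- which(pre >= (config$prescreen_min_kmers %||% 8L))
    for (i in cand) {
      r <- cpp_local_align(queries[[qi]], proteome[[i]], sub,
                           config$gap_open, config$gap_ext)
      if (r$identity >= min_identity && r$q_cov >= min_coverage) {
        rows[[length(rows) + 1L]] <-
          data.frame(protein_id = names(proteome)[i], role = role,
                     score = r$identity, query_coverage = r$q_cov,
                     stringsAsFactors = FALSE)
      }
    }
  }
  hits <- do.call(rbind, rows)
  if (is.null(hits)) return(empty_hits())
  # best query per (protein, role)
  key <- paste(hits$protein_id, hits$role)
  hits <- hits[order(key, -hits$score), , drop = FALSE]
  hits <- hits[!duplicated(paste(hits$protein_id, hits$role)), , drop = FALSE]
  hits$method <- "similarity"
  hits$flags <- ""
  if (!is.null(genomes)) {
    co <- .protein_coords(genomes, hits$protein_id)
    hits$replicon <- co$replicon
    hits$start0 <- co$start0
    hits$end0 <- co$end0
    hits$strand <- co$strand
    hits <- hits[order(hits$replicon, hits$start0, hits$role), , drop = FALSE]
  } else {
    hits$replicon <- NA_character_; hits$start0 <- NA_integer_
    hits$end0 <- NA_integer_; hits$strand <- NA_character_
  }
  rownames(hits) <- NULL
  hits[, names(empty_hits())]
}

#' Merge profile and similarity hits (two-way detection)
#'
#' Union of the two hit tables with a role-consistency check: when both
#' methods detect the same protein the roles must agree, and the hit from
#' the higher-scoring method (profile bits vs identity rescaled) is kept;
#' disagreeing roles keep the higher-scoring row and gain a
#' `role_conflict` flag.
#'
#' @param profile_hits,similarity_hits hit data.frames.
#' @return merged hit data.frame.
#' @export
merge_hits <- function(profile_hits, similarity_hits) {
  all <- rbind(profile_hits, similarity_hits)
  if (!nrow(all)) return(empty_hits())
  out <- list()
  for (pid in unique(all$protein_id)) {
    h <- all[all$protein_id == pid, , drop = FALSE]
    if (length(unique(h$role)) > 1L) {
      h <- h[order(-h$score), , drop = FALSE]
      keep <- h[1L, , drop = FALSE]
      keep$flags <- paste0(keep$flags, ";role_conflict")
    } else {
      keep <- h[which.max(h$score), , drop = FALSE]
    }
    out[[length(out) + 1L]] <- keep
  }
  res <- do.call(rbind, out)
  res <- res[order(res$replicon, res$start0, res$role), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Import a HMMER3 per-domain table as signature hits
#'
#' Parses the whitespace-delimited HMMER3 `--domtblout` dialect (comment
#' lines start with `#`), maps profile names to signature roles and filters
#' by independent E-value.
#'
#' @param path path to the domain table.
#' @param role_map named character vector mapping profile names to roles;
#'   rows whose profile name has no mapping are skipped with a warning.
#' @param evalue_cutoff maximum E-value retained.
#' @return hit data.frame (`method` = "imported"; `score` = full-sequence
#'   bit score; `query_coverage` = aligned fraction of the profile).
#' @export
import_domtbl <- function(path, role_map = NULL,
                          evalue_cutoff = 1e-6) {
  lines <- readLines(path)
  rows <- list()
  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    if (grepl("^\\s*#", line) || !nzchar(trimws(line))) next
    f <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(f) < 22L)
      stop(sprintf("malformed domain-table line %d: expected >= 22 fields, got %d",
                   ln, length(f)))
    tname <- f[1]; qname <- f[4]
    qlen <- suppressWarnings(as.numeric(f[6]))
    ievalue <- suppressWarnings(as.numeric(f[13]))
    bits <- suppressWarnings(as.numeric(f[14]))
    hfrom <- suppressWarnings(as.numeric(f[16]))
    hto <- suppressWarnings(as.numeric(f[17]))
    if (anyNA(c(qlen, ievalue, bits, hfrom, hto)))
      stop(sprintf("malformed domain-table line %d: non-numeric field", ln))
    if (ievalue > evalue_cutoff) next
    role <- if (!is.null(role_map)) unname(role_map[qname]) else qname
    if (is.na(role)) {
      warning(sprintf("domain-table line %d: profile '%s' has no role mapping; skipped",
                      ln, qname))
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      protein_id = tname, replicon = NA_character_, start0 = NA_integer_,
      end0 = NA_integer_, strand = NA_character_, role = role, score = bits,
      method = "imported", query_coverage = (hto - hfrom + 1) / qlen,
      flags = "", stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty_hits())
  do.call(rbind, rows)
}
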