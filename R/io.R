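# Reading and writing populations: nucleotide FASTA (one record per
# replicon), GFF3 (1-based inclusive coordinates; CDS/tRNA features with
# product attributes, region features carrying topology/role), and protein
# FASTA keyed by CDS id.

.seqid <- function(strain, replicon) paste0(strain, ":", replicon)

#' Write a population to FASTA/GFF3/protein-FASTA files
#'
#' One trio of files per strain (`<strain>.fna`, `<strain>.gff3`,
#' `<strain>.faa`) plus `truth.tsv` when a truth table is supplied.
#' Replicon sequence ids are `strain:replicon`; GFF3 region features carry
#' `Is_circular` and `replicon_role` attributes.
#'
#' @param pop list with `genomes` (and optionally `truth`), as returned by
#'   [generate_population()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_population <- function(pop, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genomes <- pop$genomes
  strains <- unique(vapply(genomes, `[[`, "", "strain"))
  for (st in strains) {
    gs <- Filter(function(g) g$strain == st, genomes)
    seqs <- Biostrings::DNAStringSet(vapply(gs, `[[`, "", "seq"))
    names(seqs) <- vapply(gs, function(g) .seqid(g$strain, g$replicon), "")
    safe <- gsub("[^A-Za-z0-9._-]", "_", st)
    Biostrings::writeXStringSet(seqs, file.path(dir, paste0(safe, ".fna")))
    grs <- lapply(gs, function(g) {
      f <- g$features
      region <- data.frame(id = .seqid(g$strain, g$replicon),
                           type = "region", start0 = 0L,
                           end0 = nchar(g$seq), strand = "+",
                           product = "", stringsAsFactors = FALSE)
      f <- rbind(region, f)
      gr <- GenomicRanges::GRanges(
        seqnames = .seqid(g$strain, g$replicon),
        ranges = IRanges::IRanges(start = f$start0 + 1L, end = f$end0),
        strand = f$strand)
      S4Vectors::mcols(gr)$type <- f$type
      S4Vectors::mcols(gr)$phase <- ifelse(f$type == "CDS", 0L, NA_integer_)
      S4Vectors::mcols(gr)$ID <- f$id
      S4Vectors::mcols(gr)$product <- ifelse(nzchar(f$product), f$product,
                                             NA_character_)
      S4Vectors::mcols(gr)$Is_circular <-
        ifelse(f$type == "region" & g$topology == "circular", "true",
               NA_character_)
      S4Vectors::mcols(gr)$replicon_role <-
        ifelse(f$type == "region", g$role, NA_character_)
      gr
    })
    gr <- suppressWarnings(do.call(c, unname(grs)))
    rtracklayer::export(gr, file.path(dir, paste0(safe, ".gff3")),
                        format = "gff3")
    prots <- do.call(c, unname(lapply(gs, `[[`, "proteins")))
    if (length(prots)) {
      aa <- Biostrings::AAStringSet(prots)
      Biostrings::writeXStringSet(aa, file.path(dir, paste0(safe, ".faa")))
    }
  }
  if (!is.null(pop$truth))
    write_truth_table(pop$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Read annotated replicons
#'
#' Parses a nucleotide FASTA, its GFF3 annotation (1-based inclusive
#' coordinates, converted to the 0-based half-open internal convention) and
#' the protein FASTA keyed by CDS id into [genome_record()] objects.
#'
#' @param fasta,gff,proteins file paths.
#' @return named list of `GenomeRecord` (`strain/replicon`).
#' @export
read_genome <- function(fasta, gff, proteins) {
  # cheap structural validation so malformed lines are reported by number
  lines <- readLines(gff)
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (grepl("^#", ln) || !nzchar(trimws(ln))) next
    if (length(strsplit(ln, "\t", fixed = TRUE)[[1]]) != 9L)
      stop(sprintf("malformed GFF3 line %d: expected 9 tab-separated fields",
                   i))
  }
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- vapply(strsplit(names(seqs), " "), `[`, "", 1L)
  prots <- Biostrings::readAAStringSet(proteins)
  prot_v <- stats::setNames(as.character(prots),
                            vapply(strsplit(names(prots), " "), `[`, "", 1L))
  gr <- rtracklayer::import(gff, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  out <- list()
  for (sid in unique(df$seqnames)) {
    if (!sid %in% names(seqs))
      stop("GFF3 references replicon absent from FASTA: ", sid)
    sub <- df[df$seqnames == sid, , drop = FALSE]
    reg <- sub[sub$type == "region", , drop = FALSE]
    topology <- if (nrow(reg) && !is.null(reg$Is_circular) &&
                    isTRUE(reg$Is_circular[1] == "true")) "circular"
                else "linear"
    role <- if (nrow(reg) && !is.null(reg$replicon_role) &&
                !is.na(reg$replicon_role[1])) reg$replicon_role[1]
            else "chromosome"
    feat <- sub[sub$type %in% c("CDS", "tRNA"), , drop = FALSE]
    features <- data.frame(
      id = as.character(feat$ID), type = as.character(feat$type),
      start0 = feat$start - 1L, end0 = feat$end,
      strand = ifelse(feat$strand %in% c("+", "-"), feat$strand, "+"),
      product = ifelse(is.na(feat$product %||% NA), "",
                       as.character(feat$product)),
      stringsAsFactors = FALSE)
    features <- features[order(features$start0, features$end0), ,
                         drop = FALSE]
    rownames(features) <- NULL
    cds <- features$id[features$type == "CDS"]
    missing <- setdiff(cds, names(prot_v))
    if (length(missing))
      warning("CDS without protein sequence: ",
              paste(utils::head(missing, 5), collapse = ", "),
              if (length(missing) > 5) " ..." else "")
    parts <- strsplit(sid, ":", fixed = TRUE)[[1]]
    strain <- parts[1]
    replicon <- if (length(parts) > 1) paste(parts[-1], collapse = ":")
                else parts[1]
    out[[paste0(strain, "/", replicon)]] <-
      genome_record(strain, replicon, as.character(seqs[[sid]]), features,
                    prot_v[intersect(cds, names(prot_v))],
                    topology = topology, role = role)
  }
  out
}

#' Read a whole population directory written by [write_population()]
#'
#' @param dir directory containing `<strain>.fna/.gff3/.faa` trios.
#' @return named list of `GenomeRecord`.
#' @export
read_population <- function(dir) {
  fnas <- list.files(dir, pattern = "\\.fna$", full.names = TRUE)
  out <- list()
  for (f in fnas) {
    base <- sub("\\.fna$", "", f)
    out <- c(out, read_genome(f, paste0(base, ".gff3"),
                              paste0(base, ".faa")))
  }
  out
}

#' Export classified elements as GFF3
#'
#' One `mobile_genetic_element` feature per delimited element, with class,
#' insertion site and family attributes.
#' @param elements element data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_elements_gff3 <- function(elements, path) {
  el <- elements[!is.na(elements$start0), , drop = FALSE]
  if (!nrow(el)) { writeLines("##gff-version 3", path); return(invisible(path)) }
  gr <- GenomicRanges::GRanges(
    seqnames = .seqid(el$strain, el$replicon),
    ranges = IRanges::IRanges(start = el$start0 + 1L, end = el$end0),
    strand = "+")
  S4Vectors::mcols(gr)$type <- "mobile_genetic_element"
  S4Vectors::mcols(gr)$ID <- el$element_id
  S4Vectors::mcols(gr)$mobile_element_class <- el$element_class
  S4Vectors::mcols(gr)$insertion_site <- paste0(el$site_kind, ":",
                                                el$site_name)
  S4Vectors::mcols(gr)$family <- ifelse(is.na(el$family_id), ".",
                                        el$family_id)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
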