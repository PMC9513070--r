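# Cargo-gene extraction, pseudogenization statistics against the 150-aa
# threshold, and functional categorisation from product annotations.

MOBILITY_KEYWORDS <- paste0(
  "integrase|recombinase|excisionase|relaxase|coupling protein|",
  "VirB4|secretion ATPase|conjugal transfer|spread protein|",
  "replication initiator|segregation actin|ATP/GTP-binding")

#' Extract cargo genes from a delimited element
#'
#' Cargo genes are all CDS lying entirely within the element bounds minus
#' the detected signature-role genes and genes of the mobility modules
#' (excisionase, spread, conjugal transfer and related products identified
#' by annotation keywords).
#'
#' @param element one-row element data.frame with `start0`, `end0`,
#'   `element_id`, `replicon`.
#' @param features feature data.frame of the element's replicon.
#' @param proteins named proteome of the replicon.
#' @param signature_ids protein ids of the element's signature hits.
#' @return data.frame of `CargoGene` rows: `gene_id`, `element_id`,
#'   `protein_length`, `product`, `is_short` (filled by
#'   [pseudogene_stats()] callers via the 150-aa default).
#' @export
extract_cargo <- function(element, features, proteins,
                          signature_ids = character(0)) {
  stopifnot(!is.na(element$start0), !is.na(element$end0))
  cds <- features[features$type == "CDS" &
                    features$start0 >= element$start0 &
                    features$end0 <= element$end0, , drop = FALSE]
  cds <- cds[!(cds$id %in% signature_ids), , drop = FALSE]
  cds <- cds[!grepl(MOBILITY_KEYWORDS, cds$product, ignore.case = TRUE), ,
             drop = FALSE]
  if (!nrow(cds))
    return(data.frame(gene_id = character(), element_id = character(),
                      protein_length = integer(), product = character(),
                      is_short = logical(), stringsAsFactors = FALSE))
  len <- nchar(proteins[cds$id])
  data.frame(gene_id = cds$id, element_id = element$element_id,
             protein_length = unname(len), product = cds$product,
             is_short = unname(len) < 150L, stringsAsFactors = FALSE)
}

#' Deduplicate a cargo set by exact protein sequence
#'
#' Unique-gene counting across an element set: genes with byte-identical
#' protein sequences collapse to one representative (the first occurrence).
#'
#' @param cargo cargo data.frame (rows from [extract_cargo()]).
#' @param proteins named character vector covering all `gene_id`s.
#' @return the deduplicated cargo data.frame.
#' @export
dedup_cargo <- function(cargo, proteins) {
  if (!nrow(cargo)) return(cargo)
  seqs <- proteins[cargo$gene_id]
  out <- cargo[!duplicated(seqs), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pseudogenization statistics for a cargo set
#'
#' @param cargo cargo data.frame with `protein_length`.
#' @param threshold pseudogene length threshold in amino acids.
#' @param background_fraction genome-wide fraction of short CDS used as the
#'   comparison baseline.
#' @param label element-set label carried into the report.
#' @return list of class `PseudogeneReport`: `label`, `n_cargo`, `n_short`,
#'   `fraction_short`, `background_fraction`, `ratio` (NA and flag
#'   `undefined = TRUE` when the cargo set is empty).
#' @export
pseudogene_stats <- function(cargo, threshold = 150,
                             background_fraction = NA_real_,
                             label = "cargo") {
  stopifnot(threshold > 0)
  n <- nrow(cargo)
  ns <- if (n) sum(cargo$protein_length < threshold) else 0L
  fr <- if (n > 0) ns / n else NA_real_
  structure(list(label = label, n_cargo = n, n_short = ns,
                 fraction_short = fr,
                 background_fraction = background_fraction,
                 ratio = if (!is.na(fr) && !is.na(background_fraction) &&
                             background_fraction > 0)
                   fr / background_fraction else NA_real_,
                 undefined = n == 0L),
            class = "PseudogeneReport")
}

#' Default cargo-category keyword table
#'
#' Priority-ordered regular-expression rules mapping product annotations to
#' the nine functional categories; the first matching rule wins and
#' unmatched products fall back to `hypothetical`.
#' @return data.frame with `pattern` and `category`.
#' @export
default_category_keywords <- function() {
  data.frame(
    pattern = c("transposase",
                "toxin|antitoxin",
                "phage|terminase|portal|abortive|restriction endonuclease",
                "phosphotransferase|lactamase|efflux|resistance",
                "transcriptional regulator|sigma factor|repressor",
                "protein kinase|cyclase|cyclic nucleotide|signal",
                "radA|ligase|primase|DNA-binding|DNA repair|methyltransferase|nuclease|recombination",
                "oxidoreductase|hydrolase|reductase|dehydrogenase|synthase|flavoprotein"),
    category = c("transposase", "toxin/antitoxin", "phage", "resistance",
                 "regulation", "signaling", "DNA metabolism", "metabolism"),
    stringsAsFactors = FALSE)
}

#' Categorise cargo genes from product annotations
#'
#' Assigns each cargo gene the category of the first matching keyword rule
#' (case-insensitive); products matching no rule become `hypothetical`.
#' Following the length convention of the census, only cargo of at least
#' `min_aa` amino acids is categorised unless `min_aa = 0`.
#'
#' @param cargo cargo data.frame with `product` and `protein_length`.
#' @param annotation_map keyword table as in [default_category_keywords()].
#' @param min_aa minimum protein length categorised (default 150).
#' @return list with `cargo` (input rows gaining a `category` column;
#'   length-filtered) and `counts` (named category counts over the full
#'   nine-category vocabulary).
#' @export
categorize_cargo <- function(cargo, annotation_map = default_category_keywords(),
                             min_aa = 150) {
  if (!all(annotation_map$category %in% CARGO_CATEGORIES))
    stop("unknown category in annotation map: ",
         paste(setdiff(annotation_map$category, CARGO_CATEGORIES),
               collapse = ", "))
  keep <- cargo[cargo$protein_length >= min_aa, , drop = FALSE]
  cat_of <- function(prod) {
    for (i in seq_len(nrow(annotation_map))) {
      if (grepl(annotation_map$pattern[i], prod, ignore.case = TRUE))
        return(annotation_map$category[i])
    }
    "hypothetical"
  }
  keep$category <- vapply(keep$product, cat_of, "", USE.NAMES = FALSE)
  counts <- table(factor(keep$category, levels = CARGO_CATEGORIES))
  list(cargo = keep, counts = stats::setNames(as.integer(counts),
                                              CARGO_CATEGORIES))
}
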