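# Grouping signature hits into candidate elements, classification into
# ICE/DICE/IME/AICE/DAICE/remnant, extrachromosomal filtering, and
# insertion-site assignment.

#' Group signature hits into candidate elements
#'
#' Hits on one replicon are chained left-to-right while the gap between
#' consecutive hits stays within `max_span_ice`; a chain is additionally
#' closed after each transfer-module terminator: a traB hit, a virb4 hit,
#' or a coupling-protein hit not followed closely by a virb4. This reflects
#' the canonical module order of integrative elements (recombination module
#' at the att-proximal edge, transfer pore distal), so tandem elements at
#' one site are parsed into separate candidates.
#'
#' @param hits signature-hit data.frame (sorted output of
#'   [scan_proteome()] / [merge_hits()]).
#' @param max_span_ice,max_span_aice chaining caps in bp.
#' @return list of `CandidateElement` objects: `replicon`, `anchor`
#'   (`c(start0, end0)` hull of the hit genes), `hits` (data.frame rows),
#'   `roles_present`.
#' @export
group_hits <- function(hits, max_span_ice = 120000, max_span_aice = 50000) {
  if (!nrow(hits)) return(list())
  hits <- hits[order(hits$replicon, hits$start0), , drop = FALSE]
  out <- list()
  for (repl in unique(hits$replicon)) {
    h <- hits[hits$replicon == repl, , drop = FALSE]
    i <- 1L
    cur <- integer(0)
    close_cand <- function(rows) {
      if (!length(rows)) return()
      hh <- h[rows, , drop = FALSE]
      out[[length(out) + 1L]] <<- structure(
        list(replicon = repl,
             anchor = c(min(hh$start0), max(hh$end0)),
             hits = hh, roles_present = unique(hh$role)),
        class = "CandidateElement")
    }
    while (i <= nrow(h)) {
      if (length(cur)) {
        gap <- h$start0[i] - max(h$end0[cur])
        if (gap > max_span_ice) { close_cand(cur); cur <- integer(0) }
      }
      cur <- c(cur, i)
      role <- h$role[i]
      terminator <- role == "traB" || role == "virb4" ||
        (role == "coupling" &&
           !(i < nrow(h) && h$role[i + 1L] == "virb4" &&
               h$start0[i + 1L] - h$end0[i] <= 5000))
      if (terminator) { close_cand(cur); cur <- integer(0) }
      i <- i + 1L
    }
    close_cand(cur)
  }
  out
}

#' Classification rule table
#'
#' Pure function from the signature-role content to the element class:
#' \itemize{
#'   \item traB and virb4 together: `"ambiguous"` (both module systems at
#'     one locus; reported with both tentative classes).
#'   \item traB present: AICE when rep and a functional integrase are also
#'     present, otherwise DAICE.
#'   \item virb4 present (no traB): ICE when functional integrase, relaxase
#'     and coupling protein are all present, otherwise DICE.
#'   \item relaxase present, no virb4/traB: IME (integrase optional).
#'   \item no transfer role: remnant when flanking repeats (and typically
#'     cargo) remain, otherwise `"unclassified"`.
#' }
#'
#' @param roles character vector of role tags present.
#' @param repeat_present is a flanking direct repeat available?
#' @param int_functional is at least one integrase intact (not interrupted)?
#' @return class label.
#' @export
classify_from_roles <- function(roles, repeat_present = TRUE,
                                int_functional = TRUE) {
  has <- function(x) any(x %in% roles)
  has_int <- has(c("integrase_tyr", "integrase_ser")) && int_functional
  if (has("traB") && has("virb4")) return("ambiguous")
  if (has("traB")) {
    return(if (has("rep") && has_int) "AICE" else "DAICE")
  }
  if (has("virb4")) {
    return(if (has_int && has("relaxase") && has("coupling")) "ICE"
           else "DICE")
  }
  if (has("relaxase")) return("IME")
  if (repeat_present) "remnant" else "unclassified"
}

# integrase interruption: profile coverage below the cutoff and a
# transposase annotated within `interrupt_genes` genes of the integrase
.int_interrupted <- function(cand, features, config) {
  ints <- cand$hits[grepl("integrase", cand$hits$role), , drop = FALSE]
  if (!nrow(ints)) return(FALSE)
  low <- ints$query_coverage < config$interrupt_coverage
  if (!any(low)) return(FALSE)
  if (is.null(features)) return(FALSE)
  cds <- features[features$type == "CDS", , drop = FALSE]
  cds <- cds[order(cds$start0), , drop = FALSE]
  tnp <- grepl("transposase", cds$product, ignore.case = TRUE)
  if (!any(tnp)) return(FALSE)
  for (i in which(low)) {
    gi <- match(ints$protein_id[i], cds$id)
    if (is.na(gi)) next
    near <- which(tnp & abs(seq_len(nrow(cds)) - gi) <= config$interrupt_genes)
    if (length(near)) return(TRUE)
  }
  FALSE
}

#' Classify a candidate element
#'
#' Applies the rule table of [classify_from_roles()], detecting interrupted
#' integrases (low profile coverage with an adjacent annotated transposase)
#' and the short-TraB tripartite arrangement (TraB under
#' `config$tripartite_max_aa` amino acids with ParM and ATP/GTP-binding
#' hits within `config$tripartite_genes` genes).
#'
#' @param candidate a `CandidateElement` from [group_hits()].
#' @param rep one-row repeat data.frame (or NULL when no flanking repeat
#'   was found).
#' @param features feature table of the replicon (for the transposase and
#'   gene-distance checks); may be NULL.
#' @param proteins named proteome (for TraB length); may be NULL.
#' @param config pipeline configuration.
#' @return list of class `ClassifiedElement`: `element_class`, `bounds`
#'   (NULL when undelimited), `repeat.`, `roles_present`, `flags`,
#'   `replicon`, `anchor`, `hits`.
#' @export
classify_element <- function(candidate, rep = NULL, features = NULL,
                             proteins = NULL, config = pipeline_config()) {
  stopifnot(length(candidate$roles_present) >= 1)
  flags <- character(0)
  interrupted <- .int_interrupted(candidate, features, config)
  if (interrupted) flags <- c(flags, "interrupted_integrase")
  cls <- classify_from_roles(candidate$roles_present,
                             repeat_present = !is.null(rep),
                             int_functional = !interrupted)
  if (cls == "ambiguous")
    flags <- c(flags, "ambiguous:AICE|ICE")
  # tripartite short-TraB arrangement
  tb <- candidate$hits[candidate$hits$role == "traB", , drop = FALSE]
  if (nrow(tb) && !is.null(proteins) && !is.null(features)) {
    tlen <- nchar(proteins[tb$protein_id[1]])
    if (!is.na(tlen) && tlen < config$tripartite_max_aa) {
      cds <- features[features$type == "CDS", , drop = FALSE]
      cds <- cds[order(cds$start0), , drop = FALSE]
      gi <- match(tb$protein_id[1], cds$id)
      sat <- candidate$hits$role %in% c("parM", "atp_gtp_binding")
      if (!is.na(gi) && sum(sat) >= 2) {
        si <- match(candidate$hits$protein_id[sat], cds$id)
        if (all(!is.na(si)) && all(abs(si - gi) <= config$tripartite_genes))
          flags <- c(flags, "tripartite_candidate")
      }
    }
  }
  bounds <- NULL
  if (!is.null(rep))
    bounds <- delineate_element(candidate$anchor, rep)$bounds
  structure(list(element_class = cls, bounds = bounds, rep = rep,
                 roles_present = candidate$roles_present, flags = flags,
                 replicon = candidate$replicon, anchor = candidate$anchor,
                 hits = candidate$hits),
            class = "ClassifiedElement")
}

#' Filter extrachromosomal TraB elements
#'
#' TraB-anchored elements located on plasmid replicons and lacking flanking
#' direct repeats are moved to the discarded set (flag `plasmid_borne`);
#' everything else (including plasmid-borne ICEs with a complete
#' conjugation module) is kept.
#'
#' @param elements element data.frame (see [call_elements()]).
#' @param genomes list of [genome_record()] (for replicon roles).
#' @return list with `kept` and `discarded` data.frames.
#' @export
filter_extrachromosomal <- function(elements, genomes) {
  if (!nrow(elements)) return(list(kept = elements, discarded = elements))
  roles <- vapply(genomes, `[[`, "", "role")
  keys <- vapply(genomes, function(g) paste0(g$strain, "/", g$replicon), "")
  role_of <- stats::setNames(roles, keys)
  is_plasmid <- role_of[paste0(elements$strain, "/",
                               elements$replicon)] == "plasmid"
  if (anyNA(is_plasmid)) stop("replicon role unknown for some elements")
  traB <- grepl("\\btraB\\b", elements$roles_present)
  no_rep <- is.na(elements$repeat_length)
  drop <- is_plasmid & traB & no_rep
  discarded <- elements[drop, , drop = FALSE]
  if (nrow(discarded))
    discarded$flags <- paste0(discarded$flags,
                              ifelse(nzchar(discarded$flags), ";", ""),
                              "plasmid_borne")
  kept <- elements[!drop, , drop = FALSE]
  kept$flags[is_plasmid[!drop]] <-
    paste0(kept$flags[is_plasmid[!drop]],
           ifelse(nzchar(kept$flags[is_plasmid[!drop]]), ";", ""),
           "plasmid_borne")
  rownames(kept) <- rownames(discarded) <- NULL
  list(kept = kept, discarded = discarded)
}

#' Assign the insertion-site type of a delimited element
#'
#' The site is `tRNA` when a repeat copy overlaps a tRNA feature, else
#' `CDS` when it overlaps a protein-coding feature (the name is the
#' product), else `intergenic` (name `"-"`). For elements in accretion
#' stacks whose own repeat copies lie between stacked elements, the
#' outermost left repeat copy of the stack (supplied via `outer_left`)
#' carries the site identity.
#'
#' @param element one-row element data.frame with `rep_left_start0` /
#'   `rep_left_end0` (and `rep_right_*`).
#' @param features feature data.frame of the replicon.
#' @param outer_left optional `c(start0, end0)` of the outermost left
#'   repeat copy of the element's accretion stack.
#' @return list `(kind, name)`.
#' @export
assign_insertion_site <- function(element, features, outer_left = NULL) {
  copies <- list(c(element$rep_left_start0, element$rep_left_end0),
                 c(element$rep_right_start0, element$rep_right_end0))
  if (!is.null(outer_left)) copies <- c(list(outer_left), copies)
  copies <- Filter(function(x) !anyNA(x), copies)
  if (!length(copies)) return(list(kind = "intergenic", name = "-"))
  ov <- function(type) {
    f <- features[features$type == type, , drop = FALSE]
    if (!nrow(f)) return(NA_character_)
    for (cp in copies) {
      hit <- which(f$start0 < cp[2] & f$end0 > cp[1])
      if (length(hit)) return(f$product[hit[1]])
    }
    NA_character_
  }
  t <- ov("tRNA")
  if (!is.na(t)) return(list(kind = "tRNA", name = t))
  c2 <- ov("CDS")
  if (!is.na(c2)) return(list(kind = "CDS", name = c2))
  list(kind = "intergenic", name = "-")
}
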