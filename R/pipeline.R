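# End-to-end orchestration: screen -> group -> delimit -> classify ->
# filter -> accretion/sites -> families -> cargo -> population reports.

.empty_elements <- function() {
  data.frame(element_id = character(), strain = character(),
             replicon = character(), element_class = character(),
             anchor_start0 = integer(), anchor_end0 = integer(),
             start0 = integer(), end0 = integer(), span = integer(),
             repeat_length = integer(), repeat_mismatches = integer(),
             rep_left_start0 = integer(), rep_left_end0 = integer(),
             rep_right_start0 = integer(), rep_right_end0 = integer(),
             rep_seq = character(), att_anchored = logical(),
             roles_present = character(), traB_protein = character(),
             hit_ids = character(), site_kind = character(),
             site_name = character(), family_id = character(),
             flags = character(), stringsAsFactors = FALSE)
}

#' Delimit and classify candidate elements across a genome set
#'
#' For every candidate produced by [group_hits()], searches for flanking
#' direct repeats around the signature anchor (window
#' `config$search_radius`, widened to `config$fallback_radius` when nothing
#' significant is found), filters them by chance significance / tRNA
#' anchoring, delimits the element with the top-ranked repeat and applies
#' the classification rule table.
#'
#' @param genomes named list of [genome_record()] (`strain/replicon`).
#' @param hits signature-hit data.frame.
#' @param config pipeline configuration.
#' @return element data.frame, one row per candidate (delimited or not).
#' @export
call_elements <- function(genomes, hits, config = pipeline_config()) {
  cands <- group_hits(hits, config$max_span_ice, config$max_span_aice)
  if (!length(cands)) return(.empty_elements())
  by_repl <- stats::setNames(genomes,
                             vapply(genomes, function(g)
                               paste0(g$strain, "/", g$replicon), ""))
  rows <- list()
  counter <- integer(0)
  for (cand in cands) {
    g <- by_repl[[cand$replicon]]
    if (is.null(g)) next
    top <- NULL
    for (radius in unique(c(config$search_radius, config$fallback_radius))) {
      reps <- find_flanking_repeats(g$seq, cand$anchor, radius,
                                    min_len = config$min_repeat,
                                    max_mismatch_rate = config$max_mismatch_rate,
                                    seed_k = config$seed_k,
                                    mismatch_penalty = config$repeat_mismatch_penalty)
      reps <- filter_repeats(reps, g$features, alpha = config$repeat_alpha,
                             trna_tail = config$trna_tail)
      if (nrow(reps)) { top <- reps[1, , drop = FALSE]; break }
    }
    ce <- classify_element(cand, top, g$features, g$proteins, config)
    key <- paste0(g$strain, ".", g$replicon)
    cur <- if (key %in% names(counter)) counter[[key]] else 0L
    counter[key] <- cur + 1L
    tbid <- cand$hits$protein_id[cand$hits$role == "traB"]
    rows[[length(rows) + 1L]] <- data.frame(
      element_id = sprintf("%s.e%02d", key, counter[key]),
      strain = g$strain, replicon = g$replicon,
      element_class = ce$element_class,
      anchor_start0 = cand$anchor[1], anchor_end0 = cand$anchor[2],
      start0 = if (is.null(ce$bounds)) NA_integer_ else ce$bounds[1],
      end0 = if (is.null(ce$bounds)) NA_integer_ else ce$bounds[2],
      span = if (is.null(ce$bounds)) NA_integer_ else
        ce$bounds[2] - ce$bounds[1],
      repeat_length = if (is.null(top)) NA_integer_ else top$length,
      repeat_mismatches = if (is.null(top)) NA_integer_ else top$mismatches,
      rep_left_start0 = if (is.null(top)) NA_integer_ else top$left_start0,
      rep_left_end0 = if (is.null(top)) NA_integer_ else top$left_end0,
      rep_right_start0 = if (is.null(top)) NA_integer_ else top$right_start0,
      rep_right_end0 = if (is.null(top)) NA_integer_ else top$right_end0,
      rep_seq = if (is.null(top)) NA_character_ else top$seq_left,
      att_anchored = if (is.null(top)) FALSE else isTRUE(top$att_anchored),
      roles_present = paste(sort(cand$roles_present), collapse = ","),
      traB_protein = if (length(tbid)) tbid[1] else NA_character_,
      hit_ids = paste(cand$hits$protein_id, collapse = ","),
      site_kind = NA_character_, site_name = NA_character_,
      family_id = NA_character_,
      flags = paste(ce$flags, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows) %||% .empty_elements()
  out <- out[order(out$strain, out$replicon, out$anchor_start0), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# site assignment across a population, honouring accretion stacks
.assign_sites <- function(elements, genomes, events) {
  by_key <- stats::setNames(genomes, names(genomes))
  for (i in seq_len(nrow(elements))) {
    el <- elements[i, ]
    g <- by_key[[paste0(el$strain, "/", el$replicon)]]
    if (is.null(g)) next
    outer_left <- NULL
    if (nrow(events)) {
      ev <- events[events$strain == el$strain &
                     events$replicon == el$replicon &
                     vapply(strsplit(events$element_ids, ","),
                            function(x) el$element_id %in% x, TRUE), ,
                   drop = FALSE]
      if (nrow(ev) && !is.na(ev$outer_left_start0[1]))
        outer_left <- c(ev$outer_left_start0[1], ev$outer_left_end0[1])
    }
    s <- assign_insertion_site(el, g$features, outer_left)
    elements$site_kind[i] <- s$kind
    elements$site_name[i] <- s$name
  }
  elements
}

# accretion detection + outermost-left-copy coordinates
.accretion_with_outer <- function(elements, genomes, config) {
  ev <- detect_accretion(elements, genomes,
                         accretion_gap = config$accretion_gap)
  if (!nrow(ev)) {
    ev$outer_left_start0 <- integer(0); ev$outer_left_end0 <- integer(0)
    return(ev)
  }
  ev$outer_left_start0 <- NA_integer_
  ev$outer_left_end0 <- NA_integer_
  for (i in seq_len(nrow(ev))) {
    ids <- strsplit(ev$element_ids[i], ",")[[1]]
    first <- elements[elements$element_id == ids[1], , drop = FALSE]
    if (!nrow(first) || is.na(first$rep_left_start0)) next
    l0 <- first$rep_left_start0; l1 <- first$rep_left_end0
    if (ev$remnant_present[i]) {
      g <- genomes[[paste0(ev$strain[i], "/", ev$replicon[i])]]
      pat <- substr0(g$seq, l0, l1)
      w0 <- max(0, l0 - 10000)
      win <- substr0(g$seq, w0, l0)
      hit <- gregexpr(pat, win, fixed = TRUE)[[1]]
      if (hit[1] != -1) {
        l0 <- w0 + hit[1] - 1L
        l1 <- l0 + nchar(pat)
      }
    }
    ev$outer_left_start0[i] <- l0
    ev$outer_left_end0[i] <- l1
  }
  ev
}

#' Run the full detection and comparative pipeline
#'
#' Stages: two-way signature screening (profile scan united with similarity
#' search), candidate grouping, direct-repeat delimitation, classification,
#' extrachromosomal filtering, accretion detection, insertion-site
#' assignment, TraB family clustering at the identity threshold,
#' cargo/pseudogene profiling, and population-level matrices with Fitch
#' parsimony when a cladogram is supplied.
#'
#' @param genomes named list of [genome_record()] (`strain/replicon`), e.g.
#'   from [generate_population()] or [read_population()].
#' @param tree optional newick cladogram over the strains.
#' @param config pipeline configuration.
#' @param out_dir optional directory for TSV/JSON reports.
#' @return list (report bundle): `hits`, `elements` (kept), `discarded`,
#'   `families`, `trab_tree`, `cargo`, `cargo_aice_unique`,
#'   `pseudogene_reports`, `category_counts`, `matrix`, `accretion`,
#'   `localization`, `parsimony`, `site_report`, `summary`.
#' @export
run_full_pipeline <- function(genomes, tree = NULL,
                              config = pipeline_config(), out_dir = NULL) {
  if (!length(genomes)) {
    summary <- list(n_elements = 0L, class_counts = integer(0))
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                           auto_unbox = TRUE, pretty = TRUE)
    }
    return(list(elements = .empty_elements(), summary = summary))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  profiles <- stage("screen", default_profiles(config$profile_bit_threshold))
  prof_hits <- stage("screen", scan_proteome(genomes, profiles, config))
  sim_hits <- stage("screen",
                    similarity_search(signature_seeds(), genomes,
                                      min_identity = config$min_identity,
                                      min_coverage = config$min_coverage,
                                      config = config))
  hits <- stage("screen", merge_hits(prof_hits, sim_hits))
  elements <- stage("call", call_elements(genomes, hits, config))
  elements <- elements[elements$element_class != "unclassified", ,
                       drop = FALSE]
  fl <- stage("filter", filter_extrachromosomal(elements, genomes))
  kept <- fl$kept; discarded <- fl$discarded
  events <- stage("accretion", .accretion_with_outer(kept, genomes, config))
  kept <- stage("sites", .assign_sites(kept, genomes, events))
  if (nrow(events)) {
    first_ids <- vapply(strsplit(events$element_ids, ","), `[`, "", 1L)
    events$site_name <- kept$site_name[match(first_ids, kept$element_id)]
  }
  # TraB families over kept traB-anchored elements
  proteome <- do.call(c, unname(lapply(genomes, `[[`, "proteins")))
  tb_idx <- which(!is.na(kept$traB_protein))
  families <- NULL; trab_tree <- NULL
  if (length(tb_idx) >= 1L) {
    tb_seqs <- proteome[kept$traB_protein[tb_idx]]
    names(tb_seqs) <- kept$traB_protein[tb_idx]
    im <- stage("families", identity_matrix(tb_seqs,
                                            gap_open = config$gap_open,
                                            gap_ext = config$gap_ext))
    families <- stage("families",
                      cluster_families(im, config$identity_threshold,
                                       seq_lengths = nchar(tb_seqs)))
    kept$family_id[tb_idx] <-
      families$family_id[match(kept$traB_protein[tb_idx], families$id)]
    if (length(tb_idx) >= 3L)
      trab_tree <- stage("families", neighbor_joining(im))
  }
  # cargo profiling
  by_key <- genomes
  cargo_rows <- list()
  for (i in which(!is.na(kept$start0))) {
    el <- kept[i, ]
    g <- by_key[[paste0(el$strain, "/", el$replicon)]]
    sig <- strsplit(el$hit_ids, ",")[[1]]
    cargo_rows[[length(cargo_rows) + 1L]] <-
      cbind(extract_cargo(el, g$features, g$proteins, sig),
            element_class = el$element_class, strain = el$strain,
            stringsAsFactors = FALSE)
  }
  cargo <- do.call(rbind, cargo_rows) %||%
    data.frame(gene_id = character(), element_id = character(),
               protein_length = integer(), product = character(),
               is_short = logical(), element_class = character(),
               strain = character(), stringsAsFactors = FALSE)
  genome_short_fraction <- {
    lens <- nchar(proteome)
    if (length(lens)) mean(lens < config$pseudogene_aa) else NA_real_
  }
  aice_cargo <- cargo[cargo$element_class == "AICE", , drop = FALSE]
  aice_unique <- dedup_cargo(aice_cargo, proteome)
  ps_aice <- pseudogene_stats(aice_unique, config$pseudogene_aa,
                              genome_short_fraction, "AICE cargo (unique)")
  ice_cargo <- cargo[cargo$element_class == "ICE", , drop = FALSE]
  ps_ice <- pseudogene_stats(ice_cargo, config$pseudogene_aa,
                             genome_short_fraction, "ICE cargo")
  cats <- categorize_cargo(rbind(aice_unique, ice_cargo),
                           min_aa = config$pseudogene_aa)
  # population-level
  all_strains <- unique(vapply(genomes, `[[`, "", "strain"))
  mat <- stage("population", build_matrix(kept[!is.na(kept$site_name), ,
                                               drop = FALSE],
                                          strains = all_strains))
  loc <- stage("population",
               core_arm_localization(kept, genomes, config$core_region,
                                     config))
  pars <- NULL
  if (!is.null(tree))
    pars <- stage("population", fitch_gain_loss(mat, tree))
  site_rep <- stage("population", site_occupancy_report(kept))
  role_of <- stats::setNames(
    vapply(genomes, `[[`, "", "role"),
    vapply(genomes, function(g) paste0(g$strain, "/", g$replicon), ""))
  traB_chrom <- sum(!is.na(kept$traB_protein) &
                      role_of[paste0(kept$strain, "/",
                                     kept$replicon)] == "chromosome" &
                      !is.na(kept$repeat_length))
  cls <- c("AICE", "DAICE", "ICE", "DICE", "IME")
  class_counts <- vapply(cls, function(k)
    sum(kept$element_class == k), 0L)
  summary <- list(
    n_strains = length(unique(vapply(genomes, `[[`, "", "strain"))),
    class_counts = as.list(class_counts),
    n_elements = sum(class_counts),
    n_remnants = sum(kept$element_class == "remnant"),
    n_discarded_plasmid_traB = nrow(discarded),
    traB_chromosomal = traB_chrom,
    n_families = if (is.null(families)) 0L else
      length(unique(families$family_id)),
    n_singleton_families = if (is.null(families)) 0L else
      sum(tapply(families$id, families$family_id, length) == 1L),
    site_kind_counts = as.list(site_rep$kind_counts),
    max_repeat_traB = if (any(!is.na(kept$traB_protein)))
      max(kept$repeat_length[!is.na(kept$traB_protein)], na.rm = TRUE)
      else NA_integer_,
    aice_cargo_unique = ps_aice$n_cargo,
    aice_cargo_short = ps_aice$n_short,
    ice_cargo = ps_ice$n_cargo, ice_cargo_short = ps_ice$n_short,
    genome_short_fraction = genome_short_fraction,
    thresholds = unclass(config)[c("identity_threshold", "pseudogene_aa",
                                   "evalue_cutoff", "min_coverage",
                                   "max_mismatch_rate", "min_repeat",
                                   "repeat_alpha", "search_radius",
                                   "max_span_ice", "max_span_aice")])
  bundle <- list(hits = hits, elements = kept, discarded = discarded,
                 families = families, trab_tree = trab_tree, cargo = cargo,
                 cargo_aice_unique = aice_unique,
                 pseudogene_reports = list(AICE = ps_aice, ICE = ps_ice),
                 category_counts = cats$counts, matrix = mat,
                 accretion = events, localization = loc, parsimony = pars,
                 site_report = site_rep, summary = summary)
  if (!is.null(out_dir)) .write_reports(bundle, out_dir)
  bundle
}


.write_reports <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) utils::write.table(x, file.path(out_dir, f),
                                          sep = "\t", quote = FALSE,
                                          row.names = FALSE)
  wt(bundle$hits, "hits.tsv")
  wt(bundle$elements, "elements.tsv")
  wt(bundle$discarded, "discarded.tsv")
  if (!is.null(bundle$families)) wt(bundle$families, "families.tsv")
  if (!is.null(bundle$trab_tree))
    writeLines(bundle$trab_tree, file.path(out_dir, "trab_nj.nwk"))
  wt(bundle$cargo, "cargo.tsv")
  wt(bundle$accretion, "accretion.tsv")
  wt(as.data.frame(bundle$localization$counts), "localization.tsv")
  if (!is.null(bundle$parsimony)) wt(bundle$parsimony, "parsimony.tsv")
  utils::write.table(unclass(bundle$matrix),
                     file.path(out_dir, "matrix.tsv"), sep = "\t",
                     quote = FALSE, col.names = NA)
  export_elements_gff3(bundle$elements,
                       file.path(out_dir, "elements.gff3"))
  jsonlite::write_json(bundle$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
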