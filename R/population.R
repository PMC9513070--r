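# Cross-strain comparative analyses: presence/absence matrices, accretion
# detection, core-versus-arm localisation and Fitch/Sankoff small parsimony
# on a supplied strain cladogram.

#' Family-by-site presence/absence matrix
#'
#' One column per locus, where a locus is a `(family, site)` pair for
#' TraB-anchored families and a `(class, site)` pair for ICE-type elements;
#' one row per strain.
#'
#' @param elements element data.frame with `strain`, `family_id`,
#'   `element_class`, `site_name`.
#' @param strains optional strain ordering (defaults to order of
#'   appearance).
#' @return binary matrix with strains as rows and `family@site` labels as
#'   columns; class `PopulationMatrix`.
#' @export
build_matrix <- function(elements, strains = NULL) {
  if (is.null(strains)) strains <- unique(elements$strain)
  fam <- ifelse(!is.na(elements$family_id), elements$family_id,
                elements$element_class)
  locus <- paste0(fam, "@", elements$site_name)
  loci <- unique(locus)
  m <- matrix(0L, nrow = length(strains), ncol = length(loci),
              dimnames = list(strains, loci))
  for (i in seq_len(nrow(elements)))
    m[elements$strain[i], locus[i]] <- 1L
  class(m) <- c("PopulationMatrix", class(m))
  m
}

#' Detect accretion events (tandem elements sharing one insertion site)
#'
#' Adjacent elements on one replicon whose gap is at most `accretion_gap`
#' and whose flanking repeat sequences are near-identical are grouped into
#' one event. A repeat-bounded cargo-only segment adjoining the stack (a
#' further identical repeat copy upstream of the outermost left repeat,
#' within `remnant_window`) flags a remnant.
#'
#' @param elements element data.frame (kept, delimited elements).
#' @param genomes list of [genome_record()] keyed by `strain/replicon`.
#' @param accretion_gap maximum gap (bp) between stacked elements.
#' @param remnant_window how far upstream to search for a remnant copy (bp).
#' @return data.frame of events: `strain`, `replicon`, `site_name`,
#'   `n_elements`, `element_ids` (comma-separated, left to right),
#'   `remnant_present`.
#' @export
detect_accretion <- function(elements, genomes, accretion_gap = 1000,
                             remnant_window = 10000) {
  ev <- list()
  el <- elements[!is.na(elements$start0), , drop = FALSE]
  for (key in unique(paste(el$strain, el$replicon))) {
    sub <- el[paste(el$strain, el$replicon) == key, , drop = FALSE]
    sub <- sub[order(sub$start0), , drop = FALSE]
    if (!nrow(sub)) next
    g <- genomes[[paste0(sub$strain[1], "/", sub$replicon[1])]]
    gaps <- sub$start0[-1] - utils::head(sub$end0, -1)
    same_rep <- rep(FALSE, max(0, nrow(sub) - 1))
    for (i in seq_len(nrow(sub) - 1L)) {
      a <- sub$rep_seq[i]; b <- sub$rep_seq[i + 1L]
      if (is.na(a) || is.na(b)) next
      same_rep[i] <- nchar(a) == nchar(b) &&
        sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]) <=
          ceiling(0.1 * nchar(a))
    }
    grp <- cumsum(c(1, !(gaps <= accretion_gap + 100 & same_rep)))
    for (gg in unique(grp)) {
      rows <- sub[grp == gg, , drop = FALSE]
      remnant <- FALSE
      # search for one further identical repeat copy upstream of the stack
      first <- rows[1, ]
      if (!is.na(first$rep_left_start0) && !is.null(g)) {
        l <- first$rep_left_end0 - first$rep_left_start0
        pat <- substr0(g$seq, first$rep_left_start0, first$rep_left_end0)
        w0 <- max(0, first$rep_left_start0 - remnant_window)
        win <- substr0(g$seq, w0, first$rep_left_start0)
        hit <- gregexpr(pat, win, fixed = TRUE)[[1]]
        remnant <- hit[1] != -1
      }
      if (nrow(rows) >= 2L || (nrow(rows) >= 1L && remnant)) {
        ev[[length(ev) + 1L]] <- data.frame(
          strain = rows$strain[1], replicon = rows$replicon[1],
          site_name = rows$site_name[1], n_elements = nrow(rows),
          element_ids = paste(rows$element_id, collapse = ","),
          remnant_present = remnant, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(ev))
    return(data.frame(strain = character(), replicon = character(),
                      site_name = character(), n_elements = integer(),
                      element_ids = character(), remnant_present = logical(),
                      stringsAsFactors = FALSE))
  do.call(rbind, ev)
}

#' Core-versus-arm localisation of chromosomal elements
#'
#' Each chromosomal element is assigned to the core region or to a terminal
#' arm by its midpoint; counts are tabulated by the functional/defective
#' roll-up (`config$functional_classes` count as functional; all other
#' classes, including mobilizable-dependent IMEs, as defective).
#'
#' @param elements element data.frame (with `start0`, `end0`, `replicon`,
#'   `element_class`).
#' @param genomes list of [genome_record()].
#' @param core_region `c(left_arm_bp, right_arm_bp)` measured from the
#'   chromosome ends.
#' @param config pipeline configuration.
#' @return list with `counts` (core_functional, core_defective,
#'   arm_functional, arm_defective), `by_class` (class x region table) and
#'   `elements` (input rows gaining `region` and `functional`).
#' @export
core_arm_localization <- function(elements, genomes, core_region,
                                  config = pipeline_config()) {
  keys <- vapply(genomes, function(g) paste0(g$strain, "/", g$replicon), "")
  role_of <- stats::setNames(vapply(genomes, `[[`, "", "role"), keys)
  len_of <- stats::setNames(vapply(genomes, function(g) nchar(g$seq), 0),
                            keys)
  el <- elements[!is.na(elements$start0), , drop = FALSE]
  ekey <- paste0(el$strain, "/", el$replicon)
  chrom <- role_of[ekey] == "chromosome"
  el <- el[chrom, , drop = FALSE]
  mid <- (el$start0 + el$end0) / 2
  L <- len_of[paste0(el$strain, "/", el$replicon)]
  region <- ifelse(mid < core_region[1], "arm",
                   ifelse(mid > L - core_region[2], "arm", "core"))
  functional <- el$element_class %in% config$functional_classes
  el$region <- region; el$functional <- functional
  counts <- c(core_functional = sum(region == "core" & functional),
              core_defective = sum(region == "core" & !functional),
              arm_functional = sum(region == "arm" & functional),
              arm_defective = sum(region == "arm" & !functional))
  by_class <- table(el$element_class, el$region)
  list(counts = counts, by_class = by_class, elements = el)
}

#' Fitch/Sankoff small parsimony for presence/absence loci
#'
#' Minimum-change count for each binary locus on the strain cladogram
#' (Sankoff dynamic programming over the two states, exact on arbitrary
#' multifurcating rooted trees). Polarity: the root state is chosen to
#' minimise the change count; when both root states attain the minimum the
#' locus polarity is reported as "ambiguous", otherwise gains (0 to 1) and
#' losses (1 to 0) are counted on one minimal labelling.
#'
#' @param matrix binary `PopulationMatrix` (strains x loci).
#' @param tree newick string or `ape::phylo` whose tip labels equal the
#'   matrix strains.
#' @return data.frame: `locus`, `min_changes`, `gains`, `losses`,
#'   `polarity` ("gain", "loss", "none" or "ambiguous").
#' @export
fitch_gain_loss <- function(matrix, tree) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (!setequal(tree$tip.label, rownames(matrix)))
    stop("tree tips and matrix strains differ")
  out <- lapply(colnames(matrix), function(lc) {
    states <- stats::setNames(matrix[, lc], rownames(matrix))
    r <- .sankoff_binary(tree, states)
    data.frame(locus = lc, min_changes = r$min_changes, gains = r$gains,
               losses = r$losses, polarity = r$polarity,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Sankoff DP for one binary character on an ape phylo.
.sankoff_binary <- function(tree, states) {
  nt <- length(tree$tip.label)
  nn <- tree$Nnode
  total <- nt + nn
  children <- vector("list", total)
  for (i in seq_len(nrow(tree$edge)))
    children[[tree$edge[i, 1]]] <- c(children[[tree$edge[i, 1]]],
                                     tree$edge[i, 2])
  root <- nt + 1L
  cost <- matrix(Inf, nrow = total, ncol = 2)
  # post-order via recursion
  visit <- function(v) {
    if (v <= nt) {
      s <- states[[tree$tip.label[v]]]
      cost[v, ] <<- c(if (s == 0) 0 else Inf, if (s == 1) 0 else Inf)
      return(invisible())
    }
    for (ch in children[[v]]) visit(ch)
    for (s in 1:2) {
      tot <- 0
      for (ch in children[[v]])
        tot <- tot + min(cost[ch, s], cost[ch, 3 - s] + 1)
      cost[v, s] <<- tot
    }
    invisible()
  }
  visit(root)
  min_changes <- min(cost[root, ])
  ambiguous <- cost[root, 1] == cost[root, 2]
  root_state <- which.min(cost[root, ]) - 1L
  # backtrack one minimal labelling
  lab <- integer(total)
  assign_state <- function(v, s) {
    lab[v] <<- s
    if (v <= nt) return(invisible())
    for (ch in children[[v]]) {
      keep <- cost[ch, s + 1]
      flip <- cost[ch, 2 - s] + 1
      assign_state(ch, if (keep <= flip) s else 1L - s)
    }
    invisible()
  }
  assign_state(root, root_state)
  gains <- 0L; losses <- 0L
  for (i in seq_len(nrow(tree$edge))) {
    a <- lab[tree$edge[i, 1]]; b <- lab[tree$edge[i, 2]]
    if (a == 0 && b == 1) gains <- gains + 1L
    if (a == 1 && b == 0) losses <- losses + 1L
  }
  polarity <- if (min_changes == 0) "none"
  else if (ambiguous) "ambiguous"
  else if (gains > 0 && losses == 0) "gain"
  else if (losses > 0 && gains == 0) "loss"
  else "mixed"
  list(min_changes = as.integer(min_changes), gains = gains,
       losses = losses, polarity = polarity)
}

#' Insertion-site occupancy report for TraB-anchored elements
#'
#' Counts insertion-site kinds over TraB-anchored (AICE/DAICE) elements and
#' lists, per site, the families present and the strains lacking an
#' occupant (empty sites available for further acquisition).
#'
#' @param elements element data.frame.
#' @param strains all strain ids of the population (for empty-site
#'   detection); defaults to the strains observed.
#' @return list with `kind_counts` (tRNA/CDS/intergenic), `per_site`
#'   (data.frame: site, kind, families, n_elements, strains_present,
#'   strains_absent).
#' @export
site_occupancy_report <- function(elements, strains = NULL) {
  tb <- elements[grepl("\\btraB\\b", elements$roles_present), , drop = FALSE]
  if (is.null(strains)) strains <- unique(elements$strain)
  kinds <- factor(tb$site_kind, levels = c("tRNA", "CDS", "intergenic"))
  kind_counts <- stats::setNames(as.integer(table(kinds)),
                                 c("tRNA", "CDS", "intergenic"))
  per_site <- do.call(rbind, lapply(unique(tb$site_name), function(s) {
    rows <- tb[tb$site_name == s, , drop = FALSE]
    data.frame(site = s, kind = rows$site_kind[1],
               families = paste(sort(unique(rows$family_id)), collapse = ","),
               n_elements = nrow(rows),
               strains_present = paste(sort(unique(rows$strain)),
                                       collapse = ","),
               strains_absent = paste(setdiff(strains, rows$strain),
                                      collapse = ","),
               stringsAsFactors = FALSE)
  }))
  list(kind_counts = kind_counts,
       per_site = per_site %||% data.frame())
}
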