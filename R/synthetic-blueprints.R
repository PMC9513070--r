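# Population blueprints: the declarative composition of a synthetic
# population (strains, replicons, insertion sites, planted element
# instances, cargo pools, TraB family structure, cladogram). A blueprint is
# purely declarative; generate_population() realises it with a seed.
#
# Composition (which classes, families, strains, sites) is part of the
# blueprint and therefore identical for every seed; only sequences and
# per-instance random details change with the seed.

#' Cargo specification
#'
#' @param n_cargo number of distinct cargo genes in a pool.
#' @param n_short number of them shorter than the pseudogene threshold
#'   (150 aa).
#' @param category_weights named numeric vector of functional-category
#'   probabilities (must sum to 1) used to draw products for the
#'   full-length cargo genes.
#' @return list of class `CargoSpec`.
#' @export
cargo_spec <- function(n_cargo, n_short,
                       category_weights = default_category_weights()) {
  stopifnot(n_short <= n_cargo, n_cargo >= 0)
  if (abs(sum(category_weights) - 1) > 1e-9)
    stop("category_weights must sum to 1")
  if (!all(names(category_weights) %in% CARGO_CATEGORIES))
    stop("unknown cargo category in weights")
  structure(list(n_cargo = as.integer(n_cargo),
                 n_short = as.integer(n_short),
                 category_weights = category_weights),
            class = "CargoSpec")
}

CARGO_CATEGORIES <- c("metabolism", "DNA metabolism", "resistance",
                      "regulation", "phage", "toxin/antitoxin", "signaling",
                      "transposase", "hypothetical")

#' Default cargo functional-category weights
#' @return named numeric vector over the nine functional categories.
#' @export
default_category_weights <- function() {
  c("hypothetical" = 0.35, "metabolism" = 0.12, "DNA metabolism" = 0.12,
    "regulation" = 0.10, "phage" = 0.08, "resistance" = 0.07,
    "signaling" = 0.06, "toxin/antitoxin" = 0.06, "transposase" = 0.04)
}

#' Element specification
#'
#' Declares one element type to be planted. Class/role consistency is
#' validated: an AICE must carry traB, rep and an integrase; an ICE carries
#' integrase, relaxase, coupling protein and VirB4; a DAICE carries traB but
#' lacks rep and/or integrase; a DICE carries VirB4 but lacks at least one
#' of integrase/coupling/relaxase; an IME carries a relaxase but no VirB4;
#' a remnant carries no transfer role at all.
#'
#' @param id spec identifier.
#' @param element_class one of ICE, DICE, IME, AICE, DAICE, remnant,
#'   plasmid_traB.
#' @param signature_roles character vector of role tags (see
#'   `SIGNATURE_ROLES`).
#' @param tsd_length target-site duplication length (nt, 2-94; 0 = planted
#'   without duplication, e.g. plasmid-native elements).
#' @param site_kind tRNA, CDS or intergenic.
#' @param site_name insertion-site label.
#' @param strains_carrying strain ids carrying the element.
#' @param traB_family_target family label (AICE-type) or NA.
#' @param cargo cargo specification, see [cargo_spec()].
#' @param accretion_group label shared by elements stacked at one site, or NA.
#' @return list of class `ElementSpec`.
#' @export
element_spec <- function(id, element_class, signature_roles, tsd_length,
                         site_kind, site_name, strains_carrying,
                         traB_family_target = NA, cargo = cargo_spec(10, 5),
                         accretion_group = NA) {
  element_class <- match.arg(element_class,
                             c("ICE", "DICE", "IME", "AICE", "DAICE",
                               "remnant", "plasmid_traB"))
  stopifnot(tsd_length == 0 || (tsd_length >= 2 && tsd_length <= 94))
  site_kind <- match.arg(site_kind, c("tRNA", "CDS", "intergenic"))
  r <- signature_roles
  has_int <- any(c("integrase_tyr", "integrase_ser") %in% r)
  ok <- switch(element_class,
    AICE = all(c("traB", "rep") %in% r) && has_int,
    DAICE = "traB" %in% r && !(all(c("rep") %in% r) && has_int),
    ICE = has_int && all(c("relaxase", "coupling", "virb4") %in% r),
    DICE = "virb4" %in% r &&
      !(has_int && all(c("coupling", "relaxase") %in% r)),
    IME = "relaxase" %in% r && !("virb4" %in% r),
    remnant = !any(c("traB", "virb4", "relaxase") %in% r),
    plasmid_traB = identical(unname(r), "traB") || "traB" %in% r)
  if (!ok) stop(sprintf("signature roles {%s} inconsistent with class %s",
                        paste(r, collapse = ","), element_class))
  structure(list(id = id, element_class = element_class,
                 signature_roles = r, tsd_length = as.integer(tsd_length),
                 site_kind = site_kind, site_name = site_name,
                 strains_carrying = strains_carrying,
                 traB_family_target = traB_family_target,
                 cargo_spec = cargo, accretion_group = accretion_group),
            class = "ElementSpec")
}

#' Re-derive an element specification after gene loss (decay)
#'
#' Drops signature roles from a specification and re-derives its class from
#' the remaining roles (AICE to DAICE, ICE to DICE, any element losing all
#' transfer roles to remnant). A surviving integrase can additionally be
#' truncated to model a partial integrase.
#'
#' @param spec an [element_spec()].
#' @param drop_roles roles to remove (must be present).
#' @param truncate_fraction fraction of the integrase length retained
#'   (1 = intact); recorded in the spec and honoured by the generator.
#' @return a new `ElementSpec` with re-derived class.
#' @export
#' @examples
#' a <- element_spec("a1", "AICE", c("integrase_tyr", "rep", "traB"),
#'                   20, "tRNA", "tRNA-Leu", "s1", "f01")
#' decay_element(a, "rep")$element_class   # DAICE
decay_element <- function(spec, drop_roles, truncate_fraction = 1) {
  stopifnot(inherits(spec, "ElementSpec"))
  if (!all(drop_roles %in% spec$signature_roles))
    stop("drop_roles must be a subset of the roles present")
  r <- setdiff(spec$signature_roles, drop_roles)
  new_class <- classify_from_roles(r, repeat_present = TRUE,
                                   int_functional = truncate_fraction >= 0.5)
  if (new_class %in% c("unclassified")) new_class <- "remnant"
  out <- spec
  out$signature_roles <- r
  out$element_class <- new_class
  out$int_truncation <- truncate_fraction
  out
}

#' Construct a population blueprint
#'
#' Low-level constructor; most users will call [reference_population()] or
#' [random_blueprint()]. See those functions for the table formats.
#'
#' @param strains strain ids.
#' @param replicons data.frame: `strain`, `replicon`, `length`, `topology`,
#'   `role`.
#' @param sites data.frame: `site_name`, `kind`, `pos`, `product` (chromosome
#'   insertion-site catalog; positions are background coordinates).
#' @param site_overrides data.frame: `strain`, `site_name`, `pos` (per-strain
#'   relocations, e.g. arm-located copies).
#' @param instances data.frame, one row per planted element instance:
#'   `instance_id`, `spec_id`, `family`, `class`, `strain`, `replicon`,
#'   `site_name`, `stack_order`, `tsd_len`, `roles` (comma-separated),
#'   `defect`, `cargo_pool`, `cargo_mode`, `int_identity`.
#' @param pools data.frame: `pool_id`, `n_cargo`, `n_short`.
#' @param families data.frame: `family`, `trab_len`, `tripartite`.
#' @param core_region `c(left_arm_bp, right_arm_bp)`.
#' @param cladogram newick string over the strain ids.
#' @param seed integer seed that fully determines the generated population.
#' @return list of class `PopulationBlueprint`.
#' @export
population_blueprint <- function(strains, replicons, sites, site_overrides,
                                 instances, pools, families, core_region,
                                 cladogram, seed = 42L) {
  stopifnot(all(instances$strain %in% strains),
            all(instances$tsd_len >= 0),
            all(instances$tsd_len == 0 | instances$tsd_len >= 2),
            all(instances$tsd_len <= 94),
            all(instances$cargo_pool %in% pools$pool_id),
            all(core_region >= 0))
  # planted sites must fit within their replicon
  rl <- stats::setNames(replicons$length,
                        paste(replicons$strain, replicons$replicon))
  for (i in seq_len(nrow(instances))) {
    inst <- instances[i, ]
    pos <- .site_position(sites, site_overrides, inst$strain, inst$site_name)
    if (inst$replicon != "chr") pos <- NA  # plasmid midpoints checked later
    len <- rl[[paste(inst$strain, inst$replicon)]]
    if (is.null(len)) stop("instance on unknown replicon: ", inst$instance_id)
    if (!is.na(pos) && (pos <= inst$tsd_len || pos >= len))
      stop("planted site does not fit replicon: ", inst$instance_id)
  }
  # reject overlapping (identical, non-stacked) insertion points
  key <- paste(instances$strain, instances$replicon, instances$site_name)
  for (k in unique(key)) {
    sub <- instances[key == k, , drop = FALSE]
    if (nrow(sub) > 1L && anyDuplicated(sub$stack_order))
      stop("overlapping planted sites: ",
           paste(sub$spec_id, collapse = " vs "))
  }
  structure(list(strains = strains, replicons = replicons, sites = sites,
                 site_overrides = site_overrides, instances = instances,
                 pools = pools, families = families,
                 core_region = as.numeric(core_region),
                 cladogram = cladogram, seed = as.integer(seed)),
            class = "PopulationBlueprint")
}

.site_position <- function(sites, overrides, strain, site_name) {
  if (!is.null(overrides) && nrow(overrides)) {
    hit <- overrides$strain == strain & overrides$site_name == site_name
    if (any(hit)) return(overrides$pos[hit][1])
  }
  hit <- sites$site_name == site_name
  if (any(hit)) sites$pos[hit][1] else NA_real_
}

#' The packaged reference-population blueprint
#'
#' Eleven closely related strains with one linear chromosome each (900 kb at
#' desk scale, arms of 180 kb and 105 kb devoid of planted functional
#' elements) and five plasmids. Planted composition: 43 AICEs and 8 DAICEs
#' (51 chromosomal traB anchors in 19 TraB families, 7 of them singletons;
#' insertion sites 36 tRNA / 14 CDS / 1 intergenic), 3 ICEs (two identical
#' 87-CDS chromosomal copies with a 93-nt target-site duplication at
#' tRNA-Thr, one plasmid-borne), 18 DICE occurrences of three types, 8 IME
#' occurrences (absent only in the RLB3-6/S1D4-23/S1A1-7 clade), one
#' conserved accretion-site remnant in every strain plus three decayed
#' remnants, and 4 divergent plasmid-borne TraB genes without direct
#' repeats. AICE cargo pools hold 445 distinct proteins, 223 of them shorter
#' than 150 aa; the chromosomal ICE carries 81 cargo genes, 19 of them
#' short.
#'
#' @param seed integer seed (fully determines sequences; composition is
#'   seed-invariant).
#' @param chromosome_length chromosome background length in bp. Positions of
#'   the insertion-site catalog and arm sizes scale proportionally.
#' @return a `PopulationBlueprint`.
#' @export
reference_population <- function(seed = 42L, chromosome_length = 900000L) {
  sc <- chromosome_length / 900000
  strains <- c("RLB1-8", "RLB3-5", "S1D4-14", "S1D4-20", "RLB3-17",
               "RLB1-9", "S1A1-3", "S1A1-8", "RLB3-6", "S1D4-23", "S1A1-7")
  cladogram <- paste0(
    "((((RLB1-8,RLB3-5),(S1D4-14,S1D4-20)),",
    "(RLB3-17,(RLB1-9,(S1A1-3,S1A1-8)))),",
    "(RLB3-6,(S1D4-23,S1A1-7)));")
  repl <- rbind(
    data.frame(strain = strains, replicon = "chr",
               length = as.integer(chromosome_length), topology = "linear",
               role = "chromosome", stringsAsFactors = FALSE),
    data.frame(strain = c("RLB3-6", "RLB1-8", "S1D4-20", "S1A1-3", "S1D4-23"),
               replicon = c("pRLB3-6.1", "pRLB1-8.1", "pS1D4-20.1",
                            "pS1A1-3.1", "pS1D4-23.1"),
               length = as.integer(c(60000, 35000, 30000, 32000, 28000) * sc),
               topology = c("circular", "linear", "circular", "linear",
                            "circular"),
               role = "plasmid", stringsAsFactors = FALSE))
  s <- function(name, kind, pos, product = "")
    data.frame(site_name = name, kind = kind, pos = as.integer(pos * sc),
               product = product, stringsAsFactors = FALSE)
  sites <- rbind(
    s("tRNA-Leu", "tRNA", 200000), s("dnaJ", "CDS", 243000,
      "molecular chaperone DnaJ"),
    s("tRNA-Val", "tRNA", 288000), s("rlmN", "CDS", 323000,
      "rlmN 23S rRNA methyltransferase"),
    s("tRNA-Ser", "tRNA", 360000), s("tRNA-Arg", "tRNA", 403000),
    s("glt", "CDS", 430000, "phospholipid carrier-dependent glycosyltransferase"),
    s("tRNA-Gly", "tRNA", 452000), s("tRNA-Thr", "tRNA", 497000),
    s("tRNA-Met", "tRNA", 545000), s("tRNA-Lys", "tRNA", 563000),
    s("abcT", "CDS", 600000, "ABC transporter permease"),
    s("tRNA-Cys", "tRNA", 620000), s("tRNA-Pro", "tRNA", 632000),
    s("mfsT", "CDS", 660000, "MFS transporter"),
    s("tRNA-Ile", "tRNA", 670000),
    s("acdH", "CDS", 688000, "acyl-CoA dehydrogenase"),
    s("senK", "CDS", 716000, "two-component sensor histidine kinase"),
    s("tRNA-Asp", "tRNA", 730000),
    s("cypA", "CDS", 744000, "cytochrome P450"),
    s("ig1", "intergenic", 762000))
  overrides <- data.frame(
    strain = c("RLB3-17", "RLB3-6", "S1D4-14"),
    site_name = c("tRNA-Ile", "tRNA-Cys", "tRNA-Asp"),
    pos = as.integer(c(90000, 90000, 840000) * sc),
    stringsAsFactors = FALSE)

  AICE_R <- "integrase_tyr,rep,traB"
  AICE_S <- "integrase_ser,rep,traB"
  rows <- list()
  add <- function(spec_id, family, class, strain, replicon, site, stack,
                  tsd, roles, defect = "none", pool, mode = "subset",
                  int_identity = NA) {
    rows[[length(rows) + 1L]] <<- data.frame(
      instance_id = sprintf("%s|%s", spec_id, strain), spec_id = spec_id,
      family = family, class = class, strain = strain, replicon = replicon,
      site_name = site, stack_order = as.integer(stack),
      tsd_len = as.integer(tsd), roles = roles, defect = defect,
      cargo_pool = pool, cargo_mode = mode, int_identity = int_identity,
      stringsAsFactors = FALSE)
  }
  aice_family <- function(family, site, tsd, carriers, full, roles = AICE_R,
                          stack = 0L, daice = character(),
                          daice_defect = "no_rep") {
    for (st in carriers) {
      if (st %in% daice) {
        r <- switch(daice_defect,
                    no_rep = sub("rep,", "", roles),
                    no_int = sub("integrase_(tyr|ser),", "", roles),
                    interrupted_int = roles)
        add(paste0(family, "d"), family, "DAICE", st, "chr", site, stack,
            tsd, r, daice_defect, family)
      } else {
        add(family, family, "AICE", st, "chr", site, stack, tsd, roles,
            "none", family, if (st == full) "full" else "subset")
      }
    }
  }
  aice_family("f01", "tRNA-Leu", 24, c("RLB1-8", "RLB3-5", "S1D4-14",
                                       "S1D4-20"), "RLB1-8")
  aice_family("f02", "dnaJ", 26, c("RLB1-8", "RLB3-5", "S1D4-14", "S1D4-20",
                                   "S1A1-7"), "RLB1-8", daice = "S1D4-20")
  # f03: two tRNA-Val copies sharing an integrase; a divergent-integrase
  # copy inserted in the rlmN coding sequence
  add("f03", "f03", "AICE", "S1A1-7", "chr", "tRNA-Val", 0, 46, AICE_R,
      "none", "f03", "full")
  add("f03", "f03", "AICE", "S1D4-23", "chr", "tRNA-Val", 0, 46, AICE_R,
      "none", "f03")
  add("f03r", "f03", "AICE", "RLB3-6", "chr", "rlmN", 0, 20, AICE_S,
      "none", "f03", "subset", int_identity = 55)
  aice_family("f04", "tRNA-Ser", 28, c("RLB1-8", "RLB3-5", "S1D4-14",
                                       "S1A1-7"), "RLB1-8",
              daice = "S1D4-14")
  # accretion stack at tRNA-Arg: conserved remnant leftmost in all strains
  for (st in strains)
    add("rem1", NA, "remnant", st, "chr", "tRNA-Arg", 1, 38, "", "none",
        "REM1", "full")
  aice_family("f05", "tRNA-Arg", 38, c("RLB1-8", "RLB3-5", "S1D4-14",
                                       "RLB1-9", "S1A1-3", "S1A1-8"),
              "RLB3-5", stack = 2L, daice = "RLB1-8")
  aice_family("f16", "tRNA-Arg", 38, c("RLB3-17", "S1D4-20"), "S1D4-20",
              stack = 2L)
  aice_family("f17", "tRNA-Arg", 38, c("RLB3-17", "S1D4-20"), "S1D4-20",
              stack = 3L, daice = "RLB3-17")
  aice_family("f18", "tRNA-Arg", 38, "S1D4-20", "S1D4-20", stack = 4L)
  add("f06", "f06", "AICE", "S1D4-23", "chr", "glt", 0, 32, AICE_R, "none",
      "f06", "full")
  aice_family("f07", "abcT", 22, c("RLB3-6", "S1D4-23", "S1A1-7"),
              "S1D4-23", daice = "RLB3-6")
  aice_family("f08", "tRNA-Pro", 34, c("RLB1-9", "RLB3-6", "S1A1-7"),
              "RLB3-6", daice = "RLB1-9")
  add("f09", "f09", "AICE", "RLB1-8", "chr", "mfsT", 0, 25,
      paste0(AICE_R, ",parM,atp_gtp_binding"), "none", "f09", "full")
  add("f10", "f10", "AICE", "S1D4-14", "chr", "acdH", 0, 27,
      paste0(AICE_R, ",parM,atp_gtp_binding"), "none", "f10", "full")
  aice_family("f11", "tRNA-Gly", 30, c("RLB3-17", "S1A1-3", "S1A1-8",
                                       "S1D4-23", "RLB3-6"), "RLB3-17",
              daice = "RLB3-6", daice_defect = "no_int")
  add("f12", "f12", "AICE", "RLB1-9", "chr", "senK", 0, 23,
      paste0(AICE_R, ",parM,atp_gtp_binding"), "none", "f12", "full")
  aice_family("f13", "tRNA-Thr", 94, c("RLB1-9", "S1A1-3", "S1A1-8"),
              "RLB1-9", roles = AICE_S)
  aice_family("f14", "tRNA-Met", 36, c("RLB3-17", "RLB1-9", "S1A1-3",
                                       "S1A1-8"), "RLB1-9",
              daice = "RLB3-17", daice_defect = "interrupted_int")
  add("f15", "f15", "AICE", "RLB3-6", "chr", "cypA", 0, 29,
      paste0(AICE_R, ",parM,atp_gtp_binding"), "none", "f15", "full")
  add("f19", "f19", "AICE", "S1A1-7", "chr", "ig1", 0, 40, AICE_R, "none",
      "f19", "full")
  # ICEs: two identical chromosomal copies + one plasmid-borne
  ICE_R <- "integrase_tyr,relaxase,coupling,virb4"
  for (st in c("RLB1-8", "RLB3-5"))
    add("ice01", NA, "ICE", st, "chr", "tRNA-Thr", 0, 93, ICE_R, "none",
        "ICE01", "full")
  add("icep", NA, "ICE", "RLB3-6", "pRLB3-6.1", "plasmid_locus", 0, 0,
      "integrase_ser,relaxase,coupling,virb4", "none", "ICEP", "full")
  # DICE types (per-strain occurrences)
  for (st in strains)
    add("dice1", NA, "DICE", st, "chr", "tRNA-Lys", 0, 24,
        "integrase_tyr,relaxase,virb4", "none", "DICE1", "full")
  for (st in c("RLB1-9", "S1A1-3", "S1A1-8", "RLB3-17"))
    add("dice2", NA, "DICE", st, "chr", "tRNA-Ile", 0, 26,
        "integrase_ser,coupling,virb4", "none", "DICE2", "full")
  for (st in c("S1D4-23", "S1A1-7", "RLB3-6"))
    add("dice3", NA, "DICE", st, "chr", "tRNA-Cys", 0, 28,
        "relaxase,coupling,virb4", "none", "DICE3", "full")
  # IME: absent only in the RLB3-6 / S1D4-23 / S1A1-7 clade
  for (st in setdiff(strains, c("RLB3-6", "S1D4-23", "S1A1-7")))
    add("ime1", NA, "IME", st, "chr", "tRNA-Asp", 0, 31,
        "integrase_ser,relaxase,coupling", "none", "IME1", "full")
  # decayed remnants at the glycosyltransferase site (truncated integrase)
  for (st in c("RLB3-6", "RLB3-17", "S1D4-14"))
    add("remd", NA, "remnant", st, "chr", "glt", 0, 33, "", "partial_int",
        "REMD", "full")
  # divergent plasmid-borne TraB genes, no direct repeats
  ptr <- data.frame(strain = c("RLB1-8", "S1D4-20", "S1A1-3", "S1D4-23"),
                    replicon = c("pRLB1-8.1", "pS1D4-20.1", "pS1A1-3.1",
                                 "pS1D4-23.1"),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(ptr)))
    add(paste0("ptra", i), NA, "plasmid_traB", ptr$strain[i],
        ptr$replicon[i], "plasmid_locus", 0, 0, "traB", "none", "PTRA",
        "full")
  instances <- do.call(rbind, rows)

  pools <- data.frame(
    pool_id = c("f01", "f02", "f03", "f04", "f05", "f06", "f07", "f08",
                "f09", "f10", "f11", "f12", "f13", "f14", "f15", "f16",
                "f17", "f18", "f19", "ICE01", "ICEP", "DICE1", "DICE2",
                "DICE3", "IME1", "REM1", "REMD", "PTRA"),
    n_cargo = c(26, 27, 28, 26, 25, 24, 26, 25, 18, 18, 27, 18, 26, 27, 18,
                24, 23, 22, 17, 81, 28, 25, 22, 20, 30, 3, 4, 3),
    n_short = c(13, 13, 14, 13, 13, 12, 13, 12, 9, 9, 14, 9, 13, 13, 9, 12,
                12, 11, 9, 19, 6, 6, 5, 5, 8, 1, 3, 1),
    stringsAsFactors = FALSE)
  families <- data.frame(
    family = sprintf("f%02d", 1:19),
    trab_len = c(520, 610, 480, 700, 560, 640, 500, 540, 139, 150, 738,
                 160, 460, 590, 170, 430, 470, 620, 410),
    tripartite = sprintf("f%02d", 1:19) %in% c("f09", "f10", "f12", "f15"),
    stringsAsFactors = FALSE)
  population_blueprint(
    strains = strains, replicons = repl, sites = sites,
    site_overrides = overrides, instances = instances, pools = pools,
    families = families,
    core_region = c(180000, 105000) * sc,
    cladogram = cladogram, seed = seed)
}

#' Small randomised blueprint for property testing
#'
#' Two to three strains, a short chromosome, and a handful of elements drawn
#' across the five classes. Composition is a deterministic function of
#' `index`; sequence realisation is controlled by `seed`.
#'
#' @param index composition selector (1-based).
#' @param seed generation seed.
#' @param chromosome_length background chromosome length (bp).
#' @return a `PopulationBlueprint`.
#' @export
random_blueprint <- function(index = 1L, seed = index,
                             chromosome_length = 220000L) {
  n_strains <- 2L + index %% 2L
  strains <- paste0("S", seq_len(n_strains))
  cladogram <- if (n_strains == 2L) "(S1,S2);" else "((S1,S2),S3);"
  repl <- data.frame(strain = strains, replicon = "chr",
                     length = chromosome_length, topology = "linear",
                     role = "chromosome", stringsAsFactors = FALSE)
  sc <- chromosome_length / 220000
  sites <- rbind(
    data.frame(site_name = "tRNA-Ala", kind = "tRNA",
               pos = as.integer(60000 * sc),
               product = "", stringsAsFactors = FALSE),
    data.frame(site_name = "gyrB", kind = "CDS",
               pos = as.integer(105000 * sc),
               product = "DNA gyrase subunit B", stringsAsFactors = FALSE),
    data.frame(site_name = "tRNA-Phe", kind = "tRNA",
               pos = as.integer(150000 * sc),
               product = "", stringsAsFactors = FALSE),
    data.frame(site_name = "ig9", kind = "intergenic",
               pos = as.integer(185000 * sc),
               product = "", stringsAsFactors = FALSE))
  overrides <- data.frame(strain = character(), site_name = character(),
                          pos = integer(), stringsAsFactors = FALSE)
  rows <- list()
  add <- function(spec_id, family, class, strain, site, tsd, roles,
                  defect = "none", pool, mode = "full") {
    rows[[length(rows) + 1L]] <<- data.frame(
      instance_id = sprintf("%s|%s", spec_id, strain), spec_id = spec_id,
      family = family, class = class, strain = strain, replicon = "chr",
      site_name = site, stack_order = 0L, tsd_len = as.integer(tsd),
      roles = roles, defect = defect, cargo_pool = pool, cargo_mode = mode,
      int_identity = NA, stringsAsFactors = FALSE)
  }
  AICE_R <- "integrase_tyr,rep,traB"
  tsd <- 20L + (index * 7L) %% 40L
  add("g01", "g01", "AICE", "S1", "tRNA-Ala", tsd, AICE_R, pool = "g01")
  if (n_strains >= 2L)
    add("g01", "g01", "AICE", "S2", "tRNA-Ala", tsd, AICE_R, pool = "g01")
  add("g02", "g02", if (index %% 3L == 0L) "DAICE" else "AICE", "S2",
      "gyrB", 21L + index %% 30L,
      if (index %% 3L == 0L) "integrase_tyr,traB" else AICE_R,
      if (index %% 3L == 0L) "no_rep" else "none", pool = "g02")
  add("ime", NA, "IME", "S1", "tRNA-Phe", 24L + index %% 20L,
      "integrase_ser,relaxase,coupling", pool = "IMEx")
  if (index %% 2L == 0L)
    add("dice", NA, "DICE", strains[n_strains], "ig9", 26L,
        "integrase_tyr,coupling,virb4", pool = "DICEx")
  instances <- do.call(rbind, rows)
  pools <- data.frame(pool_id = c("g01", "g02", "IMEx", "DICEx"),
                      n_cargo = c(13L, 14L, 15L, 12L),
                      n_short = c(6L, 7L, 4L, 3L),
                      stringsAsFactors = FALSE)
  families <- data.frame(family = c("g01", "g02"),
                         trab_len = c(500L, 430L + 10L * (index %% 5L)),
                         tripartite = FALSE, stringsAsFactors = FALSE)
  population_blueprint(strains = strains, replicons = repl, sites = sites,
                       site_overrides = overrides, instances = instances,
                       pools = pools, families = families,
                       core_region = c(20000, 15000), cladogram = cladogram,
                       seed = seed)
}
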