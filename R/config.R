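# Pipeline configuration: all tunable thresholds in one validated object.

#' Default pipeline configuration
#'
#' Builds the configuration object consumed by every pipeline stage. Values
#' can be overridden by name; all thresholds are validated against their
#' documented ranges.
#'
#' @param ... named overrides of the defaults listed below.
#'
#' @details Defaults:
#' \describe{
#'   \item{identity_threshold}{95 (percent) — TraB family clustering cutoff.}
#'   \item{pseudogene_aa}{150 (amino acids) — cargo genes shorter than this
#'     are counted as putative pseudogenes.}
#'   \item{evalue_cutoff}{1e-6 — E-value filter for imported domain tables
#'     and external cargo-annotation hits.}
#'   \item{min_coverage}{0.80 — query-coverage filter for similarity search.}
#'   \item{min_identity}{30 (percent) — identity floor for similarity search.}
#'   \item{max_mismatch_rate}{0.05 — per-repeat mismatch tolerance.}
#'   \item{min_repeat}{10 (nt) — minimum direct-repeat length considered;
#'     repeats below the chance-significance length are kept only when a copy
#'     overlaps the 3' tail of a tRNA (att-anchored).}
#'   \item{repeat_alpha}{1e-3 — expected number of chance repeat pairs of the
#'     observed length/mismatch pattern tolerated in the searched windows
#'     before a repeat is deemed significant.}
#'   \item{repeat_mismatch_penalty}{3 — score penalty per mismatch when
#'     ranking repeats (match scores +1).}
#'   \item{seed_k}{8 (nt) — exact seed length for the repeat finder.}
#'   \item{search_radius}{5000 (bp) — repeat search window beyond the
#'     outermost signature hit; widened to `fallback_radius` when nothing
#'     significant is found.}
#'   \item{fallback_radius}{40000 (bp).}
#'   \item{max_span_ice}{120000 (bp) — chaining cap for ICE-type candidates.}
#'   \item{max_span_aice}{50000 (bp) — chaining cap for AICE-type candidates.}
#'   \item{profile_bit_threshold}{30 (bits) — minimum anchored profile score.}
#'   \item{profile_min_overlap}{60 (columns) — minimum profile/protein
#'     overlap in the anchored scan.}
#'   \item{prescreen_min_kmers}{8 — minimum shared distinct 4-mers with the
#'     profile consensus / similarity query before a full scan is run.}
#'   \item{trna_tail}{30 (nt) — length of the tRNA 3' tail used by the
#'     short-repeat anchoring guard.}
#'   \item{accretion_gap}{1000 (bp) — maximum gap between tandem elements
#'     grouped into one accretion event.}
#'   \item{interrupt_coverage}{0.6 — integrase hits covering less than this
#'     fraction of the profile, with a transposase annotated within
#'     `interrupt_genes` genes, are flagged as interrupted.}
#'   \item{interrupt_genes}{2.}
#'   \item{tripartite_max_aa}{400 — TraB hits shorter than this are flagged
#'     tripartite candidates when ParM and ATP/GTP-binding hits lie within
#'     `tripartite_genes` genes.}
#'   \item{tripartite_genes}{5.}
#'   \item{gap_open, gap_ext}{10, 1 — affine gap penalties (BLOSUM62).}
#'   \item{core_region}{`c(left_arm_bp, right_arm_bp)` — terminal arm sizes
#'     measured from the chromosome ends for the core/arm roll-up. Defaults
#'     match the packaged desk-scale population (2.4 Mb / 1.4 Mb arms
#'     scaled to a 900-kb chromosome); set to the blueprint's values for
#'     other scales.}
#'   \item{functional_classes}{classes counted as functional in the core/arm
#'     roll-up; elements of other classes count as defective/dependent.}
#'   \item{seed}{1 — RNG seed for stages that draw random numbers.}
#' }
#' @return a named list of class `icecensus_config`.
#' @export
#' @examples
#' cfg <- pipeline_config(identity_threshold = 90)
#' cfg$identity_threshold
pipeline_config <- function(...) {
  cfg <- list(
    identity_threshold = 95,
    pseudogene_aa = 150L,
    evalue_cutoff = 1e-6,
    min_coverage = 0.80,
    min_identity = 30,
    max_mismatch_rate = 0.05,
    min_repeat = 10L,
    repeat_alpha = 1e-3,
    repeat_mismatch_penalty = 3,
    seed_k = 8L,
    search_radius = 5000L,
    fallback_radius = 40000L,
    max_span_ice = 120000L,
    max_span_aice = 50000L,
    profile_bit_threshold = 30,
    profile_min_overlap = 60L,
    prescreen_min_kmers = 8L,
    trna_tail = 30L,
    accretion_gap = 1000L,
    interrupt_coverage = 0.6,
    interrupt_genes = 2L,
    tripartite_max_aa = 400L,
    tripartite_genes = 5L,
    gap_open = 10,
    gap_ext = 1,
    core_region = c(180000, 105000),
    functional_classes = c("ICE", "AICE"),
    seed = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown configuration field(s): ",
                        paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  validate_config(cfg)
  class(cfg) <- "icecensus_config"
  cfg
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop("invalid configuration: ", msg)
  chk(cfg$identity_threshold >= 0 && cfg$identity_threshold <= 100,
      "identity_threshold must be in [0, 100]")
  chk(cfg$pseudogene_aa > 0, "pseudogene_aa must be positive")
  chk(cfg$evalue_cutoff > 0, "evalue_cutoff must be positive")
  chk(cfg$min_coverage >= 0 && cfg$min_coverage <= 1,
      "min_coverage must be in [0, 1]")
  chk(cfg$max_mismatch_rate >= 0 && cfg$max_mismatch_rate < 1,
      "max_mismatch_rate must be in [0, 1)")
  chk(cfg$min_repeat >= 2, "min_repeat must be >= 2")
  chk(cfg$search_radius > 0, "search_radius must be positive")
  chk(cfg$max_span_aice > 0 && cfg$max_span_ice >= cfg$max_span_aice,
      "span caps must be positive with max_span_ice >= max_span_aice")
  invisible(cfg)
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path file path.
#' @return `read_config` returns an `icecensus_config`; `write_config`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' @rdname read_config
#' @param config an `icecensus_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
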