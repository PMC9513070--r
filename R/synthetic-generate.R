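# Realisation of population blueprints: background replicons, element
# assembly, target-site-duplication insertion, and ground-truth records.
#
# Insertion model: planting an element of sequence E at point p with a
# TSD of length l duplicates the l nt upstream of p, producing
# ... [p-l, p) = attL | E | attR copy | original downstream ... so that the
# element bounds [p-l, p+|E|) follow the include_one_repeat convention and
# excising the bounds restores an intact site. The three bases immediately
# outside each repeat copy are forced to mismatch their counterparts so
# that the planted duplication is the exact local score optimum for the
# repeat finder (chance single-base extensions would otherwise shift the
# recovered boundaries).

PRODUCTS <- list(
  integrase_tyr = "site-specific tyrosine recombinase (integrase)",
  integrase_ser = "site-specific serine recombinase (integrase)",
  relaxase = "MobC family conjugal relaxase",
  coupling = "type IV secretion system coupling protein",
  virb4 = "VirB4 family type IV secretion ATPase",
  traB = "conjugal transfer protein TraB",
  rep = "replication initiator protein RepSA",
  parM = "plasmid segregation actin ParM",
  atp_gtp_binding = "ATP/GTP-binding protein",
  xis = "excisionase",
  spd = "intramycelial spread protein SpdB",
  traG = "conjugal transfer protein TraG",
  tnp = "IS110 family transposase",
  int_partial = "site-specific integrase, partial")

CARGO_LEXICON <- list(
  "metabolism" = c("flavoprotein oxidoreductase",
                   "glycosyl hydrolase family protein",
                   "short-chain dehydrogenase/reductase",
                   "aldo/keto reductase"),
  "DNA metabolism" = c("DNA repair protein RadA",
                       "ATP-dependent DNA ligase",
                       "DNA primase-like protein",
                       "single-stranded DNA-binding protein"),
  "resistance" = c("aminoglycoside phosphotransferase",
                   "beta-lactamase family protein",
                   "multidrug efflux pump"),
  "regulation" = c("TetR family transcriptional regulator",
                   "MarR family transcriptional regulator",
                   "ECF sigma factor"),
  "phage" = c("phage portal protein", "phage terminase large subunit",
              "type II restriction endonuclease",
              "abortive phage infection protein AIPR"),
  "toxin/antitoxin" = c("type II toxin-antitoxin system RelE family toxin",
                        "antitoxin VapB"),
  "signaling" = c("serine/threonine protein kinase",
                  "GGDEF domain diguanylate cyclase",
                  "cyclic nucleotide-binding protein"),
  "transposase" = c("IS5 family transposase", "IS481 family transposase"),
  "hypothetical" = c("hypothetical protein",
                     "DUF4352 domain-containing protein"))

.revcomp <- function(s) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
}

# substitution at exactly n distinct positions
.mutate_npos <- function(protein, n) {
  a <- strsplit(protein, "", fixed = TRUE)[[1]]
  n <- min(n, length(a))
  if (n > 0) {
    pos <- sample.int(length(a), n)
    a[pos] <- vapply(a[pos], function(x) sample(setdiff(AA20, x), 1L), "")
  }
  paste(a, collapse = "")
}

#' Mutate a protein to a target global identity
#'
#' Substitution-only mutation of a protein so that the global (affine-gap,
#' BLOSUM62) percent identity between input and output is within 0.5
#' percentage points of the target; length is preserved. The achieved
#' identity is verified with [global_identity()] and the mutation load is
#' adjusted until the target band is met.
#'
#' @param protein amino-acid sequence (>= 20 aa).
#' @param target_identity target percent identity in (0, 100].
#' @param seed optional integer seed (the global RNG state is restored).
#' @return the mutated sequence.
#' @export
mutate_to_identity <- function(protein, target_identity, seed = NULL) {
  stopifnot(target_identity > 0, target_identity <= 100)
  L <- nchar(protein)
  if (L < 20L)
    stop("target identity unreachable for sequences shorter than 20 aa")
  if (target_identity == 100) return(protein)
  if (!is.null(seed)) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  a0 <- strsplit(protein, "", fixed = TRUE)[[1]]
  a <- a0
  n_mut <- round(L * (1 - target_identity / 100))
  pos <- sample.int(L, min(L, n_mut))
  a[pos] <- vapply(a[pos], function(x) sample(setdiff(AA20, x), 1L), "")
  out <- paste(a, collapse = "")
  for (iter in 1:30) {
    id <- global_identity(protein, out)
    if (abs(id - target_identity) <= 0.5) return(out)
    delta <- round(abs(id - target_identity) / 100 * L)
    delta <- max(1L, delta)
    if (id > target_identity) {
      un <- sample(which(a == a0), min(sum(a == a0), delta))
      a[un] <- vapply(a[un], function(x) sample(setdiff(AA20, x), 1L), "")
    } else {
      mu <- which(a != a0)
      back <- sample(mu, min(length(mu), delta))
      a[back] <- a0[back]
    }
    out <- paste(a, collapse = "")
  }
  out
}

# ---- population-level resources (proteins shared across strains) ----------

.population_resources <- function(bp) {
  seeds <- signature_seeds()
  res <- list(seeds = seeds)
  # TraB family base sequences: ~85% identity to the canonical seed,
  # truncated/padded to the family length
  fam_base <- list()
  if (!is.null(bp$families) && nrow(bp$families)) {
    for (i in seq_len(nrow(bp$families))) {
      L <- bp$families$trab_len[i]
      base <- seeds[["traB"]]
      if (L <= nchar(base)) base <- substr(base, 1, L)
      else base <- paste0(base, random_protein(L - nchar(base)))
      fam_base[[bp$families$family[i]]] <- .mutate_fraction(base, 0.15)
    }
  }
  res$fam_base <- fam_base
  # per-spec signature/accessory proteins (shared by all carriers of a spec)
  spec_prot <- list()
  specs <- unique(bp$instances$spec_id)
  for (sid in specs) {
    inst <- bp$instances[bp$instances$spec_id == sid, , drop = FALSE][1, ]
    roles <- setdiff(strsplit(inst$roles, ",")[[1]], "")
    pr <- list()
    for (r in setdiff(roles, "traB")) {
      idt <- if (!is.na(inst$int_identity) &&
                 r %in% c("integrase_tyr", "integrase_ser"))
        inst$int_identity else runif(1, 78, 92)
      pr[[r]] <- mutate_to_identity(seeds[[r]], idt)
    }
    if (inst$defect == "interrupted_int") {
      r <- grep("integrase", roles, value = TRUE)[1]
      full <- pr[[r]]
      cut <- floor(nchar(full) * 0.45)
      pr[[paste0(r, "_N")]] <- substr(full, 1, cut)
      pr[[paste0(r, "_C")]] <- substr(full, cut + 1, nchar(full))
      pr[[r]] <- NULL
      pr$tnp <- random_protein(250)
    }
    if (inst$defect == "partial_int") pr$int_partial <- random_protein(30)
    has_int <- any(grepl("integrase", roles))
    if (has_int || inst$defect == "interrupted_int")
      pr$xis <- random_protein(70)
    if (inst$class %in% c("AICE", "DAICE")) pr$spd <- random_protein(140)
    if (inst$class == "ICE" && inst$replicon == "chr")
      pr$traG <- random_protein(480)
    spec_prot[[sid]] <- pr
  }
  res$spec_prot <- spec_prot
  # per-instance TraB (family structure: each member differs from the family
  # base at ~0.65% of positions, so within-family pairwise identity >= 97%)
  inst_trab <- list()
  ptra_len <- c(139L, 300L, 550L, 789L)
  ptra_i <- 0L
  for (i in seq_len(nrow(bp$instances))) {
    inst <- bp$instances[i, ]
    if (!grepl("traB", inst$roles)) next
    if (inst$class == "plasmid_traB") {
      ptra_i <- ptra_i + 1L
      L <- ptra_len[((ptra_i - 1L) %% 4L) + 1L]
      base <- seeds[["traB"]]
      base <- if (L <= nchar(base)) substr(base, 1, L)
              else paste0(base, random_protein(L - nchar(base)))
      inst_trab[[inst$instance_id]] <- .mutate_fraction(base, 0.35)
    } else {
      base <- res$fam_base[[inst$family]]
      m <- max(1L, round(nchar(base) * 0.0065))
      inst_trab[[inst$instance_id]] <- .mutate_npos(base, m)
    }
  }
  res$inst_trab <- inst_trab
  # cargo pools
  pools <- list()
  w <- default_category_weights()
  for (i in seq_len(nrow(bp$pools))) {
    p <- bp$pools[i, ]
    n <- p$n_cargo; ns <- p$n_short
    lens <- integer(n); cats <- character(n); prods <- character(n)
    if (ns > 0) {
      lens[seq_len(ns)] <- sample(40:149, ns, replace = TRUE)
      cats[seq_len(ns)] <- "hypothetical"
      prods[seq_len(ns)] <- "hypothetical protein"
    }
    if (n > ns) {
      idx <- (ns + 1L):n
      lens[idx] <- sample(150:450, n - ns, replace = TRUE)
      cats[idx] <- sample(names(w), n - ns, replace = TRUE, prob = w)
      prods[idx] <- vapply(cats[idx],
                           function(cc) sample(CARGO_LEXICON[[cc]], 1L), "")
    }
    prot <- vapply(lens, random_protein, "")
    pools[[p$pool_id]] <- data.frame(
      key = sprintf("%s.c%03d", p$pool_id, seq_len(n)), aa = lens,
      protein = prot, product = prods, category = cats, short = lens < 150,
      stringsAsFactors = FALSE)
  }
  res$pools <- pools
  res
}

# ---- element assembly -----------------------------------------------------

# Build one element body: ordered genes with spacers. Returns seq, relative
# features, proteins, role->id map and cargo ids.
.realize_element <- function(inst, res) {
  roles <- setdiff(strsplit(inst$roles, ",")[[1]], "")
  pr <- res$spec_prot[[inst$spec_id]]
  genes <- list()  # each: list(tag, protein, product)
  push <- function(tag, protein, product)
    genes[[length(genes) + 1L]] <<- list(tag = tag, protein = protein,
                                         product = product)
  int_role <- grep("integrase", roles, value = TRUE)
  # left block: recombination module
  if (inst$defect == "interrupted_int") {
    r <- grep("integrase", names(pr), value = TRUE)
    rN <- grep("_N$", r, value = TRUE); rC <- grep("_C$", r, value = TRUE)
    base <- sub("_N$", "", rN)
    push("intN", pr[[rN]], PRODUCTS[[base]])
    push("tnp", pr$tnp, PRODUCTS$tnp)
    push("intC", pr[[rC]], paste0(PRODUCTS[[base]], ", C-terminal fragment"))
    push("xis", pr$xis, PRODUCTS$xis)
  } else if (length(int_role)) {
    push("int", pr[[int_role[1]]], PRODUCTS[[int_role[1]]])
    if (!is.null(pr$xis)) push("xis", pr$xis, PRODUCTS$xis)
  } else if (!is.null(pr$int_partial)) {
    push("intP", pr$int_partial, PRODUCTS$int_partial)
  }
  moved_left <- character(0)
  right_order <- c("spd", "rep", "parM", "atp_gtp_binding", "traB", "traG",
                   "relaxase", "coupling", "virb4")
  right_tags <- intersect(right_order, c(names(pr), "traB"))
  right_tags <- right_tags[right_tags %in% c(roles, "spd", "traG")]
  if (!length(int_role) && inst$defect != "interrupted_int" &&
      is.null(pr$int_partial) && length(right_tags) >= 2L) {
    # no recombination gene at the left edge: lead with the first transfer
    # gene so the signature anchor still spans the element
    moved_left <- right_tags[1L]
    right_tags <- right_tags[-1L]
    prot <- if (moved_left == "traB") res$inst_trab[[inst$instance_id]]
            else pr[[moved_left]]
    push(moved_left, prot, PRODUCTS[[moved_left]])
  }
  # middle block: cargo
  pool <- res$pools[[inst$cargo_pool]]
  if (!is.null(pool) && nrow(pool)) {
    if (identical(inst$cargo_mode, "full")) keep <- seq_len(nrow(pool))
    else keep <- sort(sample.int(nrow(pool), ceiling(0.8 * nrow(pool))))
    keep <- sample(keep)  # shuffle order along the element
    for (k in keep)
      push(paste0("c", sprintf("%03d", k)), pool$protein[k], pool$product[k])
  }
  # right block: replication + transfer modules
  for (tag in right_tags) {
    prot <- if (tag == "traB") res$inst_trab[[inst$instance_id]]
            else pr[[tag]]
    if (is.null(prot)) next
    push(tag, prot, PRODUCTS[[tag]])
  }
  # assemble
  pieces <- character(0); feats <- list(); prots <- character(0)
  cursor <- 0L
  left_spacer <- sample(220:380, 1L)
  pieces <- c(pieces, random_dna(left_spacer)); cursor <- cursor + left_spacer
  role_map <- character(0); cargo_ids <- character(0)
  for (g in genes) {
    nt <- reverse_translate(g$protein)
    id <- sprintf("%s.%s", inst$instance_id, g$tag)
    feats[[length(feats) + 1L]] <- feature_row(id, "CDS", cursor,
                                               cursor + nchar(nt), "+",
                                               g$product)
    prots[id] <- g$protein
    if (g$tag %in% c("int", "intN", "intC"))
      role_map[if (g$tag == "int") int_role[1] else g$tag] <- id
    else if (g$tag %in% SIGNATURE_ROLES) role_map[g$tag] <- id
    else if (grepl("^c\\d+$", g$tag)) cargo_ids <- c(cargo_ids, id)
    pieces <- c(pieces, nt); cursor <- cursor + nchar(nt)
    gap <- sample(90:190, 1L)
    pieces <- c(pieces, random_dna(gap)); cursor <- cursor + gap
  }
  right_extra <- sample(130:280, 1L)
  pieces <- c(pieces, random_dna(right_extra))
  list(seq = paste(pieces, collapse = ""),
       features = do.call(rbind, feats) %||% new_feature_df(),
       proteins = prots, role_map = role_map, cargo_ids = cargo_ids)
}

# ---- insertion ------------------------------------------------------------

# Insert an element body at point p (0-based) of the replicon state,
# duplicating the tsd_len nt upstream of p. avoid_head / avoid_tail: bases
# the element's first/last three nt must additionally differ from; in
# accretion stacks these carry the previous member's head and the bytes
# flanking the outermost repeat copy, so that no pair of the identical
# stack repeats can be extended past its boundaries by chance matches.
.insert_at <- function(state, p, elem_seq, tsd_len, avoid_head = NULL,
                       avoid_tail = NULL) {
  seq <- state$seq
  n <- nchar(seq)
  stopifnot(p >= tsd_len, p <= n)
  if (tsd_len > 0) {
    if (!is.null(avoid_head) && !is.list(avoid_head))
      avoid_head <- list(avoid_head)
    head3 <- strsplit(substr0(elem_seq, 0, 3), "", fixed = TRUE)[[1]]
    for (k in 0:2) {
      bad <- substr0(seq, p + k, p + k + 1L)
      for (ah in avoid_head)
        if (length(ah) > k) bad <- c(bad, ah[k + 1L])
      if (head3[k + 1L] %in% bad)
        head3[k + 1L] <- sample(setdiff(DNA4, bad), 1L)
    }
    E <- nchar(elem_seq)
    tail3 <- strsplit(substr0(elem_seq, E - 3L, E), "", fixed = TRUE)[[1]]
    for (k in 1:3) {
      if (p - tsd_len - k < 0) next
      bad <- substr0(seq, p - tsd_len - k, p - tsd_len - k + 1L)
      if (!is.null(avoid_tail) && length(avoid_tail) >= k)
        bad <- c(bad, avoid_tail[4L - k])
      if (tail3[4L - k] %in% bad)
        tail3[4L - k] <- sample(setdiff(DNA4, bad), 1L)
    }
    elem_seq <- paste0(paste(head3, collapse = ""),
                       substr0(elem_seq, 3L, E - 3L),
                       paste(tail3, collapse = ""))
    tsd <- substr0(seq, p - tsd_len, p)
  } else tsd <- ""
  D <- nchar(elem_seq) + tsd_len
  state$seq <- paste0(substr0(seq, 0, p), elem_seq, tsd, substr0(seq, p, n))
  # features: split any CDS straddling the insertion point, shift downstream
  f <- state$features
  if (nrow(f)) {
    straddle <- f$start0 < p & f$end0 > p
    for (i in which(straddle)) {
      keep_aa <- max(1L, (p - f$start0[i]) %/% 3L)
      id <- f$id[i]
      if (!is.na(state$proteins[id]))
        state$proteins[id] <- substr(state$proteins[id], 1, keep_aa)
      f$end0[i] <- p
    }
    shift <- f$start0 >= p
    f$start0[shift] <- f$start0[shift] + D
    f$end0[shift] <- f$end0[shift] + D
    state$features <- f
  }
  # shift existing truth coordinates
  if (length(state$truth)) {
    state$truth <- lapply(state$truth, function(tr) {
      for (fld in c("start0", "end0", "tsd_left_start0", "tsd_right_start0"))
        if (!is.na(tr[[fld]]) && tr[[fld]] >= p) tr[[fld]] <- tr[[fld]] + D
      tr
    })
  }
  if (nrow(state$planted)) {
    sh <- state$planted$start0 >= p
    state$planted$start0[sh] <- state$planted$start0[sh] + D
    state$planted$end0[sh] <- state$planted$end0[sh] + D
  }
  state$last <- list(p = p, D = D, elem_seq = elem_seq, tsd = tsd)
  state
}

# ---- background replicons -------------------------------------------------

.build_background <- function(len, site_df) {
  # reserved zones around insertion sites
  zones <- list(); site_feats <- list(); site_prots <- character(0)
  if (!is.null(site_df) && nrow(site_df)) {
    site_df <- site_df[order(site_df$pos), , drop = FALSE]
    for (i in seq_len(nrow(site_df))) {
      s <- site_df[i, ]
      if (s$kind == "tRNA") {
        zones[[length(zones) + 1L]] <- c(s$pos - 150, s$pos + 60)
        site_feats[[length(site_feats) + 1L]] <-
          feature_row(paste0("site.", s$site_name), "tRNA", s$pos - 76,
                      s$pos, "+", s$site_name)
      } else if (s$kind == "CDS") {
        zones[[length(zones) + 1L]] <- c(s$pos - 700, s$pos + 700)
        id <- paste0("site.", s$site_name)
        prot <- random_protein(399L)   # 1200 nt CDS centred on the site
        site_feats[[length(site_feats) + 1L]] <-
          feature_row(id, "CDS", s$pos - 600, s$pos + 600, "+", s$product)
        site_prots[id] <- prot
      } else {
        zones[[length(zones) + 1L]] <- c(s$pos - 350, s$pos + 150)
      }
    }
  }
  # background gene layout in free regions
  feats <- list(); prots <- character(0)
  zm <- if (length(zones)) do.call(rbind, zones) else
    matrix(numeric(0), ncol = 2)
  free_start <- 0
  bounds <- rbind(zm, c(len, len))
  bounds <- bounds[order(bounds[, 1]), , drop = FALSE]
  gi <- 0L
  for (z in seq_len(nrow(bounds))) {
    a <- free_start; b <- min(bounds[z, 1], len)
    cursor <- a
    while (TRUE) {
      cursor <- cursor + sample(50:300, 1L)
      aa <- if (runif(1) < 0.07) sample(40:149, 1L) else
        min(900L, max(150L, round(stats::rlnorm(1, log(280), 0.35))))
      nt <- gene_nt_length(aa)
      if (cursor + nt > b - 30) break
      gi <- gi + 1L
      id <- sprintf("bg%05d", gi)
      prot <- random_protein(aa)
      strand <- sample(c("+", "-"), 1L)
      feats[[length(feats) + 1L]] <- feature_row(id, "CDS", cursor,
                                                 cursor + nt, strand,
                                                 "hypothetical protein")
      prots[id] <- prot
      cursor <- cursor + nt
    }
    free_start <- max(free_start, bounds[z, 2])
    if (free_start >= len) break
  }
  features <- rbind(do.call(rbind, feats) %||% new_feature_df(),
                    do.call(rbind, site_feats) %||% new_feature_df())
  features <- features[order(features$start0, features$end0), , drop = FALSE]
  prots <- c(prots, site_prots)
  # assemble sequence: random gaps, reverse-translated CDS, random tRNA
  pieces <- character(0); cursor <- 0L
  for (i in seq_len(nrow(features))) {
    ft <- features[i, ]
    if (ft$start0 > cursor)
      pieces <- c(pieces, random_dna(ft$start0 - cursor))
    if (ft$type == "CDS") {
      nt <- reverse_translate(prots[[ft$id]])
      if (ft$strand == "-") nt <- .revcomp(nt)
      pieces <- c(pieces, nt)
    } else {
      pieces <- c(pieces, random_dna(ft$end0 - ft$start0))
    }
    cursor <- ft$end0
  }
  if (cursor < len) pieces <- c(pieces, random_dna(len - cursor))
  list(seq = paste(pieces, collapse = ""), features = features,
       proteins = prots)
}

# ---- population generation ------------------------------------------------

.truth_template <- function() {
  data.frame(strain = character(), replicon = character(),
             element_id = character(), class = character(),
             family = character(), site_kind = character(),
             site_name = character(), start0 = integer(), end0 = integer(),
             tsd_len = integer(), tsd_left_start0 = integer(),
             tsd_right_start0 = integer(), tsd_seq = character(),
             accretion_group = character(), stack_order = integer(),
             roles = character(), cargo_ids = character(),
             spec_id = character(), stringsAsFactors = FALSE)
}

#' Generate a synthetic population from a blueprint
#'
#' Realises every element instance of the blueprint in every carrying
#' strain, embedded in randomly generated annotated background replicons.
#' The same seed yields byte-identical output; different seeds share the
#' identical composition (class counts, families, sites) with different
#' sequences.
#'
#' @param blueprint a [population_blueprint()].
#' @return list with `genomes` (list of [genome_record()], named
#'   `strain/replicon`) and `truth` (data.frame, one row per planted
#'   element; coordinates 0-based half-open on the final sequences).
#' @export
generate_population <- function(blueprint) {
  bp <- blueprint
  stopifnot(inherits(bp, "PopulationBlueprint"))
  set.seed(bp$seed)
  res <- .population_resources(bp)
  genomes <- list(); truth_rows <- list()
  for (si in seq_along(bp$strains)) {
    strain <- bp$strains[si]
    reps <- bp$replicons[bp$replicons$strain == strain, , drop = FALSE]
    for (ri in seq_len(nrow(reps))) {
      rep_row <- reps[ri, ]
      is_chr <- rep_row$role == "chromosome"
      site_df <- if (is_chr) {
        sd <- bp$sites
        if (nrow(bp$site_overrides)) {
          ov <- bp$site_overrides[bp$site_overrides$strain == strain, ,
                                  drop = FALSE]
          for (j in seq_len(nrow(ov)))
            sd$pos[sd$site_name == ov$site_name[j]] <- ov$pos[j]
        }
        sd
      } else NULL
      bg <- .build_background(rep_row$length, site_df)
      state <- list(seq = bg$seq, features = bg$features,
                    proteins = bg$proteins, truth = list(),
                    planted = data.frame(start0 = integer(),
                                         end0 = integer(),
                                         spec = character(),
                                         stringsAsFactors = FALSE))
      inst_here <- bp$instances[bp$instances$strain == strain &
                                  bp$instances$replicon == rep_row$replicon, ,
                                drop = FALSE]
      if (nrow(inst_here)) {
        pos <- vapply(seq_len(nrow(inst_here)), function(i) {
          if (is_chr)
            .site_position(bp$sites, bp$site_overrides, strain,
                           inst_here$site_name[i])
          else floor(rep_row$length / 2)
        }, numeric(1))
        inst_here$.pos <- pos
        o <- order(-inst_here$.pos, inst_here$stack_order)
        inst_here <- inst_here[o, , drop = FALSE]
        i <- 1L
        while (i <= nrow(inst_here)) {
          base_pos <- inst_here$.pos[i]
          grp <- which(inst_here$.pos == base_pos)
          p <- as.integer(base_pos)
          head_hist <- list()   # heads of the two previous stack members
          l1 <- inst_here$tsd_len[grp[1]]
          avoid_tail <- if (l1 > 0 && p - l1 - 3 >= 0)
            strsplit(substr0(state$seq, p - l1 - 3L, p - l1), "",
                     fixed = TRUE)[[1]]
          else NULL
          for (gidx in grp) {
            inst <- inst_here[gidx, , drop = FALSE]
            ok <- !nrow(state$planted) ||
              all(p <= state$planted$start0 | p >= state$planted$end0)
            if (!ok)
              stop(sprintf("overlapping planted sites: %s vs %s",
                           inst$spec_id,
                           paste(state$planted$spec, collapse = ",")))
            elem <- .realize_element(inst, res)
            l <- inst$tsd_len
            state <- .insert_at(state, p, elem$seq, l, head_hist,
                                avoid_tail)
            E <- nchar(state$last$elem_seq)
            kind <- if (!is_chr) "intergenic" else
              bp$sites$kind[match(inst$site_name, bp$sites$site_name)]
            tr <- list(strain = strain, replicon = rep_row$replicon,
                       element_id = inst$instance_id, class = inst$class,
                       family = inst$family %||% NA_character_,
                       site_kind = kind %||% "intergenic",
                       site_name = inst$site_name,
                       start0 = if (l > 0) p - l else p, end0 = p + E,
                       tsd_len = l,
                       tsd_left_start0 = if (l > 0) p - l else NA_integer_,
                       tsd_right_start0 = if (l > 0) p + E else NA_integer_,
                       tsd_seq = if (l > 0) state$last$tsd else "",
                       accretion_group =
                         if (inst$stack_order > 0)
                           paste0(strain, ".", inst$site_name)
                         else NA_character_,
                       stack_order = inst$stack_order,
                       roles = paste(sprintf("%s=%s", names(elem$role_map),
                                             elem$role_map), collapse = ";"),
                       cargo_ids = paste(elem$cargo_ids, collapse = ","),
                       spec_id = inst$spec_id)
            state$truth[[length(state$truth) + 1L]] <- tr
            # register element features/proteins
            ef <- elem$features
            ef$start0 <- ef$start0 + p; ef$end0 <- ef$end0 + p
            state$features <- rbind(state$features, ef)
            state$proteins <- c(state$proteins, elem$proteins)
            state$planted <- rbind(state$planted,
                                   data.frame(start0 = if (l > 0) p - l else p,
                                              end0 = p + E + l,
                                              spec = inst$spec_id,
                                              stringsAsFactors = FALSE))
            head_hist <- c(list(strsplit(substr0(state$last$elem_seq, 0, 3),
                                         "", fixed = TRUE)[[1]]),
                           head_hist)
            head_hist <- head_hist[seq_len(min(2L, length(head_hist)))]
            p <- p + state$last$D   # next stack member right of the new attR
          }
          i <- max(grp) + 1L
        }
      }
      # renumber features left-to-right with neutral ids
      f <- state$features
      f <- f[order(f$start0, f$end0), , drop = FALSE]
      new_ids <- sprintf("%s_%s_%05d", gsub("[^A-Za-z0-9]", "", strain),
                         gsub("[^A-Za-z0-9]", "", rep_row$replicon),
                         seq_len(nrow(f)))
      id_map <- stats::setNames(new_ids, f$id)
      f$id <- new_ids
      prot <- state$proteins
      keep <- names(prot) %in% names(id_map)
      prot <- prot[keep]
      names(prot) <- unname(id_map[names(prot)])
      # truth gene ids remapped
      state$truth <- lapply(state$truth, function(tr) {
        if (nzchar(tr$roles)) {
          parts <- strsplit(tr$roles, ";", fixed = TRUE)[[1]]
          kv <- strsplit(parts, "=", fixed = TRUE)
          tr$roles <- paste(vapply(kv, function(x)
            sprintf("%s=%s", x[1], id_map[[x[2]]]), ""), collapse = ";")
        }
        if (nzchar(tr$cargo_ids)) {
          ids <- strsplit(tr$cargo_ids, ",", fixed = TRUE)[[1]]
          tr$cargo_ids <- paste(unname(id_map[ids]), collapse = ",")
        }
        tr
      })
      rownames(f) <- NULL
      g <- genome_record(strain, rep_row$replicon, state$seq, f, prot,
                         topology = rep_row$topology, role = rep_row$role)
      genomes[[paste0(strain, "/", rep_row$replicon)]] <- g
      truth_rows <- c(truth_rows, state$truth)
    }
  }
  truth <- if (length(truth_rows))
    do.call(rbind, lapply(truth_rows, function(x)
      as.data.frame(x, stringsAsFactors = FALSE)))
  else .truth_template()
  rownames(truth) <- NULL
  list(genomes = genomes, truth = truth)
}

#' Plant a single element into a genome record
#'
#' Inserts an element built from `spec` at `site_position`, duplicating the
#' `tsd_length` nt upstream of the site so that identical direct repeats
#' flank the element, and shifting downstream features consistently.
#'
#' @param replicon a [genome_record()].
#' @param spec an [element_spec()] (with `tsd_length >= 2`).
#' @param site_position 0-based insertion point.
#' @return list with `record` (modified genome), `truth` (one-row truth
#'   data.frame) and `element_seq` (the inserted body between the repeat
#'   copies).
#' @export
plant_element <- function(replicon, spec, site_position) {
  stopifnot(inherits(replicon, "GenomeRecord"), inherits(spec, "ElementSpec"))
  p <- as.integer(site_position)
  if (p <= spec$tsd_length || p >= nchar(replicon$seq))
    stop("site_position outside replicon")
  if (spec$tsd_length < 2) stop("tsd_length must be >= 2")
  planted <- attr(replicon, "planted")
  if (!is.null(planted) && nrow(planted) &&
      any(p > planted$start0 & p < planted$end0))
    stop("site inside an existing planted element: ",
         paste(planted$spec[p > planted$start0 & p < planted$end0],
               collapse = ","))
  inst <- data.frame(instance_id = paste0(spec$id, "|", replicon$strain),
                     spec_id = spec$id, family = spec$traB_family_target,
                     class = spec$element_class, strain = replicon$strain,
                     replicon = replicon$replicon,
                     site_name = spec$site_name, stack_order = 0L,
                     tsd_len = spec$tsd_length,
                     roles = paste(spec$signature_roles, collapse = ","),
                     defect = "none", cargo_pool = "adhoc",
                     cargo_mode = "full", int_identity = NA,
                     stringsAsFactors = FALSE)
  bp_like <- list(instances = inst,
                  pools = data.frame(pool_id = "adhoc",
                                     n_cargo = spec$cargo_spec$n_cargo,
                                     n_short = spec$cargo_spec$n_short,
                                     stringsAsFactors = FALSE),
                  families = if (!is.na(spec$traB_family_target))
                    data.frame(family = spec$traB_family_target,
                               trab_len = 520L, tripartite = FALSE,
                               stringsAsFactors = FALSE)
                  else data.frame(family = character(),
                                  trab_len = integer(),
                                  tripartite = logical()))
  res <- .population_resources(bp_like)
  elem <- .realize_element(inst, res)
  state <- list(seq = replicon$seq, features = replicon$features,
                proteins = replicon$proteins, truth = list(),
                planted = planted %||% data.frame(start0 = integer(),
                                                  end0 = integer(),
                                                  spec = character(),
                                                  stringsAsFactors = FALSE))
  state <- .insert_at(state, p, elem$seq, spec$tsd_length)
  E <- nchar(state$last$elem_seq)
  ef <- elem$features
  ef$start0 <- ef$start0 + p; ef$end0 <- ef$end0 + p
  feats <- rbind(state$features, ef)
  feats <- feats[order(feats$start0, feats$end0), , drop = FALSE]
  rownames(feats) <- NULL
  rec <- genome_record(replicon$strain, replicon$replicon, state$seq, feats,
                       c(state$proteins, elem$proteins),
                       topology = replicon$topology, role = replicon$role)
  pl <- rbind(state$planted,
              data.frame(start0 = p - spec$tsd_length,
                         end0 = p + E + spec$tsd_length, spec = spec$id,
                         stringsAsFactors = FALSE))
  attr(rec, "planted") <- pl
  truth <- data.frame(
    strain = replicon$strain, replicon = replicon$replicon,
    element_id = inst$instance_id, class = spec$element_class,
    family = spec$traB_family_target, site_kind = spec$site_kind,
    site_name = spec$site_name, start0 = p - spec$tsd_length, end0 = p + E,
    tsd_len = spec$tsd_length, tsd_left_start0 = p - spec$tsd_length,
    tsd_right_start0 = p + E, tsd_seq = state$last$tsd,
    accretion_group = spec$accretion_group, stack_order = 0L,
    roles = paste(sprintf("%s=%s", names(elem$role_map), elem$role_map),
                  collapse = ";"),
    cargo_ids = paste(elem$cargo_ids, collapse = ","),
    spec_id = spec$id, stringsAsFactors = FALSE)
  list(record = rec, truth = truth, element_seq = state$last$elem_seq)
}

#' Write / read a truth table
#'
#' Tab-separated, one row per planted element; round-trips losslessly.
#' @param truth truth data.frame from [generate_population()].
#' @param path file path.
#' @return `read_truth_table` returns the data.frame; `write_truth_table`
#'   returns `path` invisibly.
#' @export
write_truth_table <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_truth_table
#' @export
read_truth_table <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = "NA",
                    colClasses = c(tsd_seq = "character",
                                   cargo_ids = "character",
                                   roles = "character",
                                   family = "character",
                                   accretion_group = "character",
                                   site_name = "character"))
}
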