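## Synthetic genome / methylome / ChIP / expression generator. The planted
## parameters in the returned manifest are the ground truth against which
## the analysis modules are validated.

#' Simulation configuration
#'
#' Builds a validated configuration for the synthetic-data generator. The
#' defaults describe a compact caricature of a repeat-rich plant genome:
#' 1 Mb over two chromosomes; multi-exon genes, a fraction of which carry a
#' large transposon inside an intron; LTR-like retrotransposon families with
#' high CG/CHG methylation and high H3K9me2 (one family spreading its marks
#' into 1 kb flanks, one with sharp boundaries); TIR-like DNA transposon
#' families, one of which is high-CHH / low-H3K9me2; a LINE family; 20x
#' binomially sampled read support per cytosine; and log-normal expression
#' with a silent fraction. Genes and transposons are placed with at least
#' `min_gap` bp of clean background between features so that 1 kb flank
#' analyses are uncontaminated.
#'
#' @param seed integer seed; all four generator stages derive their RNG
#'   streams from it (byte-identical outputs for equal seeds).
#' @param n_chroms,chrom_length number and length (bp) of chromosomes.
#' @param window_size analysis window width the planted features are aligned
#'   to (TSS tiles), default 100.
#' @param coverage mean reads per cytosine (Poisson).
#' @param cytosine_density named vector: sites per 100 bp per context.
#' @param background list `p_cg, p_chg, p_chh, chip_rate` for unannotated
#'   sequence (chip_rate = expected reads overlapping a 100 bp window).
#' @param genes list `n, length_range, exons_per_gene, cg_edge, cg_mid,
#'   p_chg, p_chh, chip_rate`; the gene-body CG probability runs from
#'   `cg_edge` at the ends to `cg_mid` mid-body (triangular).
#' @param te_families list of family descriptors: `code, te_class,
#'   n_elements, length_range, p_cg, p_chg, p_chh, chip_rate, spreading`
#'   ("spreading"/"non_spreading"), `flank_decay_bp` (linear decay distance
#'   for spreading families).
#' @param genic_te list `fraction` (of genes receiving an intronic TE),
#'   `length_range`, `family` (code of the regime the insertion copies;
#'   genic insertions never spread, mirroring their sharp boundaries).
#' @param tss_high list `n_chg, n_k9, n_both, p_chg, chip_rate`: numbers of
#'   genes planted with high CHG and/or high H3K9me2 in the TSS tile.
#' @param expression list `meanlog, sdlog, fraction_silent, n_replicates,
#'   library_size, suppression_multiplier` (multiplier applied to the
#'   planted RPKM of TSS-high genes; 0 silences them outright).
#' @param chip_read_length ChIP read length in bp.
#' @param min_gap,max_gap background gap drawn between consecutive features.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L,
                       chrom_length = 500000L,
                       window_size = 100L,
                       coverage = 20,
                       cytosine_density = c(CG = 5, CHG = 5, CHH = 15),
                       background = list(p_cg = 0.40, p_chg = 0.05,
                                         p_chh = 0.02, chip_rate = 5),
                       genes = list(n = 40L, length_range = c(2000L, 6000L),
                                    exons_per_gene = 3L,
                                    cg_edge = 0.10, cg_mid = 0.70,
                                    p_chg = 0.05, p_chh = 0.02,
                                    chip_rate = 5),
                       te_families = list(
                         list(code = "RLG", te_class = "LTR", n_elements = 12L,
                              length_range = c(3000L, 8000L), p_cg = 0.90,
                              p_chg = 0.85, p_chh = 0.01, chip_rate = 40,
                              spreading = "spreading", flank_decay_bp = 1000L),
                         list(code = "RLC", te_class = "LTR", n_elements = 12L,
                              length_range = c(3000L, 8000L), p_cg = 0.90,
                              p_chg = 0.85, p_chh = 0.02, chip_rate = 35,
                              spreading = "non_spreading", flank_decay_bp = 0L),
                         list(code = "DTM", te_class = "TIR", n_elements = 15L,
                              length_range = c(600L, 2500L), p_cg = 0.90,
                              p_chg = 0.70, p_chh = 0.15, chip_rate = 6,
                              spreading = "non_spreading", flank_decay_bp = 0L),
                         list(code = "DTT", te_class = "TIR", n_elements = 15L,
                              length_range = c(600L, 2500L), p_cg = 0.90,
                              p_chg = 0.70, p_chh = 0.02, chip_rate = 10,
                              spreading = "non_spreading", flank_decay_bp = 0L),
                         list(code = "RIL", te_class = "LINE", n_elements = 8L,
                              length_range = c(1500L, 5000L), p_cg = 0.90,
                              p_chg = 0.80, p_chh = 0.03, chip_rate = 30,
                              spreading = "non_spreading", flank_decay_bp = 0L)),
                       genic_te = list(fraction = 0.15,
                                       length_range = c(1200L, 2500L),
                                       family = "RLG"),
                       tss_high = list(n_chg = 4L, n_k9 = 4L, n_both = 2L,
                                       p_chg = 0.95, chip_rate = 60),
                       expression = list(meanlog = 1.5, sdlog = 1.2,
                                         fraction_silent = 0.2,
                                         n_replicates = 3L,
                                         library_size = 1e6,
                                         suppression_multiplier = 0),
                       chip_read_length = 50L,
                       min_gap = 2200L, max_gap = 4000L) {
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_length = as.integer(chrom_length),
              window_size = as.integer(window_size), coverage = coverage,
              cytosine_density = cytosine_density, background = background,
              genes = genes, te_families = te_families, genic_te = genic_te,
              tss_high = tss_high, expression = expression,
              chip_read_length = as.integer(chip_read_length),
              min_gap = as.integer(min_gap), max_gap = as.integer(max_gap))
  probs <- c(background$p_cg, background$p_chg, background$p_chh,
             genes$cg_edge, genes$cg_mid, genes$p_chg, genes$p_chh,
             tss_high$p_chg,
             unlist(lapply(te_families, function(f) c(f$p_cg, f$p_chg, f$p_chh))))
  if (any(probs < 0 | probs > 1)) stop("all methylation probabilities must be in [0,1]")
  if (any(cytosine_density < 0)) stop("cytosine densities must be non-negative")
  if (coverage < 0) stop("coverage must be non-negative")
  if (!genic_te$family %in% vapply(te_families, `[[`, "", "code")) {
    stop("genic_te$family must name a configured TE family")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' @rdname sim_config
#' @param n_genes,n_high_chg,n_high_k9 TSS-demo preset sizes.
#' @details `sim_config_tss()` is a preset sized for validating TSS
#'   chromatin-state classification: 8 Mb over four chromosomes, 1000 small
#'   genes of which `n_high_chg` carry a planted high-CHG TSS tile
#'   (p = 0.95 vs 0.05 elsewhere in genic/background sequence) and
#'   `n_high_k9` a planted high-H3K9me2 tile, plus one abundant LTR family
#'   (roughly 15% of the genome at CHG 0.85) so that the genome-wide
#'   top-decile CHG boundary falls inside the transposon mode, as it does in
#'   a repeat-rich genome.
#' @export
sim_config_tss <- function(seed = 1L, n_genes = 1000L, n_high_chg = 50L,
                           n_high_k9 = 25L) {
  sim_config(
    seed = seed, n_chroms = 4L, chrom_length = 2000000L,
    genes = list(n = as.integer(n_genes), length_range = c(1500L, 3000L),
                 exons_per_gene = 2L, cg_edge = 0.10, cg_mid = 0.70,
                 p_chg = 0.05, p_chh = 0.02, chip_rate = 5),
    te_families = list(
      list(code = "RLG", te_class = "LTR", n_elements = 250L,
           length_range = c(3000L, 6000L), p_cg = 0.90, p_chg = 0.85,
           p_chh = 0.01, chip_rate = 40, spreading = "non_spreading",
           flank_decay_bp = 0L)),
    genic_te = list(fraction = 0.05, length_range = c(1200L, 2500L),
                    family = "RLG"),
    tss_high = list(n_chg = as.integer(n_high_chg),
                    n_k9 = as.integer(n_high_k9), n_both = 0L,
                    p_chg = 0.95, chip_rate = 60),
    min_gap = 2200L, max_gap = 3600L)
}

.runif_int <- function(n, lo, hi) lo + floor(runif(n) * (hi - lo + 1))

## lay out one gene: exon/intron segmentation, optional intronic TE in the
## first intron. All segment lengths are multiples of `snap` so that every
## feature boundary falls on an analysis-window boundary — this keeps the
## planted per-window ground truth unambiguous (no window straddles a
## regime change). Returns list(exons = data.table rows, te = NULL or row).
.build_gene <- function(gid, chrom, gstart, glen, k_exons, strand,
                        te_len = NA_integer_, te_id = NA_character_,
                        te_family = NULL, snap = 100L) {
  n_seg <- 2L * k_exons - 1L
  min_exon <- 2L * snap
  min_intron <- snap
  fixed_intron1 <- if (!is.na(te_len)) te_len + 2L * snap else NA_integer_
  mins <- integer(n_seg)
  mins[seq(1L, n_seg, by = 2L)] <- min_exon
  if (n_seg > 1L) mins[seq(2L, n_seg, by = 2L)] <- min_intron
  if (!is.na(fixed_intron1)) mins[2L] <- fixed_intron1
  spare <- glen - sum(mins)
  stopifnot(spare >= 0)
  w <- runif(n_seg)
  if (!is.na(fixed_intron1)) w[2L] <- 0  # intron 1 stays at its fixed size
  extra <- (floor(spare * w / sum(w)) %/% snap) * snap
  extra[1L] <- extra[1L] + (spare - sum(extra))
  seg_len <- mins + extra
  seg_end <- gstart + cumsum(seg_len)
  seg_start <- seg_end - seg_len
  ex_idx <- seq(1L, n_seg, by = 2L)
  exons <- data.table(
    chrom = chrom, start = seg_start[ex_idx], end = seg_end[ex_idx],
    strand = strand, kind = "exon",
    feature_id = paste0(gid, "_ex", seq_along(ex_idx)), parent_id = gid,
    te_class = NA_character_, te_subfamily = NA_character_,
    spreading = NA_character_, gene_set = NA_character_,
    synteny = NA_character_, subgenome = NA_character_)
  te_row <- NULL
  if (!is.na(te_len)) {
    i1s <- seg_start[2L]
    te_start <- i1s + snap
    te_row <- data.table(
      chrom = chrom, start = te_start, end = te_start + te_len,
      strand = sample(c("+", "-"), 1L), kind = "TE", feature_id = te_id,
      parent_id = NA_character_, te_class = te_family$te_class,
      te_subfamily = te_family$code, spreading = "non_spreading",
      gene_set = NA_character_, synteny = NA_character_,
      subgenome = NA_character_)
  }
  list(exons = exons, te = te_row)
}

#' Simulate an annotated genome (features only)
#'
#' Places non-overlapping genes and transposable elements with clean
#' background gaps, nests intronic TEs into designated host genes, and
#' plants the high-CHG / high-H3K9me2 TSS gene sets. Fully deterministic
#' given the config seed.
#'
#' @param config a [sim_config()].
#' @return manifest list: `config`, `chrom_sizes`, `features` (feature
#'   table in [read_features()] layout), `te_params` (planted per-element
#'   methylation/ChIP regimes), `genic_te_hosts`, `tss_high` (data.table of
#'   planted TSS tiles and which marks were planted), `intronic_tes`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    chrom_sizes <- setNames(rep(config$chrom_length, config$n_chroms),
                            paste0("chr", seq_len(config$n_chroms)))
    gcfg <- config$genes
    n_genes <- gcfg$n
    n_host <- as.integer(round(config$genic_te$fraction * n_genes))
    ## units to place: genes then TE elements, shuffled
    units <- data.table(kind = "gene", code = NA_character_,
                        id = sprintf("g%04d", seq_len(n_genes)))
    for (fam in config$te_families) {
      units <- rbind(units, data.table(
        kind = "TE", code = fam$code,
        id = sprintf("%s%05d", fam$code, seq_len(fam$n_elements))))
    }
    units <- units[sample(.N)]
    host_ids <- sample(units[kind == "gene", id], n_host)
    fam_by_code <- setNames(config$te_families,
                            vapply(config$te_families, `[[`, "", "code"))
    genic_fam <- fam_by_code[[config$genic_te$family]]
    ## draw lengths; everything is snapped to the window grid so feature
    ## boundaries coincide with window boundaries (see .build_gene)
    ws <- config$window_size
    snap_up <- function(x) as.integer(ceiling(x / ws) * ws)
    lens <- integer(nrow(units))
    te_in_len <- rep(NA_integer_, nrow(units))
    for (i in seq_len(nrow(units))) {
      if (units$kind[i] == "gene") {
        L <- snap_up(.runif_int(1L, gcfg$length_range[1L], gcfg$length_range[2L]))
        if (units$id[i] %in% host_ids) {
          tl <- snap_up(.runif_int(1L, config$genic_te$length_range[1L],
                                   config$genic_te$length_range[2L]))
          te_in_len[i] <- tl
          L <- max(L, tl + 2L * ws + gcfg$exons_per_gene * 2L * ws +
                     (gcfg$exons_per_gene - 2L) * ws + ws)
        }
        lens[i] <- L
      } else {
        fam <- fam_by_code[[units$code[i]]]
        lens[i] <- snap_up(.runif_int(1L, fam$length_range[1L], fam$length_range[2L]))
      }
    }
    ## sequential placement with grid-aligned gaps
    feats <- list()
    intronic <- list()
    ci <- 1L
    cursor <- 0L
    for (i in seq_len(nrow(units))) {
      gap <- snap_up(.runif_int(1L, config$min_gap, config$max_gap))
      start <- cursor + gap
      while (start + lens[i] + config$min_gap > chrom_sizes[ci]) {
        ci <- ci + 1L
        if (ci > length(chrom_sizes)) {
          stop("infeasible packing: requested features exceed genome capacity")
        }
        cursor <- 0L
        gap <- snap_up(.runif_int(1L, config$min_gap, config$max_gap))
        start <- cursor + gap
      }
      cn <- names(chrom_sizes)[ci]
      if (units$kind[i] == "gene") {
        strand <- sample(c("+", "-"), 1L)
        gid <- units$id[i]
        grow <- data.table(
          chrom = cn, start = start, end = start + lens[i], strand = strand,
          kind = "gene", feature_id = gid, parent_id = NA_character_,
          te_class = NA_character_, te_subfamily = NA_character_,
          spreading = NA_character_,
          gene_set = sample(c("FGS", "WGS"), 1L, prob = c(0.8, 0.2)),
          synteny = sample(c("syntenic", "inserted"), 1L, prob = c(0.7, 0.3)),
          subgenome = sample(c("sg1", "sg2"), 1L))
        built <- .build_gene(gid, cn, start, lens[i], gcfg$exons_per_gene,
                             strand, te_len = te_in_len[i],
                             te_id = if (!is.na(te_in_len[i]))
                               paste0(genic_fam$code, "9", gid) else NA_character_,
                             te_family = genic_fam, snap = ws)
        feats[[length(feats) + 1L]] <- grow
        feats[[length(feats) + 1L]] <- built$exons
        if (!is.null(built$te)) {
          feats[[length(feats) + 1L]] <- built$te
          intronic[[length(intronic) + 1L]] <-
            data.table(host_gene_id = gid, te_id = built$te$feature_id,
                       te_length = te_in_len[i])
        }
      } else {
        fam <- fam_by_code[[units$code[i]]]
        feats[[length(feats) + 1L]] <- data.table(
          chrom = cn, start = start, end = start + lens[i],
          strand = sample(c("+", "-"), 1L), kind = "TE",
          feature_id = units$id[i], parent_id = NA_character_,
          te_class = fam$te_class, te_subfamily = fam$code,
          spreading = fam$spreading, gene_set = NA_character_,
          synteny = NA_character_, subgenome = NA_character_)
      }
      cursor <- start + lens[i]
    }
    features <- rbindlist(feats)
    setorder(features, chrom, start, kind)
    ## planted per-element regimes
    te_rows <- features[kind == "TE"]
    genic_te_ids <- unlist(lapply(intronic, `[[`, "te_id"))
    te_params <- rbindlist(lapply(seq_len(nrow(te_rows)), function(i) {
      fam <- fam_by_code[[te_rows$te_subfamily[i]]]
      genic <- te_rows$feature_id[i] %in% genic_te_ids
      data.table(feature_id = te_rows$feature_id[i],
                 p_cg = fam$p_cg, p_chg = fam$p_chg, p_chh = fam$p_chh,
                 chip_rate = fam$chip_rate,
                 flank_decay_bp = if (genic) 0L else as.integer(fam$flank_decay_bp))
    }))
    ## TSS-high planting
    th <- config$tss_high
    genes_dt <- features[kind == "gene"]
    n_pick <- th$n_chg + th$n_k9 + th$n_both
    pool <- setdiff(genes_dt$feature_id, host_ids)
    if (n_pick > length(pool)) stop("not enough genes for tss_high planting")
    picked <- sample(pool, n_pick)
    assign_chg <- c(rep(TRUE, th$n_chg), rep(FALSE, th$n_k9), rep(TRUE, th$n_both))
    assign_k9 <- c(rep(FALSE, th$n_chg), rep(TRUE, th$n_k9), rep(TRUE, th$n_both))
    ws <- config$window_size
    gsel <- genes_dt[match(picked, feature_id)]
    tss <- ifelse(gsel$strand == "+", gsel$start, gsel$end - 1L)
    tile_start <- (tss %/% ws) * ws
    tss_high <- data.table(gene_id = picked, chrom = gsel$chrom,
                           start = tile_start, end = tile_start + ws,
                           plant_chg = assign_chg, plant_k9 = assign_k9,
                           p_chg = th$p_chg, chip_rate = th$chip_rate)
    list(config = config, chrom_sizes = chrom_sizes, features = features,
         te_params = te_params,
         genic_te_hosts = sort(unlist(lapply(intronic, `[[`, "host_gene_id"))),
         intronic_tes = if (length(intronic)) rbindlist(intronic) else
           data.table(host_gene_id = character(), te_id = character(),
                      te_length = integer()),
         tss_high = tss_high)
  })
}

## planted methylation probability for sorted positions on one chromosome
.planted_p <- function(manifest, cn, pos, context) {
  cfg <- manifest$config
  bg <- switch(context, CG = cfg$background$p_cg,
               CHG = cfg$background$p_chg, CHH = cfg$background$p_chh)
  p <- rep(bg, length(pos))
  feats <- manifest$features[chrom == cn]
  pdt <- data.table(start = pos, end = pos + 1L, chrom = cn)
  ## gene bodies
  genes <- feats[kind == "gene"]
  if (nrow(genes)) {
    hits <- .overlap_pairs(pdt, genes)
    if (nrow(hits)) {
      g <- genes[hits$yid]
      t_rel <- (pos[hits$xid] - g$start) / pmax(g$end - g$start - 1L, 1L)
      gv <- switch(context,
                   CG = cfg$genes$cg_edge +
                     (cfg$genes$cg_mid - cfg$genes$cg_edge) * (1 - abs(2 * t_rel - 1)),
                   CHG = rep(cfg$genes$p_chg, nrow(hits)),
                   CHH = rep(cfg$genes$p_chh, nrow(hits)))
      p[hits$xid] <- gv
    }
  }
  ## spreading zones (linear decay from TE edge to local background)
  tes <- feats[kind == "TE"]
  tp <- manifest$te_params
  if (nrow(tes)) {
    tes2 <- tp[tes, on = "feature_id"]
    spreaders <- tes2[flank_decay_bp > 0L]
    if (nrow(spreaders)) {
      fam_p <- switch(context, CG = spreaders$p_cg, CHG = spreaders$p_chg,
                      CHH = spreaders$p_chh)
      for (i in seq_len(nrow(spreaders))) {
        D <- spreaders$flank_decay_bp[i]
        for (sideq in c("up", "down")) {
          if (sideq == "up") {
            zs <- spreaders$start[i] - D; ze <- spreaders$start[i]
          } else {
            zs <- spreaders$end[i]; ze <- spreaders$end[i] + D
          }
          sel <- which(pos >= zs & pos < ze)
          if (length(sel)) {
            dist <- if (sideq == "up") spreaders$start[i] - pos[sel]
                    else pos[sel] - spreaders$end[i] + 1L
            p[sel] <- p[sel] + (fam_p[i] - p[sel]) * pmax(0, 1 - dist / D)
          }
        }
      }
    }
    ## TE interiors override
    hits <- .overlap_pairs(pdt, tes2)
    if (nrow(hits)) {
      fam_p <- switch(context, CG = tes2$p_cg, CHG = tes2$p_chg, CHH = tes2$p_chh)
      p[hits$xid] <- fam_p[hits$yid]
    }
  }
  ## planted TSS tiles (CHG only)
  if (context == "CHG" && nrow(manifest$tss_high)) {
    tiles <- manifest$tss_high[plant_chg == TRUE & chrom == cn]
    if (nrow(tiles)) {
      hits <- .overlap_pairs(pdt, tiles)
      if (nrow(hits)) p[hits$xid] <- tiles$p_chg[hits$yid]
    }
  }
  p
}

#' Simulate a per-cytosine methylation report
#'
#' Cytosine sites are laid down at uniform random positions at the
#' configured per-context densities (contexts are site labels; no sequence
#' is modelled). Per-site read depth is Poisson(coverage) and methylated
#' reads are Binomial(depth, p) where p is the planted probability of the
#' enclosing feature regime, with linear decay over the flank for spreading
#' families.
#'
#' @param manifest from [simulate_genome()].
#' @return cytosine table in [read_cytosine_report()] layout.
#' @export
simulate_methylome <- function(manifest) {
  cfg <- manifest$config
  withr::with_seed(cfg$seed + 1L, {
    out <- list()
    for (cn in names(manifest$chrom_sizes)) {
      len <- manifest$chrom_sizes[[cn]]
      for (ctx in .CONTEXTS) {
        dens <- cfg$cytosine_density[[ctx]]
        n <- round(dens * len / 100)
        if (n < 1) next
        pos <- sort(sample.int(len, n)) - 1L
        p <- .planted_p(manifest, cn, pos, ctx)
        depth <- rpois(n, cfg$coverage)
        meth <- rbinom(n, depth, p)
        out[[length(out) + 1L]] <- data.table(
          chrom = cn, pos = pos,
          strand = sample(c("+", "-"), n, replace = TRUE),
          context = ctx, n_meth = meth, n_total = depth)
      }
    }
    cyt <- rbindlist(out)
    setorder(cyt, chrom, pos, context)
    cyt[, low_coverage := n_total < 1L]
    cyt[]
  })
}

## Poisson read sprinkle over [rstart - rl + 1, rend - 1] start positions so
## interior 100 bp windows see the target per-window intensity.
.sprinkle_reads <- function(rstart, rend, rate_per_window, ws, rl, chrom_len) {
  lambda_bp <- rate_per_window / (ws + rl - 1)
  npos <- (rend - rstart) + rl - 1L
  n <- rpois(1L, lambda_bp * npos)
  if (n == 0L) return(integer())
  s <- rstart - rl + 1L + .runif_int(n, 0L, npos - 1L)
  pmin(pmax(s, 0L), chrom_len - rl)
}

#' Simulate ChIP-seq reads
#'
#' Fixed-length single-end reads whose per-window expected overlap count
#' inside a feature equals that feature's planted chip rate; background
#' windows see the background rate. Feature rates below the background are
#' floored at the background (intensities are additive).
#'
#' @param manifest from [simulate_genome()].
#' @return read table in [read_chip_bed()] layout (sorted BED3).
#' @export
simulate_chip <- function(manifest) {
  cfg <- manifest$config
  ws <- cfg$window_size
  rl <- cfg$chip_read_length
  bg <- cfg$background$chip_rate
  withr::with_seed(cfg$seed + 2L, {
    starts <- list()
    chroms <- list()
    for (cn in names(manifest$chrom_sizes)) {
      len <- manifest$chrom_sizes[[cn]]
      s_bg <- .sprinkle_reads(0L, len, bg, ws, rl, len)
      starts[[length(starts) + 1L]] <- s_bg
      chroms[[length(chroms) + 1L]] <- rep(cn, length(s_bg))
      tes <- manifest$features[chrom == cn & kind == "TE"]
      if (nrow(tes)) {
        tes2 <- manifest$te_params[tes, on = "feature_id"]
        for (i in seq_len(nrow(tes2))) {
          extra <- max(0, tes2$chip_rate[i] - bg)
          if (extra > 0) {
            s <- .sprinkle_reads(tes2$start[i], tes2$end[i], extra, ws, rl, len)
            starts[[length(starts) + 1L]] <- s
            chroms[[length(chroms) + 1L]] <- rep(cn, length(s))
          }
        }
      }
      tiles <- manifest$tss_high[plant_k9 == TRUE & chrom == cn]
      if (nrow(tiles)) {
        for (i in seq_len(nrow(tiles))) {
          extra <- max(0, tiles$chip_rate[i] - bg)
          s <- .sprinkle_reads(tiles$start[i], tiles$end[i], extra, ws, rl, len)
          starts[[length(starts) + 1L]] <- s
          chroms[[length(chroms) + 1L]] <- rep(cn, length(s))
        }
      }
    }
    st <- unlist(starts)
    reads <- data.table(chrom = unlist(chroms), start = as.integer(st),
                        end = as.integer(st + rl))
    setorder(reads, chrom, start, end)
    reads[]
  })
}

#' Simulate a replicated expression table
#'
#' Planted per-gene RPKM values are log-normal draws; a configured fraction
#' of genes is exactly silent; genes in the planted TSS-high sets have their
#' planted RPKM multiplied by `suppression_multiplier` (0 by default, i.e.
#' fully silenced). Replicate counts are Poisson draws matching the planted
#' RPKM in expectation at the configured library size.
#'
#' @param manifest from [simulate_genome()].
#' @return list: `expression` (data.table `gene_id`, `length_bp`, one count
#'   column per replicate) and `planted_rpkm` (data.table `gene_id`,
#'   `planted_rpkm`).
#' @export
simulate_expression <- function(manifest) {
  cfg <- manifest$config
  ec <- cfg$expression
  withr::with_seed(cfg$seed + 3L, {
    genes <- manifest$features[kind == "gene"]
    n <- nrow(genes)
    planted <- rlnorm(n, ec$meanlog, ec$sdlog)
    n_silent <- round(ec$fraction_silent * n)
    silent <- sample.int(n, n_silent)
    planted[silent] <- 0
    high <- union(manifest$tss_high$gene_id[manifest$tss_high$plant_chg],
                  manifest$tss_high$gene_id[manifest$tss_high$plant_k9])
    planted[genes$feature_id %in% high] <-
      planted[genes$feature_id %in% high] * ec$suppression_multiplier
    len_kb <- (genes$end - genes$start) / 1000
    lib_m <- ec$library_size / 1e6
    counts <- matrix(rpois(n * ec$n_replicates,
                           rep(planted * len_kb * lib_m, ec$n_replicates)),
                     nrow = n)
    expr <- data.table(gene_id = genes$feature_id,
                       length_bp = genes$end - genes$start)
    for (r in seq_len(ec$n_replicates)) {
      expr[, (paste0("rep", r)) := counts[, r]]
    }
    list(expression = expr[],
         planted_rpkm = data.table(gene_id = genes$feature_id,
                                   planted_rpkm = planted))
  })
}

#' Simulate a window table with a planted CHG -> ChIP coupling
#'
#' Directly fabricates window-level rows (no genome) in which the ChIP read
#' sum is Poisson with rate `base_rate + slope * CHG_level` for windows with
#' CHH below `chh_break`, and `base_rate` otherwise. Used to validate the
#' structure of the CHG x CHH heatmap: within low-CHH rows, cell means must
#' increase along the CHG axis.
#'
#' @param n_windows number of windows.
#' @param seed integer seed.
#' @param base_rate,slope coupling parameters.
#' @param frac_low_chh fraction of windows drawn with CHH below `chh_break`.
#' @param chh_break CHH level separating coupled from flat windows.
#' @return window-like data.table with `level_CG`, `level_CHG`, `level_CHH`,
#'   `chip_count`.
#' @export
simulate_coupled_windows <- function(n_windows = 20000L, seed = 1L,
                                     base_rate = 5, slope = 30,
                                     frac_low_chh = 0.9, chh_break = 0.05) {
  withr::with_seed(seed, {
    chg <- runif(n_windows)
    low <- runif(n_windows) < frac_low_chh
    chh <- ifelse(low, runif(n_windows, 0, chh_break),
                  runif(n_windows, chh_break, 0.5))
    rate <- ifelse(chh < chh_break, base_rate + slope * chg, base_rate)
    data.table(level_CG = runif(n_windows), level_CHG = chg, level_CHH = chh,
               chip_count = rpois(n_windows, rate))
  })
}

#' Run every simulator stage and optionally write the files
#'
#' @param config a [sim_config()].
#' @param dir output directory (created); when NULL nothing is written.
#' @return manifest with added elements `cytosines`, `chip_reads`,
#'   `expression`, `planted_rpkm` and (when `dir` is given) `paths`.
#' @export
simulate_all <- function(config, dir = NULL) {
  manifest <- simulate_genome(config)
  manifest$cytosines <- simulate_methylome(manifest)
  manifest$chip_reads <- simulate_chip(manifest)
  ex <- simulate_expression(manifest)
  manifest$expression <- ex$expression
  manifest$planted_rpkm <- ex$planted_rpkm
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      gff3 = file.path(dir, "genes.gff3"),
      te_bed = file.path(dir, "tes.bed"),
      cytosine_report = file.path(dir, "cytosines.tsv"),
      chip_bed = file.path(dir, "chip_reads.bed"),
      expression = file.path(dir, "expression.tsv"),
      manifest = file.path(dir, "manifest.json"))
    write_gff3(manifest$features, paths$gff3)
    write_te_bed(manifest$features, paths$te_bed)
    write_cytosine_report(manifest$cytosines, paths$cytosine_report)
    fwrite(manifest$chip_reads, paths$chip_bed, sep = "\t", col.names = FALSE)
    fwrite(manifest$expression, paths$expression, sep = "\t")
    truth <- list(seed = config$seed,
                  chrom_sizes = as.list(manifest$chrom_sizes),
                  genic_te_hosts = manifest$genic_te_hosts,
                  intronic_tes = manifest$intronic_tes,
                  tss_high = manifest$tss_high,
                  te_params = manifest$te_params,
                  planted_rpkm = manifest$planted_rpkm)
    jsonlite::write_json(truth, paths$manifest, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
    manifest$paths <- paths
  }
  manifest
}

#' Write features to GFF3 / TE BED
#'
#' `write_gff3` emits gene and exon rows (1-based inclusive coordinates,
#' `ID`/`Parent` linkage, `gene_set`/`synteny`/`subgenome` attributes);
#' `write_te_bed` emits TE rows as BED6+2 (name, score, strand, te_class,
#' spreading).
#'
#' @param features feature table.
#' @param path output path.
#' @export
write_gff3 <- function(features, path) {
  ft <- as.data.table(features)[kind %in% c("gene", "exon")]
  attrs <- character(nrow(ft))
  g <- ft$kind == "gene"
  attrs[g] <- paste0("ID=", ft$feature_id[g],
                     ";gene_set=", ft$gene_set[g],
                     ";synteny=", ft$synteny[g],
                     ";subgenome=", ft$subgenome[g])
  attrs[!g] <- paste0("ID=", ft$feature_id[!g], ";Parent=", ft$parent_id[!g])
  lines <- paste(ft$chrom, "sim", ft$kind, ft$start + 1L, ft$end, ".",
                 ft$strand, ".", attrs, sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' @rdname write_gff3
#' @export
write_te_bed <- function(features, path) {
  te <- as.data.table(features)[kind == "TE"]
  out <- data.table(te$chrom, te$start, te$end, te$feature_id, 0L, te$strand,
                    te$te_class, te$spreading)
  fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}
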