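## End-to-end orchestration and the command-line interface. All numeric
## defaults are the canonical analysis parameters: 100 bp windows, 1 kb TE
## flanks, 2 kb upstream / 3 kb genic profile extents, 900-1000 bp flank
## bands, >1 kb genic-TE threshold, 1 and 2 SD ChIP cutoffs, top-decile CHG.

#' Pipeline run configuration
#'
#' @param cytosines,chip,gff3,te_bed,expr input file paths (see the readers
#'   in this package for the formats).
#' @param out output directory.
#' @param window_size window width in bp.
#' @param flank relative-profile flank (bp).
#' @param upstream,into_gene absolute-profile extents (bp).
#' @param flank_near,flank_far TE flank band (bp).
#' @param genic_te_min_len genic-TE length threshold (strict, bp).
#' @param k9_sig_sd,k9_tss_sd SD multipliers for window significance and the
#'   TSS promoter rule.
#' @param chg_quantile quantile defining the high-CHG cutoff.
#' @param expr_floor RPKM at or below which a gene is not expressed.
#' @param mask_genic_tes also produce gene profiles with genic TEs masked.
#' @param make_plots render line plots / heatmap PNGs (skipped with a
#'   message if no graphics device is available).
#' @return list of class `run_config`.
#' @export
run_config <- function(cytosines, chip, gff3, te_bed, expr = NULL,
                       out = "epilandscape_out",
                       window_size = 100L, flank = 1000L,
                       upstream = 2000L, into_gene = 3000L,
                       flank_near = 900L, flank_far = 1000L,
                       genic_te_min_len = 1000L,
                       k9_sig_sd = 1, k9_tss_sd = 2,
                       chg_quantile = 0.90, expr_floor = 0,
                       mask_genic_tes = TRUE, make_plots = TRUE) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

.log_line <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

.try_png <- function(path, expr, width = 900, height = 600) {
  ok <- tryCatch({
    grDevices::png(path, width = width, height = height, type = "cairo")
    TRUE
  }, error = function(e) {
    tryCatch({
      grDevices::png(path, width = width, height = height)
      TRUE
    }, error = function(e2) FALSE)
  })
  if (!ok) return(invisible(FALSE))
  on.exit(grDevices::dev.off())
  force(expr)
  invisible(TRUE)
}

.plot_profile <- function(prof, tracks, main) {
  for (tr in tracks) {
    d <- prof[track == tr][order(bin_index)]
    graphics::plot(d$bin_index, d$mean, type = "l", xlab = "bin",
                   ylab = tr, main = paste(main, tr))
  }
}

#' Run the full windowed chromatin-landscape pipeline
#'
#' Reads the inputs, builds the 100 bp window table (weighted methylation +
#' ChIP read sums + location labels), then computes tile-level
#' distributions, the CHG x CHH heatmap, relative TE profiles, absolute
#' gene profiles (optionally with genic TEs masked), TE sub-family and
#' flank summaries, the genic-TE catalog and class enrichment, TSS
#' chromatin-state classification, expression grouping and the class x
#' expression crosstab. Every stage's table is written as TSV to the output
#' directory along with a run log recording realized data-derived cutoffs.
#'
#' @param config a [run_config()].
#' @param chrom_sizes optional named vector; when NULL, inferred as the
#'   maximum annotated/observed coordinate per chromosome rounded up to a
#'   window boundary.
#' @return invisibly, a list with the main in-memory results.
#' @export
run_pipeline <- function(config, chrom_sizes = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  log_con <- file(file.path(config$out, "run_log.txt"), open = "wt")
  on.exit(close(log_con), add = TRUE)
  fail <- function(stage, e) {
    writeLines(paste0("FAILED at stage: ", stage), file.path(config$out, "FAILED"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e))
  }
  stage <- function(name, expr) {
    .log_line(log_con, "stage: ", name)
    tryCatch(expr, error = function(e) fail(name, e))
  }

  inputs <- stage("read_inputs", {
    list(cyt = read_cytosine_report(config$cytosines),
         chip = read_chip_bed(config$chip),
         features = read_features(config$gff3, config$te_bed),
         expr = if (!is.null(config$expr)) read_expression_table(config$expr) else NULL)
  })
  feats <- inputs$features
  genes <- feats[kind == "gene"]
  tes <- feats[kind == "TE"]
  .log_line(log_con, "records: ", nrow(inputs$cyt), " cytosines, ",
            nrow(inputs$chip), " chip reads, ", nrow(genes), " genes, ",
            nrow(tes), " TEs")

  win <- stage("windows", {
    if (is.null(chrom_sizes)) {
      ext <- rbind(feats[, .(chrom, end)], inputs$chip[, .(chrom, end)],
                   inputs$cyt[, .(chrom, end = pos + 1L)])
      mx <- ext[, .(len = max(end)), by = chrom]
      chrom_sizes <- setNames(
        as.integer(ceiling(mx$len / config$window_size) * config$window_size),
        mx$chrom)
      .log_line(log_con, "inferred chrom sizes: ",
                paste(names(chrom_sizes), chrom_sizes, collapse = ", "))
    }
    w <- tile_genome(chrom_sizes, config$window_size)
    w <- weighted_methylation(inputs$cyt, w)
    w <- chip_window_counts(inputs$chip, w)
    w <- classify_window_location(w, feats)
    write_window_table(w, file.path(config$out, "window_table.tsv"))
    w
  })

  stage("distributions", {
    hists <- rbindlist(lapply(.CONTEXTS, function(ctx) {
      h <- level_distribution(win, ctx)
      h[, context := ctx]
    }))
    fwrite(hists, file.path(config$out, "level_histograms.tsv"), sep = "\t")
    thr1 <- significance_threshold(win$chip_count, k = config$k9_sig_sd)
    .log_line(log_con, sprintf(
      "window H3K9me2 significance cutoff (mean + %g sd): %.3f; %d/%d windows significant",
      config$k9_sig_sd, thr1$cutoff, sum(flag_significant(win$chip_count, thr1)),
      nrow(win)))
  })

  heat <- stage("heatmap", {
    h <- chg_chh_heatmap(win)
    fwrite(h, file.path(config$out, "chg_chh_heatmap.tsv"), sep = "\t", na = "NA")
    if (config$make_plots) {
      .try_png(file.path(config$out, "chg_chh_heatmap.png"), {
        m <- matrix(h$mean_chip, nrow = 10, ncol = 9, byrow = TRUE)
        graphics::image(x = 1:10, y = 1:9, z = m, xlab = "CHG bin",
                        ylab = "CHH bin", main = "mean H3K9me2 read sum")
      })
    }
    h
  })

  rel <- stage("relative_profile", {
    p <- relative_profile(win, tes, flank = config$flank)
    fwrite(p, file.path(config$out, "te_relative_profile.tsv"), sep = "\t", na = "NA")
    if (config$make_plots) {
      .try_png(file.path(config$out, "te_relative_profile.png"), {
        graphics::par(mfrow = c(2, 2))
        .plot_profile(p, unique(p$track), "TE profile:")
      })
    }
    p
  })

  gene_prof <- stage("gene_profiles", {
    gp <- absolute_gene_profile(win, genes, config$upstream, config$into_gene)
    fwrite(gp$five_prime, file.path(config$out, "gene_profile_5p.tsv"),
           sep = "\t", na = "NA")
    fwrite(gp$three_prime, file.path(config$out, "gene_profile_3p.tsv"),
           sep = "\t", na = "NA")
    if (config$make_plots) {
      .try_png(file.path(config$out, "gene_profile_5p.png"), {
        graphics::par(mfrow = c(2, 2))
        .plot_profile(gp$five_prime, unique(gp$five_prime$track), "5' profile:")
      })
    }
    gp
  })

  catalog <- stage("genic_te_catalog", {
    cat_res <- genic_te_catalog(tes, feats, config$genic_te_min_len)
    fwrite(cat_res$catalog, file.path(config$out, "genic_te_catalog.tsv"), sep = "\t")
    writeLines(cat_res$flagged_genes,
               file.path(config$out, "genes_with_genic_te.txt"))
    .log_line(log_con, length(cat_res$flagged_genes), "/", nrow(genes),
              " genes carry a >", config$genic_te_min_len,
              " bp intronic TE (", cat_res$n_boundary_tes,
              " long TEs overlap genes without intron containment)")
    chroma <- genic_te_chromatin(win, cat_res, tes, feats)
    fwrite(chroma, file.path(config$out, "genic_te_chromatin.tsv"),
           sep = "\t", na = "NA")
    enr <- class_enrichment_in_genes(cat_res, tes)
    fwrite(enr, file.path(config$out, "genic_te_class_enrichment.tsv"),
           sep = "\t", na = "NA")
    cat_res
  })

  if (config$mask_genic_tes) {
    stage("masked_profiles", {
      mask <- tes[tes$feature_id %in% catalog$catalog$te_id]
      mp <- masked_profile(win, genes, mask, config$upstream, config$into_gene)
      fwrite(mp$five_prime, file.path(config$out, "gene_profile_5p_masked.tsv"),
             sep = "\t", na = "NA")
      fwrite(mp$three_prime, file.path(config$out, "gene_profile_3p_masked.tsv"),
             sep = "\t", na = "NA")
    })
  }

  stage("te_summaries", {
    ss <- subfamily_summary(win, tes, group_field = c("te_subfamily", "spreading"))
    fwrite(ss, file.path(config$out, "subfamily_summary.tsv"), sep = "\t", na = "NA")
    fs <- flank_summary(win, tes, config$flank_near, config$flank_far)
    fwrite(fs, file.path(config$out, "flank_summary.tsv"), sep = "\t", na = "NA")
    nd <- nearest_gene_distance(tes, genes)
    fwrite(nd$per_subfamily, file.path(config$out, "te_nearest_gene.tsv"),
           sep = "\t", na = "NA")
  })

  cls <- stage("classify", {
    hi <- high_tss_genes(genes, win, config$chg_quantile, config$k9_tss_sd)
    .log_line(log_con, sprintf(
      "realized high-CHG TSS cutoff (quantile %.2f of window CHG): %.4f",
      config$chg_quantile, hi$chg_cutoff))
    .log_line(log_con, sprintf(
      "realized high-H3K9me2 TSS cutoff (mean + %g sd): %.3f",
      config$k9_tss_sd, hi$k9_threshold$cutoff))
    .log_line(log_con, length(hi$high_chg), " high-CHG TSS genes, ",
              length(hi$high_k9), " high-H3K9me2 TSS genes, ",
              length(hi$both), " both")
    writeLines(hi$high_chg, file.path(config$out, "genes_high_chg_tss.txt"))
    writeLines(hi$high_k9, file.path(config$out, "genes_high_k9_tss.txt"))
    fwrite(hi$set_means, file.path(config$out, "tss_set_means.tsv"),
           sep = "\t", na = "NA")
    hi
  })

  result <- list(windows = win, heatmap = heat, relative = rel,
                 gene_profiles = gene_prof, catalog = catalog, tss = cls)

  if (!is.null(inputs$expr)) {
    stage("expression", {
      rp <- compute_rpkm(inputs$expr)
      grp <- expression_groups(rp, floor = config$expr_floor)
      classification <- grp[, .(gene_id, rpkm, expr_group)]
      classification[, has_genic_te := gene_id %in% catalog$flagged_genes]
      classification[, high_chg_tss := gene_id %in% cls$high_chg]
      classification[, high_k9_tss := gene_id %in% cls$high_k9]
      fwrite(classification, file.path(config$out, "gene_classification.tsv"),
             sep = "\t", na = "NA")
      xt <- class_expression_crosstab(classification)
      fwrite(xt, file.path(config$out, "expression_crosstab.tsv"),
             sep = "\t", na = "NA")
      result$classification <- classification
      result$crosstab <- xt
    })
  }
  .log_line(log_con, "pipeline complete: ", config$out)
  invisible(result)
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (emit a synthetic dataset), `all` (full
#' pipeline), plus stage-wise `windows`, `profiles`, `te-summary`,
#' `classify` which run the corresponding subset. Returns an exit status
#' (0 on success) rather than calling `quit()`, so it is testable; the
#' installed `exec/epilandscape` script forwards the status.
#'
#' @param args character vector of command-line arguments (default: the
#'   process's trailing arguments).
#' @return integer exit status, invisibly.
#' @export
el_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: epilandscape <simulate|all|windows|profiles|te-summary|classify> [options]",
    "  simulate: --seed INT -o DIR",
    "  analysis: --cytosines F --chip F --genes F --tes F [--expr F] -o DIR",
    "            [--window-size N --flank N --chg-quantile Q --no-mask --no-plots]",
    sep = "\n")
  status <- tryCatch({
    if (!length(args)) stop(usage, call. = FALSE)
    cmd <- args[1L]
    rest <- args[-1L]
    opts <- list(
      optparse::make_option("--cytosines", type = "character"),
      optparse::make_option("--chip", type = "character"),
      optparse::make_option("--genes", type = "character"),
      optparse::make_option("--tes", type = "character"),
      optparse::make_option("--expr", type = "character", default = NULL),
      optparse::make_option(c("-o", "--out"), type = "character",
                            default = "epilandscape_out"),
      optparse::make_option("--seed", type = "integer", default = 1L),
      optparse::make_option("--window-size", type = "integer", default = 100L,
                            dest = "window_size"),
      optparse::make_option("--flank", type = "integer", default = 1000L),
      optparse::make_option("--chg-quantile", type = "double", default = 0.90,
                            dest = "chg_quantile"),
      optparse::make_option("--no-mask", action = "store_true", default = FALSE,
                            dest = "no_mask"),
      optparse::make_option("--no-plots", action = "store_true", default = FALSE,
                            dest = "no_plots"))
    parsed <- optparse::parse_args(optparse::OptionParser(option_list = opts),
                                   args = rest)
    if (cmd == "simulate") {
      cfg <- sim_config(seed = parsed$seed)
      simulate_all(cfg, dir = parsed$out)
      message("synthetic dataset written to ", parsed$out)
    } else if (cmd %in% c("all", "windows", "profiles", "te-summary", "classify")) {
      need <- c("cytosines", "chip", "genes", "tes")
      miss <- need[vapply(need, function(k) is.null(parsed[[k]]), logical(1))]
      if (length(miss)) {
        stop("missing required option(s): ", paste0("--", miss, collapse = ", "))
      }
      rc <- run_config(cytosines = parsed$cytosines, chip = parsed$chip,
                       gff3 = parsed$genes, te_bed = parsed$tes,
                       expr = parsed$expr, out = parsed$out,
                       window_size = parsed$window_size, flank = parsed$flank,
                       chg_quantile = parsed$chg_quantile,
                       mask_genic_tes = !parsed$no_mask,
                       make_plots = !parsed$no_plots)
      run_pipeline(rc)
    } else {
      stop("unknown subcommand '", cmd, "'\n", usage, call. = FALSE)
    }
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
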