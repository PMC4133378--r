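## CHG x CHH -> H3K9me2 heatmap, TSS chromatin-state gene classification,
## RPKM and five-category expression grouping, class x expression crosstab.

## CHH bin edges in percent. Nine groups: 0-5% by 1%, 5-20% by 5%, then >20%.
## The 8th bin is closed at 20 so the edges partition [0,100] with no gaps;
## the top bins are closed so no valid level is unbinned.
.chh_bin <- function(level) {
  p <- level * 100
  b <- rep(NA_integer_, length(p))
  b[p < 1] <- 1L
  b[p >= 1 & p < 2] <- 2L
  b[p >= 2 & p < 3] <- 3L
  b[p >= 3 & p < 4] <- 4L
  b[p >= 4 & p < 5] <- 5L
  b[p >= 5 & p < 10] <- 6L
  b[p >= 10 & p < 15] <- 7L
  b[p >= 15 & p <= 20] <- 8L
  b[p > 20] <- 9L
  b
}

## CHG: ten equal groups from 0 to 100%, top edge closed.
.chg_bin <- function(level) {
  pmin(as.integer(floor(level * 10)) + 1L, 10L)
}

#' CHG x CHH methylation heatmap of mean H3K9me2
#'
#' Windows with data on all three marks (defined CHG level, defined CHH
#' level, and a ChIP read sum) are cross-tabulated into 10 CHG groups (equal
#' 10% steps from 0 to 100%) by 9 CHH groups (1% steps to 5%, 5% steps to
#' 20%, then >20%), 90 cells in total; the cell value is the mean ChIP read
#' sum over member windows.
#'
#' @param windows window table with `level_CHG`, `level_CHH`, `chip_count`.
#' @return data.table with one row per cell: `chg_bin` (1-10), `chh_bin`
#'   (1-9), `mean_chip` (NA when empty), `n_windows`. All 90 cells present.
#' @export
chg_chh_heatmap <- function(windows) {
  W <- as.data.table(windows)
  .check_tracks(W, c("level_CHG", "level_CHH", "chip_count"))
  use <- W[!is.na(level_CHG) & !is.na(level_CHH) & !is.na(chip_count)]
  grid <- CJ(chg_bin = 1:10, chh_bin = 1:9)
  if (!nrow(use)) {
    grid[, `:=`(mean_chip = NA_real_, n_windows = 0L)]
    return(grid[])
  }
  cells <- use[, .(chg_bin = .chg_bin(level_CHG), chh_bin = .chh_bin(level_CHH),
                   chip_count)][
    , .(mean_chip = mean(chip_count), n_windows = .N), by = .(chg_bin, chh_bin)]
  out <- cells[grid, on = c("chg_bin", "chh_bin")]
  out[is.na(n_windows), n_windows := 0L]
  setorder(out, chg_bin, chh_bin)
  out[]
}

#' Window overlapping each gene's transcription start site
#'
#' The TSS is the gene's first base in transcription order: `start` for
#' plus-strand genes, `end - 1` for minus-strand genes. Exactly one tile of
#' the genome tiling contains it.
#'
#' @param genes gene rows of a feature table (strand required).
#' @param windows tiling-derived window table.
#' @return data.table: `gene_id` plus the matching window row columns.
#' @export
tss_window <- function(genes, windows) {
  G <- as.data.table(genes)
  W <- as.data.table(windows)
  if (any(!G$strand %in% c("+", "-"))) {
    stop("gene(s) without strand: ",
         paste(head(G$feature_id[!G$strand %in% c("+", "-")], 3), collapse = ", "))
  }
  tss <- ifelse(G$strand == "+", G$start, G$end - 1L)
  idx <- .window_index(G$chrom, tss, W, what = "TSS")
  row <- match(idx, W$win_id)
  cbind(data.table(gene_id = G$feature_id, tss = tss), W[row])
}

#' Genes with high CHG methylation or high H3K9me2 at the TSS
#'
#' The CHG cutoff is the empirical `chg_quantile` quantile of all defined
#' window CHG levels genome-wide (it is a property of the dataset, not a
#' fixed constant); the H3K9me2 cutoff is mean + `k9_sd_mult` population
#' standard deviations of the window ChIP read sums. A gene is flagged when
#' the value in its TSS-overlapping tile strictly exceeds the cutoff.
#'
#' @param genes gene rows of a feature table.
#' @param windows window table with `level_CHG` and `chip_count`.
#' @param chg_quantile quantile defining the CHG cutoff (default 0.90, i.e.
#'   the top decile boundary).
#' @param k9_sd_mult SD multiplier for the H3K9me2 cutoff (default 2).
#' @return list with `high_chg`, `high_k9`, `both` (gene id vectors),
#'   `chg_cutoff`, `k9_threshold` (a `sig_threshold`), `tss` (per-gene TSS
#'   window table with `high_chg_tss` / `high_k9_tss` flags) and
#'   `set_means` (mean TSS CHG and chip within each flag set).
#' @export
high_tss_genes <- function(genes, windows, chg_quantile = 0.90, k9_sd_mult = 2) {
  G <- as.data.table(genes)
  if (!nrow(G)) stop("no genes supplied")
  W <- as.data.table(windows)
  .check_tracks(W, c("level_CHG", "chip_count"))
  chg_cutoff <- unname(quantile(W$level_CHG, chg_quantile, na.rm = TRUE))
  thr <- significance_threshold(W$chip_count, k = k9_sd_mult)
  tssw <- tss_window(G, W)
  tssw[, high_chg_tss := !is.na(level_CHG) & level_CHG > chg_cutoff]
  tssw[, high_k9_tss := !is.na(chip_count) & chip_count > thr$cutoff]
  high_chg <- tssw$gene_id[tssw$high_chg_tss]
  high_k9 <- tssw$gene_id[tssw$high_k9_tss]
  sets <- list(high_chg = tssw$high_chg_tss, high_k9 = tssw$high_k9_tss,
               both = tssw$high_chg_tss & tssw$high_k9_tss,
               all_genes = rep(TRUE, nrow(tssw)))
  set_means <- rbindlist(lapply(names(sets), function(s) {
    sel <- sets[[s]]
    data.table(set = s, n = sum(sel),
               mean_chg = if (any(sel)) mean(tssw$level_CHG[sel], na.rm = TRUE) else NA_real_,
               mean_chip = if (any(sel)) mean(tssw$chip_count[sel], na.rm = TRUE) else NA_real_)
  }))
  list(high_chg = high_chg, high_k9 = high_k9,
       both = intersect(high_chg, high_k9),
       chg_cutoff = chg_cutoff, k9_threshold = thr,
       tss = tssw[], set_means = set_means[])
}

#' Reads per kilobase per million mapped (RPKM)
#'
#' Per replicate, `rpkm = count / (gene_length_kb * library_size_millions)`
#' where the library size is that replicate's total mapped count; the gene
#' value aggregates replicates (mean by default).
#'
#' @param expression table from [read_expression_table()]: `gene_id`,
#'   `length_bp`, replicate count columns (or a precomputed `rpkm` column,
#'   returned as-is).
#' @param replicate_policy "mean" (default) or "median".
#' @return data.table `gene_id`, `rpkm`.
#' @export
compute_rpkm <- function(expression, replicate_policy = c("mean", "median")) {
  replicate_policy <- match.arg(replicate_policy)
  dt <- as.data.table(expression)
  if ("rpkm" %in% names(dt)) {
    return(dt[, .(gene_id, rpkm = as.numeric(rpkm))])
  }
  cnt_cols <- setdiff(names(dt), c("gene_id", "length_bp"))
  if (!length(cnt_cols)) stop("no replicate count columns found")
  if (!"length_bp" %in% names(dt)) stop("length_bp column required for counts")
  if (any(dt$length_bp <= 0)) stop("gene lengths must be positive")
  counts <- as.matrix(dt[, cnt_cols, with = FALSE])
  lib <- colSums(counts)
  if (any(lib == 0)) {
    stop("replicate(s) with zero total mapped reads: ",
         paste(cnt_cols[lib == 0], collapse = ", "))
  }
  rpkm_mat <- sweep(counts / (dt$length_bp / 1000), 2, lib / 1e6, "/")
  val <- switch(replicate_policy,
                mean = rowMeans(rpkm_mat),
                median = apply(rpkm_mat, 1, stats::median))
  data.table(gene_id = dt$gene_id, rpkm = val)
}

#' Five-category expression grouping
#'
#' Genes at or below the expression floor are `not_expressed`; the remaining
#' genes are ranked by RPKM (ties broken by gene id for determinism) and cut
#' into four quartiles of equal size (within one gene), `Q1` lowest to `Q4`
#' highest.
#'
#' @param rpkm data.table `gene_id`, `rpkm` from [compute_rpkm()].
#' @param floor expression floor (default 0: only exact zeros are
#'   `not_expressed`).
#' @return data.table `gene_id`, `rpkm`, `expr_group` (factor with levels
#'   not_expressed, Q1..Q4).
#' @export
expression_groups <- function(rpkm, floor = 0) {
  dt <- as.data.table(rpkm)[, .(gene_id, rpkm)]
  lv <- c("not_expressed", "Q1", "Q2", "Q3", "Q4")
  dt[, expr_group := factor(NA_character_, levels = lv)]
  dt[rpkm <= floor, expr_group := factor("not_expressed", levels = lv)]
  ex <- which(dt$rpkm > floor)
  if (length(ex)) {
    ord <- ex[order(dt$rpkm[ex], dt$gene_id[ex])]
    q <- ceiling(4 * seq_along(ord) / length(ord))
    dt[ord, expr_group := factor(paste0("Q", q), levels = lv)]
  }
  dt[]
}

#' Expression crosstab of gene classes
#'
#' For each logical gene flag (e.g. carries a large intronic TE, high-CHG
#' TSS, high-H3K9me2 TSS), the proportion of flagged genes in each of the
#' five expression categories. A background row over all genes is included;
#' each row with n > 0 sums to 1.
#'
#' @param classification data.table with `gene_id`, `expr_group` and one or
#'   more logical flag columns.
#' @param flags flag column names (default: all logical columns).
#' @return data.table: `flag`, `n`, then one proportion column per
#'   expression category.
#' @export
class_expression_crosstab <- function(classification, flags = NULL) {
  dt <- as.data.table(classification)
  if (!all(c("gene_id", "expr_group") %in% names(dt))) {
    stop("classification needs gene_id and expr_group columns")
  }
  if (is.null(flags)) {
    flags <- names(dt)[vapply(dt, is.logical, logical(1))]
  }
  lv <- c("not_expressed", "Q1", "Q2", "Q3", "Q4")
  groups <- factor(as.character(dt$expr_group), levels = lv)
  row_for <- function(sel, label) {
    n <- sum(sel, na.rm = TRUE)
    props <- if (n > 0) {
      as.numeric(table(groups[which(sel)]) / n)
    } else rep(NA_real_, length(lv))
    out <- data.table(flag = label, n = n)
    for (i in seq_along(lv)) out[, (lv[i]) := props[i]]
    out
  }
  rows <- rbindlist(c(list(row_for(rep(TRUE, nrow(dt)), "all_genes")),
                      lapply(flags, function(f) row_for(dt[[f]], f))))
  rows[]
}
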