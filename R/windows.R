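## Genome tiling, weighted methylation per window, ChIP read sums,
## significance thresholds, tile-level distributions and location labels.

#' Tile a genome into fixed-size non-overlapping windows
#'
#' Each chromosome is partitioned into consecutive `window_size` bp windows;
#' the terminal window may be shorter. The tiling has no gaps or overlaps and
#' conserves total bp.
#'
#' @param chrom_sizes named integer vector of chromosome lengths (bp).
#' @param window_size window width in bp (default 100).
#' @return data.table with `chrom`, `start`, `end`, `win_id` (global 1..n).
#'   Attributes `window_size` and `chrom_sizes` record the tiling.
#' @export
tile_genome <- function(chrom_sizes, window_size = 100L) {
  if (length(window_size) != 1L || is.na(window_size) || window_size <= 0) {
    stop("window_size must be a positive integer")
  }
  window_size <- as.integer(window_size)
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes)))) {
    stop("chrom_sizes must be a named vector")
  }
  if (any(chrom_sizes <= 0)) stop("chromosome sizes must be positive")
  pieces <- lapply(names(chrom_sizes), function(cn) {
    len <- as.integer(chrom_sizes[[cn]])
    starts <- seq.int(0L, len - 1L, by = window_size)
    data.table(chrom = cn, start = starts,
               end = pmin(starts + window_size, len))
  })
  out <- rbindlist(pieces)
  out[, win_id := .I]
  setattr(out, "window_size", window_size)
  setattr(out, "chrom_sizes", chrom_sizes)
  out[]
}

.window_size_of <- function(windows) {
  ws <- attr(windows, "window_size")
  if (is.null(ws)) ws <- max(windows$end - windows$start)
  as.integer(ws)
}

## Map positions to the win_id of the tiling; errors on unknown chrom or
## out-of-range position.
.window_index <- function(chrom, pos, windows, what = "position") {
  ws <- .window_size_of(windows)
  ## first global window index per chromosome, and chromosome extents
  info <- windows[, .(first = win_id[1L], len = max(end)), by = chrom]
  m <- match(chrom, info$chrom)
  if (anyNA(m)) {
    stop(what, " on unknown chromosome: ",
         paste(unique(chrom[is.na(m)]), collapse = ", "))
  }
  if (any(pos < 0) || any(pos >= info$len[m])) {
    bad <- which(pos < 0 | pos >= info$len[m])[1L]
    stop(what, " outside chromosome bounds: ", chrom[bad], ":", pos[bad])
  }
  info$first[m] + pos %/% ws
}

#' Weighted methylation levels per window
#'
#' For every window and sequence context, the weighted methylation level is
#' the sum of methylated read counts divided by the sum of total read counts
#' over all cytosines of that context in the window — read-count-weighted,
#' not a mean of per-site fractions. Windows with no covered cytosine in a
#' context get a missing level (`NA`), which downstream averages exclude;
#' missing is not 0. Cytosines from both strands are pooled.
#'
#' @param cytosines table from [read_cytosine_report()].
#' @param windows tiling from [tile_genome()].
#' @param min_sites minimum number of covered cytosines (total reads > 0)
#'   required for a level to be reported (default 1).
#' @param use_low_coverage include records flagged `low_coverage`
#'   (default TRUE; they still carry reads).
#' @return copy of `windows` with, per context C in CG/CHG/CHH: `meth_C`,
#'   `total_C`, `covered_C` and `level_C`.
#' @export
weighted_methylation <- function(cytosines, windows, min_sites = 1L,
                                 use_low_coverage = TRUE) {
  cyt <- as.data.table(cytosines)
  if (!use_low_coverage && "low_coverage" %in% names(cyt)) {
    cyt <- cyt[low_coverage == FALSE]
  }
  out <- copy(as.data.table(windows))
  keep_attrs <- attributes(windows)[c("window_size", "chrom_sizes")]
  idx <- .window_index(cyt$chrom, cyt$pos, windows, what = "cytosine")
  agg <- data.table(win_id = idx, context = cyt$context,
                    n_meth = cyt$n_meth, n_total = cyt$n_total)[
    , .(meth = sum(n_meth), total = sum(n_total), covered = sum(n_total > 0L)),
    by = .(win_id, context)]
  for (ctx in .CONTEXTS) {
    a <- agg[context == ctx]
    m <- match(out$win_id, a$win_id)
    meth <- ifelse(is.na(m), 0L, a$meth[m])
    total <- ifelse(is.na(m), 0L, a$total[m])
    covered <- ifelse(is.na(m), 0L, a$covered[m])
    level <- ifelse(total > 0L & covered >= min_sites, meth / total, NA_real_)
    set(out, j = paste0("meth_", ctx), value = as.integer(meth))
    set(out, j = paste0("total_", ctx), value = as.integer(total))
    set(out, j = paste0("covered_", ctx), value = as.integer(covered))
    set(out, j = paste0("level_", ctx), value = level)
  }
  for (a in names(keep_attrs)) setattr(out, a, keep_attrs[[a]])
  out[]
}

#' Sum of intersecting ChIP reads per window
#'
#' A read increments every window it overlaps by at least 1 bp (BED-intersect
#' semantics), so a read spanning a window boundary is counted in both
#' windows.
#'
#' @param reads table from [read_chip_bed()].
#' @param windows tiling from [tile_genome()].
#' @param scale either "raw" (default, raw read sums) or "cpm"
#'   (counts per million reads, for cross-library comparison).
#' @return copy of `windows` with a `chip_count` column.
#' @export
chip_window_counts <- function(reads, windows, scale = c("raw", "cpm")) {
  scale <- match.arg(scale)
  reads <- as.data.table(reads)
  out <- copy(as.data.table(windows))
  keep_attrs <- attributes(windows)[c("window_size", "chrom_sizes")]
  ws <- .window_size_of(windows)
  info <- out[, .(first = win_id[1L], nwin = .N), by = chrom]
  counts <- numeric(nrow(out))
  if (nrow(reads)) {
    m <- match(reads$chrom, info$chrom)
    if (anyNA(m)) {
      stop("ChIP read on unknown chromosome: ",
           paste(unique(reads$chrom[is.na(m)]), collapse = ", "))
    }
    lo <- pmax(reads$start %/% ws, 0L)
    hi <- pmin((reads$end - 1L) %/% ws, info$nwin[m] - 1L)
    lo <- pmin(lo, info$nwin[m] - 1L)
    first <- info$first[m]
    ## difference-array accumulation over global window indices
    delta <- numeric(nrow(out) + 1L)
    ia <- first + lo
    ib <- first + hi + 1L
    ta <- tabulate(ia, nbins = nrow(out) + 1L)
    tb <- tabulate(ib, nbins = nrow(out) + 1L)
    counts <- cumsum(ta - tb)[seq_len(nrow(out))]
  }
  if (scale == "cpm" && nrow(reads)) counts <- counts * 1e6 / nrow(reads)
  out[, chip_count := counts]
  for (a in names(keep_attrs)) setattr(out, a, keep_attrs[[a]])
  out[]
}

#' Significance threshold as mean + k standard deviations
#'
#' Genome-wide windows are treated as the full population of interest, so the
#' population standard deviation (denominator n) is used. Values are flagged
#' when strictly greater than the cutoff.
#'
#' @param values numeric vector (e.g. per-window ChIP read sums).
#' @param k standard-deviation multiplier (1 for window significance, 2 for
#'   the TSS promoter rule).
#' @return object of class `sig_threshold`: list with `mean`, `sd`, `k`,
#'   `cutoff`.
#' @export
significance_threshold <- function(values, k = 1) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) stop("need at least 2 values for a threshold")
  mu <- mean(values)
  sigma <- sqrt(mean((values - mu)^2)) # population sd
  structure(list(mean = mu, sd = sigma, k = k, cutoff = mu + k * sigma),
            class = "sig_threshold")
}

#' @rdname significance_threshold
#' @param threshold a `sig_threshold` object.
#' @return `flag_significant`: logical vector, TRUE where `values > cutoff`
#'   (strict; NA values give NA).
#' @export
flag_significant <- function(values, threshold) {
  stopifnot(inherits(threshold, "sig_threshold"))
  values > threshold$cutoff
}

#' @export
print.sig_threshold <- function(x, ...) {
  cat(sprintf("threshold: mean %.4g + %g * sd %.4g = %.4g (strict >)\n",
              x$mean, x$k, x$sd, x$cutoff))
  invisible(x)
}

#' Distribution of window methylation levels
#'
#' Histogram of tile counts per level bin for one context, over windows with
#' a defined (non-missing) level. Bins are half-open `[lo, hi)` with the
#' final bin closed at the top.
#'
#' @param windows window table carrying `level_<context>` columns.
#' @param context one of "CG", "CHG", "CHH".
#' @param bin_edges increasing numeric vector of bin boundaries on \[0,1\]
#'   (default deciles).
#' @return data.table `bin_low`, `bin_high`, `count`, `proportion`
#'   (proportions sum to 1 over covered windows); attribute `n` = number of
#'   non-missing windows.
#' @export
level_distribution <- function(windows, context = c("CG", "CHG", "CHH"),
                               bin_edges = seq(0, 1, by = 0.1)) {
  context <- match.arg(context)
  if (is.unsorted(bin_edges, strictly = TRUE)) {
    stop("bin_edges must be strictly increasing")
  }
  lv <- windows[[paste0("level_", context)]]
  lv <- lv[!is.na(lv)]
  nb <- length(bin_edges) - 1L
  idx <- findInterval(lv, bin_edges, rightmost.closed = TRUE, all.inside = FALSE)
  idx <- idx[idx >= 1L & idx <= nb]
  cnt <- tabulate(idx, nbins = nb)
  out <- data.table(bin_low = bin_edges[-length(bin_edges)],
                    bin_high = bin_edges[-1L],
                    count = cnt,
                    proportion = if (length(lv)) cnt / length(lv) else rep(NA_real_, nb))
  setattr(out, "n", length(lv))
  out[]
}

#' Label windows by genomic location
#'
#' A window is `genic` if it overlaps any gene, `TE` if it overlaps any
#' transposable element, `both` if both, otherwise `other`.
#'
#' @param windows window table.
#' @param features feature table from [read_features()].
#' @return copy of `windows` with a `location` column.
#' @export
classify_window_location <- function(windows, features) {
  out <- copy(as.data.table(windows))
  keep_attrs <- attributes(windows)[c("window_size", "chrom_sizes")]
  features <- as.data.table(features)
  in_gene <- .overlaps_any(out, features[kind == "gene"])
  in_te <- .overlaps_any(out, features[kind == "TE"])
  out[, location := fifelse(in_gene & in_te, "both",
                     fifelse(in_gene, "genic",
                     fifelse(in_te, "TE", "other")))]
  for (a in names(keep_attrs)) setattr(out, a, keep_attrs[[a]])
  out[]
}
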