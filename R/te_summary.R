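## Transposon sub-family chromatin summaries, flank-band summaries,
## nearest-gene distances, genic-TE cataloguing and class enrichment.

#' Per-sub-family chromatin summary
#'
#' For each transposon sub-family (or any grouping of TE metadata), the mean
#' of each track is taken over the 100 bp windows that overlap or fall
#' within any member element. A window overlapping elements of two groups
#' contributes to both; within one group each window is counted once.
#' Pooling is window-weighted by default; `element_first = TRUE` averages
#' per element before averaging over elements.
#'
#' @param windows window table carrying the requested tracks.
#' @param tes TE rows of a feature table.
#' @param group_field grouping column(s) of `tes` (default `te_subfamily`;
#'   e.g. `c("te_subfamily", "spreading")` to split by spreading class).
#' @param tracks track columns.
#' @param element_first average within elements first (default FALSE).
#' @return data.table: group columns, `n_elements`, then per track
#'   `mean_<track>` and `n_<track>` (contributing windows with data).
#' @export
subfamily_summary <- function(windows, tes, group_field = "te_subfamily",
                              tracks = .DEFAULT_TRACKS,
                              element_first = FALSE) {
  W <- as.data.table(windows)
  TE <- as.data.table(tes)
  .check_tracks(W, tracks)
  miss <- setdiff(group_field, names(TE))
  if (length(miss)) stop("unknown TE grouping field(s): ", paste(miss, collapse = ", "))
  hits <- .overlap_pairs(W, TE)
  base <- TE[, unique(.SD), .SDcols = group_field]
  n_el <- TE[, .(n_elements = .N), by = group_field]
  if (!nrow(hits)) {
    out <- n_el
    for (tr in tracks) {
      out[, (paste0("mean_", tr)) := NA_real_]
      out[, (paste0("n_", tr)) := 0L]
    }
    return(out[])
  }
  tab <- cbind(TE[hits$yid, group_field, with = FALSE],
               data.table(eid = hits$yid, wid = hits$xid),
               W[hits$xid, tracks, with = FALSE])
  agg_one <- function(d) {
    res <- list()
    for (tr in tracks) {
      v <- d[[tr]]
      if (element_first) {
        per_el <- d[!is.na(get(tr)), .(m = mean(get(tr))), by = eid]
        res[[paste0("mean_", tr)]] <- if (nrow(per_el)) mean(per_el$m) else NA_real_
      } else {
        res[[paste0("mean_", tr)]] <- if (any(!is.na(v))) mean(v, na.rm = TRUE) else NA_real_
      }
      res[[paste0("n_", tr)]] <- sum(!is.na(v))
    }
    res
  }
  ## dedupe windows within a group (a window overlapping 2 elements of the
  ## same group counts once in window-weighted mode)
  tab_w <- unique(tab, by = c(group_field, "wid"))
  use <- if (element_first) tab else tab_w
  out <- use[, agg_one(.SD), by = group_field,
             .SDcols = c(tracks, "eid", "wid")]
  out <- n_el[out, on = group_field]
  out[]
}

#' Sub-family flank-band summary
#'
#' For each element the upstream band `[start - far, start - near)` and
#' downstream band `[end + near, end + far)` are formed; a window qualifies
#' by overlapping a band by at least 1 bp. Per-group track means are
#' reported separately for the upstream and downstream bands and pooled.
#'
#' @inheritParams subfamily_summary
#' @param near,far distances (bp) bounding the band (defaults 900 and 1000,
#'   i.e. the region 900-1000 bp away from the element).
#' @param exclude_te_overlap drop qualifying windows that themselves overlap
#'   any TE (default FALSE); useful to keep flank signal clean of
#'   neighbouring elements when assessing spreading.
#' @return data.table: group columns, `side` (upstream/downstream/pooled),
#'   per track `mean_<track>` and `n_<track>`.
#' @export
flank_summary <- function(windows, tes, near = 900L, far = 1000L,
                          group_field = "te_subfamily",
                          tracks = .DEFAULT_TRACKS,
                          exclude_te_overlap = FALSE) {
  if (!(near < far)) stop("need near < far")
  W <- as.data.table(windows)
  TE <- as.data.table(tes)
  .check_tracks(W, tracks)
  miss <- setdiff(group_field, names(TE))
  if (length(miss)) stop("unknown TE grouping field(s): ", paste(miss, collapse = ", "))
  bands <- rbind(
    TE[, c(.(chrom = chrom, start = start - far, end = start - near,
             side = "upstream"), .SD), .SDcols = group_field],
    TE[, c(.(chrom = chrom, start = end + near, end = end + far,
             side = "downstream"), .SD), .SDcols = group_field]
  )
  bands <- bands[end > 0]
  bands[start < 0, start := 0L]
  bands <- bands[end > start]
  hits <- .overlap_pairs(W, bands)
  if (exclude_te_overlap && nrow(hits)) {
    in_te <- .overlaps_any(W, TE)
    hits <- hits[!in_te[hits$xid]]
  }
  tab <- cbind(bands[hits$yid, c(group_field, "side"), with = FALSE],
               data.table(wid = hits$xid), W[hits$xid, tracks, with = FALSE])
  tab <- unique(tab, by = c(group_field, "side", "wid"))
  pooled <- copy(tab)[, side := "pooled"]
  pooled <- unique(pooled, by = c(group_field, "side", "wid"))
  both <- rbind(tab, pooled)
  agg <- function(d) {
    res <- list()
    for (tr in tracks) {
      v <- d[[tr]]
      res[[paste0("mean_", tr)]] <- if (any(!is.na(v))) mean(v, na.rm = TRUE) else NA_real_
      res[[paste0("n_", tr)]] <- sum(!is.na(v))
    }
    res
  }
  out <- both[, agg(.SD), by = c(group_field, "side"), .SDcols = tracks]
  setorderv(out, c(group_field, "side"))
  out[]
}

#' Distance from each TE to its nearest gene
#'
#' Distance is 0 when the intervals overlap, otherwise the bp gap between
#' the closest ends. Also reports the arithmetic mean distance per
#' sub-family.
#'
#' @param tes TE rows of a feature table.
#' @param genes gene rows.
#' @return list: `per_te` (data.table `feature_id`, `te_subfamily`,
#'   `distance`; NA when the TE's chromosome has no gene) and `per_subfamily`
#'   (`te_subfamily`, `mean_distance`, `n`).
#' @export
nearest_gene_distance <- function(tes, genes) {
  TE <- as.data.table(tes)
  G <- as.data.table(genes)
  if (!nrow(TE) || !nrow(G)) stop("need non-empty TE and gene sets")
  d <- rep(NA_real_, nrow(TE))
  for (cn in unique(TE$chrom)) {
    ti <- which(TE$chrom == cn)
    gi <- which(G$chrom == cn)
    if (!length(gi)) next
    best <- rep(Inf, length(ti))
    for (j in gi) {
      dj <- pmax(G$start[j] - TE$end[ti], TE$start[ti] - G$end[j], 0)
      best <- pmin(best, dj)
    }
    d[ti] <- best
  }
  per_te <- data.table(feature_id = TE$feature_id,
                       te_subfamily = TE$te_subfamily, distance = d)
  per_sub <- per_te[!is.na(distance),
                    .(mean_distance = mean(distance), n = .N),
                    by = te_subfamily]
  list(per_te = per_te[], per_subfamily = per_sub[])
}

#' Catalog transposons inserted within introns
#'
#' A TE qualifies when its length is strictly greater than `min_len` and its
#' interval is fully contained within a single intron of a gene. TEs longer
#' than `min_len` that overlap a gene without being contained in one intron
#' (e.g. spanning an exon boundary) are excluded and counted separately.
#'
#' @param tes TE rows of a feature table.
#' @param features full feature table (genes + exons) for intron derivation.
#' @param min_len length threshold in bp (default 1000, strict `>`).
#' @return list: `catalog` (data.table `host_gene_id, intron_start,
#'   intron_end, te_id, te_length, te_class, te_subfamily, chrom`),
#'   `flagged_genes` (character vector of host gene ids), and
#'   `n_boundary_tes` (long TEs overlapping genes but not intron-contained).
#' @export
genic_te_catalog <- function(tes, features, min_len = 1000L) {
  TE <- as.data.table(tes)
  introns <- derive_introns(features)
  genes <- as.data.table(features)[kind == "gene"]
  long <- TE[(end - start) > min_len]
  if (!nrow(long) || !nrow(introns)) {
    n_bound <- if (nrow(long)) sum(.overlaps_any(long, genes)) else 0L
    return(list(catalog = data.table(host_gene_id = character(),
                                     intron_start = integer(),
                                     intron_end = integer(),
                                     te_id = character(), te_length = integer(),
                                     te_class = character(),
                                     te_subfamily = character(),
                                     chrom = character()),
                flagged_genes = character(), n_boundary_tes = n_bound))
  }
  hits <- .overlap_pairs(long, introns)
  contained <- hits[
    long$start[hits$xid] >= introns$start[hits$yid] &
    long$end[hits$xid] <= introns$end[hits$yid] &
    long$chrom[hits$xid] == introns$chrom[hits$yid]]
  catalog <- data.table(
    host_gene_id = introns$gene_id[contained$yid],
    intron_start = introns$start[contained$yid],
    intron_end = introns$end[contained$yid],
    te_id = long$feature_id[contained$xid],
    te_length = long$end[contained$xid] - long$start[contained$xid],
    te_class = long$te_class[contained$xid],
    te_subfamily = long$te_subfamily[contained$xid],
    chrom = long$chrom[contained$xid]
  )
  setorder(catalog, host_gene_id, intron_start, te_id)
  in_gene <- .overlaps_any(long, genes)
  n_boundary <- sum(in_gene & !seq_len(nrow(long)) %in% contained$xid)
  list(catalog = catalog[],
       flagged_genes = sort(unique(catalog$host_gene_id)),
       n_boundary_tes = as.integer(n_boundary))
}

#' Chromatin of genic TEs vs all TEs vs exons
#'
#' Mean of each track over windows overlapping (a) any TE, (b) the genic TEs
#' of a catalog, (c) exons.
#'
#' @param windows window table.
#' @param catalog catalog from [genic_te_catalog()] (the list or its
#'   `catalog` element).
#' @param tes all TE rows.
#' @param features full feature table (for exons).
#' @param tracks track columns.
#' @return data.table `region_class` (all_TEs / genic_TEs / exons), `track`,
#'   `mean`, `n`.
#' @export
genic_te_chromatin <- function(windows, catalog, tes, features,
                               tracks = .DEFAULT_TRACKS) {
  W <- as.data.table(windows)
  .check_tracks(W, tracks)
  if (is.list(catalog) && "catalog" %in% names(catalog)) catalog <- catalog$catalog
  TE <- as.data.table(tes)
  exons <- as.data.table(features)[kind == "exon"]
  genic <- TE[TE$feature_id %in% catalog$te_id]
  regions <- list(all_TEs = TE, genic_TEs = genic, exons = exons)
  out <- rbindlist(lapply(names(regions), function(rc) {
    rg <- regions[[rc]]
    idx <- if (nrow(rg)) which(.overlaps_any(W, rg)) else integer()
    rbindlist(lapply(tracks, function(tr) {
      v <- W[[tr]][idx]
      data.table(region_class = rc, track = tr,
                 mean = if (any(!is.na(v))) mean(v, na.rm = TRUE) else NA_real_,
                 n = sum(!is.na(v)))
    }))
  }))
  out[]
}

#' TE class composition of genic TEs vs the whole genome
#'
#' Proportion of TIR, LINE and LTR elements among the genic-TE catalog
#' compared to all TEs, with the genic/genome-wide enrichment ratio per
#' class.
#'
#' @param catalog catalog from [genic_te_catalog()].
#' @param tes all TE rows.
#' @return data.table `te_class`, `genic_n`, `genic_prop`, `genome_n`,
#'   `genome_prop`, `ratio`. Proportion columns each sum to 1.
#' @export
class_enrichment_in_genes <- function(catalog, tes) {
  if (is.list(catalog) && "catalog" %in% names(catalog)) catalog <- catalog$catalog
  TE <- as.data.table(tes)
  classes <- c("TIR", "LINE", "LTR")
  gn <- vapply(classes, function(cl) sum(catalog$te_class == cl, na.rm = TRUE), integer(1))
  an <- vapply(classes, function(cl) sum(TE$te_class == cl, na.rm = TRUE), integer(1))
  out <- data.table(
    te_class = classes, genic_n = gn,
    genic_prop = if (sum(gn)) gn / sum(gn) else rep(NA_real_, 3),
    genome_n = an,
    genome_prop = if (sum(an)) an / sum(an) else rep(NA_real_, 3)
  )
  out[, ratio := genic_prop / genome_prop]
  out[]
}
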