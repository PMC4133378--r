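## Element-anchored metaprofiles. Two geometries:
##   relative: nearest-element assignment, element interior rescaled to a
##     1..1000 axis, fixed-width bp flanks, 60 bins (20 per segment);
##   absolute: TSS/TTS-anchored bp distances, 100 equal bins per 5 kb plot,
##     genic side capped at the gene's actual extent.

.DEFAULT_TRACKS <- c("level_CG", "level_CHG", "level_CHH", "chip_count")

.check_tracks <- function(windows, tracks) {
  miss <- setdiff(tracks, names(windows))
  if (length(miss)) stop("window table lacks track column(s): ",
                         paste(miss, collapse = ", "))
  tracks
}

## Nearest element per window midpoint, ties broken by genome order
## (leftmost element, then input order). Returns data.table with one row per
## window: element row index (eid), signed bp distance d (0 if midpoint
## inside the element). Distance is measured from the window midpoint to the
## closest base of the element.
.nearest_element <- function(windows, elements) {
  W <- as.data.table(windows)
  E <- as.data.table(elements)
  res_eid <- rep(NA_integer_, nrow(W))
  res_d <- rep(NA_real_, nrow(W))
  for (cn in unique(W$chrom)) {
    wi <- which(W$chrom == cn)
    ei <- which(E$chrom == cn)
    if (!length(ei)) next
    ord <- ei[order(E$start[ei], E$end[ei])]
    m <- (W$start[wi] + W$end[wi]) / 2
    best_d <- rep(Inf, length(wi))
    best_e <- rep(NA_integer_, length(wi))
    for (j in ord) {  # genome order => strict < keeps leftmost on ties
      dj <- pmax(E$start[j] - m, m - (E$end[j] - 1L), 0)
      upd <- dj < best_d
      best_d[upd] <- dj[upd]
      best_e[upd] <- j
    }
    res_eid[wi] <- best_e
    res_d[wi] <- best_d
  }
  data.table(eid = res_eid, absd = res_d)
}

.profile_means <- function(pairs, tracks, n_bins, mode, bin_center) {
  ## pairs: data.table(bin_index, <track columns>)
  out <- rbindlist(lapply(tracks, function(tr) {
    v <- pairs[[tr]]
    dt <- data.table(bin_index = pairs$bin_index, value = v)[
      !is.na(value), .(mean = mean(value), n = .N), by = bin_index]
    full <- data.table(bin_index = seq_len(n_bins))
    dt <- dt[full, on = "bin_index"]
    dt[is.na(n), n := 0L]
    dt[, track := tr]
    dt
  }))
  out[, mode := mode]
  out[, bin_center := bin_center[bin_index]]
  setcolorder(out, c("mode", "bin_index", "bin_center", "track", "mean", "n"))
  setorder(out, track, bin_index)
  out[]
}

#' Relative-distance profile over elements
#'
#' Each window is assigned to its closest element (ties to the leftmost in
#' genome order). Windows whose midpoint lies inside the element get a
#' normalized position on a 1..1000 scale
#' (`1 + floor(999 * (mid - start) / (length - 1))`, midpoint clipped into
#' the element for edge-straddling windows); windows within `flank` bp
#' upstream get negative bp distances, downstream positive. The concatenated
#' axis (-flank..0, scaled 1..1000, 0..+flank) is cut into `3 *
#' bins_per_segment` equal bins and per-bin track means are computed over all
#' retained windows.
#'
#' @param windows window table carrying the requested tracks.
#' @param elements interval table (e.g. TE rows of [read_features()]).
#' @param flank flank width in bp (default 1000).
#' @param tracks track column names (default methylation levels + chip).
#' @param bins_per_segment bins per segment (default 20, i.e. 60 total).
#' @return data.table `mode, bin_index, bin_center, track, mean, n`; bins
#'   1..20 upstream, 21..40 element interior (centers on the 1..1000 scale),
#'   41..60 downstream. Attribute `n_pairs` = retained windows.
#' @export
relative_profile <- function(windows, elements, flank = 1000L,
                             tracks = .DEFAULT_TRACKS,
                             bins_per_segment = 20L) {
  if (flank <= 0) stop("flank must be positive")
  if (!nrow(elements)) stop("no elements supplied")
  .check_tracks(windows, tracks)
  W <- as.data.table(windows)
  E <- as.data.table(elements)
  B <- as.integer(bins_per_segment)
  near <- .nearest_element(W, E)
  keep <- which(!is.na(near$eid) & near$absd <= flank)
  if (!length(keep)) {
    warning("no window within range of any element; empty profile")
    empty <- .profile_means(
      data.table(bin_index = integer())[, (tracks) := numeric(0)],
      tracks, 3L * B, "relative", rep(NA_real_, 3L * B))
    setattr(empty, "n_pairs", 0L)
    return(empty)
  }
  m <- (W$start[keep] + W$end[keep]) / 2
  es <- E$start[near$eid[keep]]
  ee <- E$end[near$eid[keep]]
  len <- ee - es
  inside <- m >= es & m < ee
  bin <- integer(length(keep))
  ## interior: clip midpoint, rescale to 1..1000, 50-unit bins
  mi <- pmin(pmax(m, es), ee - 1L)
  scaled <- ifelse(len > 1L, 1 + floor(999 * (mi - es) / (len - 1L)), 1)
  bin[inside] <- B + 1L + floor((scaled[inside] - 1) / (1000 / B))
  ## flanks: signed distance from the element boundary (upstream negative,
  ## measured from the first element base; downstream non-negative, from the
  ## first base past the element) so the two flanks bin symmetrically
  up <- !inside & m < es
  dn <- !inside & m >= ee
  d_up <- m[up] - es[up]                    # in [-flank, 0)
  d_dn <- m[dn] - ee[dn]                    # in [0, flank)
  bin[up] <- pmax(1L, pmin(B, 1L + floor((d_up + flank) / (flank / B))))
  bin[dn] <- pmax(2L * B + 1L, pmin(3L * B, 2L * B + 1L + floor(d_dn / (flank / B))))
  pairs <- cbind(data.table(bin_index = bin), W[keep, tracks, with = FALSE])
  centers <- c(-flank + (seq_len(B) - 0.5) * flank / B,
               (seq_len(B) - 0.5) * (1000 / B),
               (seq_len(B) - 0.5) * flank / B)
  out <- .profile_means(pairs, tracks, 3L * B, "relative", centers)
  seg <- rep(c("upstream", "element", "downstream"), each = B)
  out[, segment := seg[bin_index]]
  setattr(out, "n_pairs", length(keep))
  out[]
}

## shared geometry for the absolute plots
.absolute_pairs <- function(windows, genes, anchor, upstream, into_gene) {
  W <- as.data.table(windows)
  G <- as.data.table(genes)
  if (!nrow(G)) stop("no genes supplied")
  if (any(!G$strand %in% c("+", "-"))) {
    stop("gene(s) without strand: ",
         paste(head(G$feature_id[!G$strand %in% c("+", "-")], 3), collapse = ", "))
  }
  span <- G$end - G$start
  dir <- ifelse(G$strand == "+", 1L, -1L)
  if (anchor == "tss") {
    apos <- ifelse(G$strand == "+", G$start, G$end - 1L)
    lo_ax <- rep(-upstream, nrow(G))   # axis: [-upstream, +into_gene], gene right
    hi_ax <- pmin(into_gene, span)
  } else {
    apos <- ifelse(G$strand == "+", G$end - 1L, G$start)
    lo_ax <- pmax(-into_gene, -span)   # axis: [-into_gene, +upstream], gene left
    hi_ax <- rep(upstream, nrow(G))
  }
  GA <- data.table(gidx = seq_len(nrow(G)), chrom = G$chrom, apos = apos,
                   dir = dir, lo = as.numeric(lo_ax), hi = as.numeric(hi_ax))
  W[, mid := (start + end) / 2]
  ## genomic interval of midpoints contributing to each gene
  GA[, `:=`(glo = fifelse(dir == 1L, apos + lo, apos - hi),
            ghi = fifelse(dir == 1L, apos + hi, apos - lo))]
  pairs <- W[GA, on = .(chrom, mid >= glo, mid <= ghi), allow.cartesian = TRUE,
             nomatch = NULL,
             .(gidx = i.gidx, wrow = x.win_id, dx = (x.mid - i.apos) * i.dir)]
  ## wrow is win_id which equals row index for a full tiling; map defensively
  pairs[, wrow := match(wrow, W$win_id)]
  pairs
}

.absolute_one <- function(windows, genes, anchor, upstream, into_gene,
                          tracks, n_bins = 100L, drop_pairs = NULL) {
  W <- as.data.table(windows)
  pairs <- .absolute_pairs(W, genes, anchor, upstream, into_gene)
  if (!is.null(drop_pairs)) pairs <- drop_pairs(pairs)
  span_ax <- upstream + into_gene
  bw <- span_ax / n_bins
  if (anchor == "tss") {
    bin <- 1L + floor((pairs$dx + upstream) / bw)
  } else {
    bin <- 1L + floor((pairs$dx + into_gene) / bw)
  }
  pairs[, bin_index := pmax(1L, pmin(n_bins, as.integer(bin)))]
  tab <- cbind(pairs[, .(bin_index)], W[pairs$wrow, tracks, with = FALSE])
  centers <- if (anchor == "tss") {
    -upstream + (seq_len(n_bins) - 0.5) * bw
  } else {
    -into_gene + (seq_len(n_bins) - 0.5) * bw
  }
  mode <- if (anchor == "tss") "absolute_5prime" else "absolute_3prime"
  out <- .profile_means(tab, tracks, n_bins, mode, centers)
  setattr(out, "n_pairs", nrow(pairs))
  out
}

#' Absolute-distance gene profiles (5' and 3' plots)
#'
#' The 5' plot spans `upstream` bp before the TSS plus `into_gene` bp of
#' genic sequence from the TSS; the 3' plot spans `into_gene` bp of genic
#' sequence before the TTS plus `upstream` bp after it. The distance for a
#' window is the bp offset of its midpoint from the anchor, sign-flipped for
#' minus-strand genes so both axes run 5' to 3'. Windows beyond a short
#' gene's actual extent are dropped, so bin counts fall off with distance
#' into the gene body. Each axis is cut into 100 equal bins and per-bin
#' means are pooled over all gene-window pairs.
#'
#' @param windows window table.
#' @param genes gene rows of a feature table (strand required).
#' @param upstream bp upstream of TSS / downstream of TTS (default 2000).
#' @param into_gene bp of gene body from the anchor (default 3000).
#' @param tracks track columns (default methylation levels + chip).
#' @param n_bins bins per plot (default 100).
#' @return list with elements `five_prime` and `three_prime`, each a profile
#'   data.table (`mode, bin_index, bin_center, track, mean, n`).
#' @export
absolute_gene_profile <- function(windows, genes, upstream = 2000L,
                                  into_gene = 3000L,
                                  tracks = .DEFAULT_TRACKS, n_bins = 100L) {
  .check_tracks(windows, tracks)
  list(
    five_prime = .absolute_one(windows, genes, "tss", upstream, into_gene,
                               tracks, n_bins),
    three_prime = .absolute_one(windows, genes, "tts", upstream, into_gene,
                                tracks, n_bins)
  )
}

#' Gene profiles with masked or restricted genic windows
#'
#' Identical geometry to [absolute_gene_profile()], but windows overlapping
#' any `mask_features` interval (typically genic transposons) are excluded
#' from genic bins; flank bins are unaffected. Alternatively (or in
#' addition) the genic side can be restricted to windows overlapping exons
#' only or introns only.
#'
#' @inheritParams absolute_gene_profile
#' @param mask_features intervals to mask out of the genic region (may be
#'   empty/NULL for no masking).
#' @param restrict "none", "exon" or "intron": keep only genic windows
#'   overlapping that feature kind. Requires `features` when not "none".
#' @param features full feature table (for exon lookup when `restrict !=
#'   "none"`).
#' @return list with `five_prime` and `three_prime` profiles.
#' @export
masked_profile <- function(windows, genes, mask_features = NULL,
                           upstream = 2000L, into_gene = 3000L,
                           tracks = .DEFAULT_TRACKS, n_bins = 100L,
                           restrict = c("none", "exon", "intron"),
                           features = NULL) {
  restrict <- match.arg(restrict)
  .check_tracks(windows, tracks)
  W <- as.data.table(windows)
  masked <- if (!is.null(mask_features) && nrow(as.data.table(mask_features))) {
    .overlaps_any(W, as.data.table(mask_features))
  } else rep(FALSE, nrow(W))
  keepable <- rep(TRUE, nrow(W))
  if (restrict != "none") {
    if (is.null(features)) stop("restrict != 'none' requires the feature table")
    features <- as.data.table(features)
    region <- if (restrict == "exon") {
      features[kind == "exon"]
    } else {
      derive_introns(features)
    }
    keepable <- .overlaps_any(W, region)
  }
  drop_fun_5p <- function(pairs) pairs[!(dx >= 0 & (masked[wrow] | !keepable[wrow]))]
  drop_fun_3p <- function(pairs) pairs[!(dx <= 0 & (masked[wrow] | !keepable[wrow]))]
  list(
    five_prime = .absolute_one(W, genes, "tss", upstream, into_gene, tracks,
                               n_bins, drop_pairs = drop_fun_5p),
    three_prime = .absolute_one(W, genes, "tts", upstream, into_gene, tracks,
                                n_bins, drop_pairs = drop_fun_3p)
  )
}

#' Gene profiles split by a metadata field
#'
#' Computes [absolute_gene_profile()] independently for each level of a gene
#' metadata column (e.g. `gene_set`, `synteny`, `subgenome`).
#'
#' @inheritParams absolute_gene_profile
#' @param group_by name of a column of `genes`.
#' @return named list of profile pairs, one per group label.
#' @export
grouped_profiles <- function(windows, genes, group_by,
                             upstream = 2000L, into_gene = 3000L,
                             tracks = .DEFAULT_TRACKS, n_bins = 100L) {
  genes <- as.data.table(genes)
  if (!group_by %in% names(genes)) {
    stop("unknown gene metadata field: ", group_by)
  }
  labs <- unique(genes[[group_by]])
  labs <- labs[!is.na(labs)]
  out <- lapply(labs, function(lb) {
    absolute_gene_profile(windows, genes[genes[[group_by]] == lb],
                          upstream, into_gene, tracks, n_bins)
  })
  names(out) <- as.character(labs)
  out
}
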