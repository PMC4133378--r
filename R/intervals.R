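## Internal interval utilities. Every interval in the package is a row of a
## data.table with columns chrom (character), start, end (integer, 0-based
## half-open) and optionally strand ("+", "-" or ".").

.assert_intervals <- function(x, what = "interval") {
  stopifnot(is.data.frame(x))
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop(what, " table lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(x)) {
    if (any(is.na(x$start)) || any(is.na(x$end))) {
      stop(what, " table has NA coordinates")
    }
    if (any(x$start < 0)) stop(what, " start < 0 (coordinates are 0-based)")
    bad <- which(x$end <= x$start)
    if (length(bad)) {
      stop(what, " with end <= start at row ", bad[1L],
           " (", x$chrom[bad[1L]], ":", x$start[bad[1L]], "-", x$end[bad[1L]], ")")
    }
  }
  invisible(x)
}

## 0-based half-open data.table -> GRanges (1-based closed)
.as_granges <- function(x) {
  strand <- if ("strand" %in% names(x)) {
    s <- as.character(x$strand)
    s[!s %in% c("+", "-")] <- "*"
    s
  } else "*"
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = strand
  )
}

## Overlap pairs between two 0-based half-open interval tables.
## Returns data.table(xid, yid) of row indices with >= 1 bp overlap.
.overlap_pairs <- function(x, y) {
  if (!nrow(x) || !nrow(y)) {
    return(data.table(xid = integer(), yid = integer()))
  }
  hits <- GenomicRanges::findOverlaps(.as_granges(x), .as_granges(y),
                                      ignore.strand = TRUE)
  data.table(xid = S4Vectors::queryHits(hits), yid = S4Vectors::subjectHits(hits))
}

## Row indices of x overlapping any interval in y.
.overlaps_any <- function(x, y) {
  if (!nrow(x) || !nrow(y)) return(rep(FALSE, nrow(x)))
  IRanges::overlapsAny(.as_granges(x), .as_granges(y), ignore.strand = TRUE)
}

#' Derive intron intervals from genes and exons
#'
#' Introns are the complement of a gene's exons within the gene span. For
#' every gene the summed intron and exon widths equal the gene width.
#'
#' @param features feature table as returned by [read_features()] (must
#'   contain `kind == "gene"` and `kind == "exon"` rows; exons carry
#'   `parent_id`).
#' @return data.table with columns `chrom`, `start`, `end`, `strand`,
#'   `gene_id` — one row per intron, 0-based half-open.
#' @export
derive_introns <- function(features) {
  features <- as.data.table(features)
  genes <- features[kind == "gene"]
  exons <- features[kind == "exon"]
  if (!nrow(genes)) {
    return(data.table(chrom = character(), start = integer(), end = integer(),
                      strand = character(), gene_id = character()))
  }
  orphan <- setdiff(exons$parent_id, genes$feature_id)
  if (length(orphan)) {
    stop("exon(s) reference unknown parent gene: ", paste(head(orphan, 3), collapse = ", "))
  }
  ex <- exons[order(parent_id, start)]
  gb <- genes[, .(parent_id = feature_id, gchrom = chrom, gstart = start,
                  gend = end, gstrand = strand)]
  ex <- gb[ex, on = "parent_id"]
  out <- ex[, {
    s <- c(gstart[1L], end)  # candidate intron starts
    e <- c(start, gend[1L])  # candidate intron ends
    keep <- e > s
    list(chrom = rep(gchrom[1L], sum(keep)), start = s[keep], end = e[keep],
         strand = rep(gstrand[1L], sum(keep)))
  }, by = .(gene_id = parent_id)]
  setcolorder(out, c("chrom", "start", "end", "strand", "gene_id"))
  out[]
}
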