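## Readers and writers for the plain-text interchange formats. All readers
## convert to 0-based half-open coordinates on ingest; writers convert back.

.CONTEXTS <- c("CG", "CHG", "CHH")

#' Read a per-cytosine methylation report
#'
#' Parses the 7-column cytosine report dialect emitted by common bisulfite
#' methylation extractors: chrom, 1-based position, strand, methylated read
#' count, unmethylated read count, context (CG/CHG/CHH) and trinucleotide.
#' Positions are shifted to 0-based on ingest. Records with total coverage
#' below `min_coverage` are retained but flagged `low_coverage`.
#'
#' @param path path to a TSV (optionally gzipped), no header.
#' @param min_coverage minimum total read count for a record to count as
#'   covered; lower records are kept with `low_coverage = TRUE`.
#' @return data.table with columns `chrom`, `pos` (0-based), `strand`,
#'   `context`, `n_meth`, `n_total`, `low_coverage`.
#' @export
read_cytosine_report <- function(path, min_coverage = 1L) {
  dt <- fread(path, header = FALSE, sep = "\t", colClasses = list(character = c(1, 3, 6, 7)))
  if (ncol(dt) < 7L) {
    stop("cytosine report must have 7 columns; got ", ncol(dt), " in ", path)
  }
  setnames(dt, 1:7, c("chrom", "pos1", "strand", "n_meth", "n_unmeth",
                      "context", "tri"))
  for (col in c("pos1", "n_meth", "n_unmeth")) {
    v <- dt[[col]]
    if (!is.numeric(v)) {
      vv <- suppressWarnings(as.numeric(v))
      if (anyNA(vv)) {
        stop("unparseable ", col, " at line ", which(is.na(vv))[1L], " of ", path)
      }
      set(dt, j = col, value = vv)
    } else if (anyNA(v)) {
      stop("unparseable ", col, " at line ", which(is.na(v))[1L], " of ", path)
    }
  }
  bad_ctx <- which(!dt$context %in% .CONTEXTS)
  if (length(bad_ctx)) {
    stop("unknown methylation context '", dt$context[bad_ctx[1L]],
         "' at line ", bad_ctx[1L], " of ", path)
  }
  bad_strand <- which(!dt$strand %in% c("+", "-"))
  if (length(bad_strand)) {
    stop("invalid strand at line ", bad_strand[1L], " of ", path)
  }
  if (any(dt$n_meth < 0) || any(dt$n_unmeth < 0)) {
    stop("negative read count in ", path)
  }
  out <- dt[, .(chrom, pos = as.integer(pos1 - 1L), strand, context,
                n_meth = as.integer(n_meth),
                n_total = as.integer(n_meth + n_unmeth))]
  if (any(out$pos < 0)) {
    stop("position < 1 at line ", which(out$pos < 0)[1L], " of ", path)
  }
  out[, low_coverage := n_total < min_coverage]
  out[]
}

#' Write a cytosine report
#'
#' Inverse of [read_cytosine_report()]; positions converted back to 1-based.
#' A placeholder trinucleotide consistent with the context is emitted.
#'
#' @param cytosines table as returned by [read_cytosine_report()].
#' @param path output path (".gz" suffix enables compression).
#' @export
write_cytosine_report <- function(cytosines, path) {
  tri <- c(CG = "CGA", CHG = "CAG", CHH = "CTA")[cytosines$context]
  out <- data.table(cytosines$chrom, cytosines$pos + 1L, cytosines$strand,
                    cytosines$n_meth, cytosines$n_total - cytosines$n_meth,
                    cytosines$context, tri)
  fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

## Map sub-family code -> coarse TE class, used when the BED lacks a class
## column. Codes follow the three-letter wicker-style convention.
.te_class_from_code <- function(code) {
  first2 <- substr(code, 1, 2)
  out <- rep(NA_character_, length(code))
  out[first2 == "RL"] <- "LTR"
  out[first2 == "DT"] <- "TIR"
  out[first2 == "RI" | toupper(substr(code, 1, 4)) == "LINE"] <- "LINE"
  out
}

#' Read gene/exon and transposable-element annotation
#'
#' Genes and exons come from a GFF3 file (exons linked to genes via
#' `Parent`); TEs from a BED6+2 file whose extra columns carry the TE class
#' (TIR/LTR/LINE) and an optional spreading label. All intervals are
#' normalized to 0-based half-open.
#'
#' @param gff3_path GFF3 with `gene` and `exon` features. Optional gene
#'   attributes `gene_set`, `synteny` and `subgenome` are carried through.
#' @param te_bed_path BED file: chrom, start, end, name, score, strand,
#'   te_class, spreading. `te_class` may be omitted, in which case it is
#'   inferred from the leading letters of the sub-family code in `name`.
#' @return data.table of features with columns `chrom,start,end,strand,kind,
#'   feature_id,parent_id,te_class,te_subfamily,spreading,gene_set,synteny,
#'   subgenome`.
#' @export
read_features <- function(gff3_path, te_bed_path = NULL) {
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  md <- as.data.frame(S4Vectors::mcols(gr))
  grab <- function(col) {
    if (col %in% names(md)) {
      v <- md[[col]]
      if (methods::is(v, "List") || is.list(v)) {
        v <- vapply(v, function(e) if (length(e)) as.character(e[1]) else NA_character_,
                    character(1))
      }
      as.character(v)
    } else rep(NA_character_, length(gr))
  }
  dt <- data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    kind = as.character(md$type),
    feature_id = grab("ID"),
    parent_id = grab("Parent"),
    gene_set = grab("gene_set"),
    synteny = grab("synteny"),
    subgenome = grab("subgenome")
  )
  dt <- dt[kind %in% c("gene", "exon")]
  dt[, `:=`(te_class = NA_character_, te_subfamily = NA_character_,
            spreading = NA_character_)]
  genes <- dt[kind == "gene"]
  if (anyDuplicated(genes$feature_id)) {
    stop("duplicate gene id(s): ",
         paste(head(unique(genes$feature_id[duplicated(genes$feature_id)]), 3),
               collapse = ", "))
  }
  exons <- dt[kind == "exon"]
  if (nrow(exons)) {
    if (any(is.na(exons$parent_id))) stop("exon without Parent attribute in ", gff3_path)
    orphan <- setdiff(exons$parent_id, genes$feature_id)
    if (length(orphan)) {
      stop("exon references unknown parent gene: ", paste(head(orphan, 3), collapse = ", "))
    }
  }
  out <- dt
  if (!is.null(te_bed_path)) {
    te <- fread(te_bed_path, header = FALSE, sep = "\t", fill = TRUE)
    if (ncol(te) < 4L) stop("TE BED needs at least 4 columns (chrom,start,end,name)")
    nm <- c("chrom", "start", "end", "feature_id", "score", "strand",
            "te_class", "spreading")[seq_len(min(ncol(te), 8L))]
    setnames(te, seq_along(nm), nm)
    if (!"strand" %in% names(te)) te[, strand := "."]
    if (!"te_class" %in% names(te) || all(is.na(te$te_class)) || all(te$te_class == "")) {
      te[, te_class := .te_class_from_code(feature_id)]
    }
    if (!"spreading" %in% names(te)) te[, spreading := "unknown"]
    te[is.na(spreading) | spreading == "", spreading := "unknown"]
    ## sub-family code = leading letters of the element name (e.g. RLG00001 -> RLG;
    ## names like DTM-nc001 keep the -nc suffix as part of the code)
    te[, te_subfamily := sub("^([A-Za-z]+(-nc)?).*$", "\\1", feature_id)]
    if (anyDuplicated(te$feature_id)) {
      stop("duplicate TE id(s): ",
           paste(head(unique(te$feature_id[duplicated(te$feature_id)]), 3), collapse = ", "))
    }
    te_dt <- te[, .(chrom = as.character(chrom), start = as.integer(start),
                    end = as.integer(end), strand = as.character(strand),
                    kind = "TE", feature_id = as.character(feature_id),
                    parent_id = NA_character_, gene_set = NA_character_,
                    synteny = NA_character_, subgenome = NA_character_,
                    te_class = as.character(te_class),
                    te_subfamily = te_subfamily,
                    spreading = as.character(spreading))]
    out <- rbind(out, te_dt, use.names = TRUE)
  }
  setcolorder(out, c("chrom", "start", "end", "strand", "kind", "feature_id",
                     "parent_id", "te_class", "te_subfamily", "spreading",
                     "gene_set", "synteny", "subgenome"))
  .assert_intervals(out, "feature")
  out[]
}

#' Read aligned ChIP reads from a BED file
#'
#' BED3+ intervals, returned 0-based half-open and sorted by (chrom, start).
#' Duplicate-read removal is assumed to have been done upstream; a warning is
#' issued when more than 10% of reads are exact-interval duplicates.
#'
#' @param path BED3+ file (optionally gzipped).
#' @return data.table with columns `chrom`, `start`, `end`.
#' @export
read_chip_bed <- function(path) {
  dt <- fread(path, header = FALSE, sep = "\t")
  if (ncol(dt) < 3L) stop("ChIP BED needs at least 3 columns")
  setnames(dt, 1:3, c("chrom", "start", "end"))
  dt <- dt[, .(chrom = as.character(chrom), start = as.integer(start),
               end = as.integer(end))]
  bad <- which(dt$start >= dt$end)
  if (length(bad)) {
    stop("read with start >= end at line ", bad[1L], " of ", path)
  }
  setorder(dt, chrom, start, end)
  if (nrow(dt)) {
    dup_frac <- mean(duplicated(dt))
    if (dup_frac > 0.10) {
      warning(sprintf("%.1f%% of reads are exact-interval duplicates; was the library deduplicated?",
                      100 * dup_frac))
    }
  }
  dt[]
}

#' Write / read the per-window track table
#'
#' TSV with one row per 100 bp window: coordinates, per-context methylated
#' and total read sums, covered-cytosine counts, weighted levels and the
#' ChIP read sum. Windows with no covered cytosine in a context have a
#' missing (`NA`) level — missing is distinct from 0.
#'
#' @param windows window table from [weighted_methylation()] /
#'   [chip_window_counts()].
#' @param path output TSV path.
#' @return `write_window_table`: the path, invisibly. `read_window_table`:
#'   the table, with the same column types.
#' @export
write_window_table <- function(windows, path) {
  fwrite(as.data.table(windows), path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_window_table
#' @export
read_window_table <- function(path) {
  dt <- fread(path, sep = "\t", na.strings = "NA")
  dt[, chrom := as.character(chrom)]
  dt[]
}

#' Read a per-gene expression table
#'
#' TSV with header: `gene_id`, `length_bp`, then one column of read counts
#' per replicate (any names). Alternatively a precomputed `rpkm` column may
#' be present.
#'
#' @param path TSV path.
#' @return data.table with `gene_id`, `length_bp` and count/rpkm columns.
#' @export
read_expression_table <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE)
  if (!"gene_id" %in% names(dt)) stop("expression table needs a gene_id column")
  has_counts <- length(setdiff(names(dt), c("gene_id", "length_bp", "rpkm"))) > 0
  if (!has_counts && !"rpkm" %in% names(dt)) {
    stop("expression table needs replicate count columns or an rpkm column")
  }
  if (has_counts && !"length_bp" %in% names(dt)) {
    stop("expression table with counts needs a length_bp column")
  }
  dt[, gene_id := as.character(gene_id)]
  dt[]
}
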