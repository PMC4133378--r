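## Independent brute-force oracles and small in-code fixtures. The oracles
## deliberately use naive per-record scans so they share no code path with
## the implementation they check.

library(data.table)

## per-window weighted methylation by scanning every cytosine individually
oracle_weighted_methylation <- function(cyt, windows) {
  res <- list()
  for (wi in seq_len(nrow(windows))) {
    w <- windows[wi]
    for (ctx in c("CG", "CHG", "CHH")) {
      meth <- 0L; total <- 0L
      for (ci in seq_len(nrow(cyt))) {
        if (cyt$chrom[ci] == w$chrom && cyt$context[ci] == ctx &&
            cyt$pos[ci] >= w$start && cyt$pos[ci] < w$end) {
          meth <- meth + cyt$n_meth[ci]
          total <- total + cyt$n_total[ci]
        }
      }
      res[[length(res) + 1L]] <- data.table(
        win_id = w$win_id, context = ctx, meth = meth, total = total,
        level = if (total > 0) meth / total else NA_real_)
    }
  }
  rbindlist(res)
}

## vectorised but structurally independent version for larger instances:
## assignment by explicit interval comparison per window, not by floor division
oracle_weighted_methylation_fast <- function(cyt, windows) {
  res <- list()
  for (ctx in c("CG", "CHG", "CHH")) {
    cc <- cyt[context == ctx]
    meth <- integer(nrow(windows)); total <- integer(nrow(windows))
    for (wi in seq_len(nrow(windows))) {
      sel <- cc$chrom == windows$chrom[wi] & cc$pos >= windows$start[wi] &
        cc$pos < windows$end[wi]
      meth[wi] <- sum(cc$n_meth[sel])
      total[wi] <- sum(cc$n_total[sel])
    }
    res[[ctx]] <- data.table(win_id = windows$win_id, context = ctx,
                             meth = meth, total = total,
                             level = ifelse(total > 0, meth / total, NA_real_))
  }
  rbindlist(res)
}

## quadratic all-pairs read-vs-window overlap counts (every read is tested
## against every window of its chromosome)
oracle_chip_counts <- function(reads, windows) {
  counts <- integer(nrow(windows))
  for (wi in seq_len(nrow(windows))) {
    counts[wi] <- sum(reads$chrom == windows$chrom[wi] &
                        reads$start < windows$end[wi] &
                        reads$end > windows$start[wi])
  }
  counts
}

## nearest-gene gap distance by explicit all-pairs minimum
oracle_nearest_distance <- function(tes, genes) {
  sapply(seq_len(nrow(tes)), function(i) {
    ds <- sapply(seq_len(nrow(genes)), function(j) {
      if (genes$chrom[j] != tes$chrom[i]) return(Inf)
      if (tes$start[i] < genes$end[j] && tes$end[i] > genes$start[j]) return(0)
      max(genes$start[j] - tes$end[i], tes$start[i] - genes$end[j])
    })
    d <- min(ds)
    if (is.infinite(d)) NA_real_ else d
  })
}

## random cytosine table over a tiling
random_cytosines <- function(n, chrom_sizes, seed) {
  withr::with_seed(seed, {
    chroms <- sample(names(chrom_sizes), n, replace = TRUE)
    pos <- sapply(chroms, function(cn) sample.int(chrom_sizes[[cn]], 1L)) - 1L
    total <- rpois(n, 8)
    data.table(chrom = chroms, pos = as.integer(pos),
               strand = sample(c("+", "-"), n, TRUE),
               context = sample(c("CG", "CHG", "CHH"), n, TRUE),
               n_meth = rbinom(n, total, runif(n)), n_total = total,
               low_coverage = total < 1L)
  })
}

## minimal window table with explicit tracks (for profile/classify tests)
make_track_windows <- function(chrom_sizes, window_size = 100L,
                               cg = NA_real_, chg = NA_real_, chh = NA_real_,
                               chip = 0) {
  w <- tile_genome(chrom_sizes, window_size)
  w[, level_CG := rep_len(cg, .N)]
  w[, level_CHG := rep_len(chg, .N)]
  w[, level_CHH := rep_len(chh, .N)]
  w[, chip_count := rep_len(chip, .N)]
  w
}

## single TE feature row in the read_features() layout
mk_te <- function(chrom, start, end, id, subfam, class = "LTR",
                  spreading = "non_spreading") {
  data.table(chrom = chrom, start = as.integer(start), end = as.integer(end),
             strand = "+", kind = "TE", feature_id = id, parent_id = NA_character_,
             te_class = class, te_subfamily = subfam, spreading = spreading,
             gene_set = NA_character_, synteny = NA_character_,
             subgenome = NA_character_)
}

## in-memory toy annotation: gene A's intron holds a 1200 bp TE, gene B's an
## 800 bp TE, gene C none, gene D a TE of exactly 1000 bp (strict threshold)
toy_genic_annotation <- function() {
  feats <- rbindlist(lapply(list(
    list("gA", 1000L, 6000L), list("gB", 10000L, 15000L),
    list("gC", 20000L, 25000L), list("gD", 30000L, 35000L)
  ), function(g) {
    rbind(
      data.table(chrom = "chr1", start = g[[2]], end = g[[3]], strand = "+",
                 kind = "gene", feature_id = g[[1]], parent_id = NA_character_,
                 te_class = NA_character_, te_subfamily = NA_character_,
                 spreading = NA_character_, gene_set = "FGS",
                 synteny = NA_character_, subgenome = NA_character_),
      data.table(chrom = "chr1", start = c(g[[2]], g[[3]] - 500L),
                 end = c(g[[2]] + 500L, g[[3]]), strand = "+", kind = "exon",
                 feature_id = paste0(g[[1]], c("_e1", "_e2")),
                 parent_id = g[[1]], te_class = NA_character_,
                 te_subfamily = NA_character_, spreading = NA_character_,
                 gene_set = NA_character_, synteny = NA_character_,
                 subgenome = NA_character_))
  }))
  tes <- rbind(mk_te("chr1", 2000, 3200, "teA", "RLG"),            # 1200 bp
               mk_te("chr1", 11000, 11800, "teB", "RLC"),          # 800 bp
               mk_te("chr1", 31000, 32000, "teD", "RLX"),          # exactly 1000
               mk_te("chr1", 40000, 42000, "teX", "DTM", "TIR"))   # intergenic
  list(features = rbind(feats, tes), tes = tes)
}

## tiny GFF3 + TE BED fixture written to tempfiles; returns the two paths
write_tiny_annotation <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  gff <- file.path(dir, "genes.gff3")
  bed <- file.path(dir, "tes.bed")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsim\tgene\t1001\t3000\t.\t+\t.\tID=gA;gene_set=FGS;synteny=syntenic;subgenome=sg1",
    "chr1\tsim\texon\t1001\t1400\t.\t+\t.\tID=gA_ex1;Parent=gA",
    "chr1\tsim\texon\t2601\t3000\t.\t+\t.\tID=gA_ex2;Parent=gA",
    "chr1\tsim\tgene\t8001\t9500\t.\t-\t.\tID=gB;gene_set=WGS;synteny=inserted;subgenome=sg2",
    "chr1\tsim\texon\t8001\t8500\t.\t-\t.\tID=gB_ex1;Parent=gB",
    "chr1\tsim\texon\t9001\t9500\t.\t-\t.\tID=gB_ex2;Parent=gB"
  ), gff)
  writeLines(c(
    "chr1\t5000\t7000\tRLG00001\t0\t+\tLTR\tspreading",
    "chr1\t12000\t12800\tDTM00001\t0\t-\tTIR\tnon_spreading"
  ), bed)
  list(gff3 = gff, te_bed = bed)
}
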