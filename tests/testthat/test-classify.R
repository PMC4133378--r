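test_that("heatmap bins follow the 10 x 9 grouping with closed top edges", {
  w <- data.table(level_CHG = c(0.95, 1.00, 0.00, 0.05, 0.42),
                  level_CHH = c(0.005, 0.25, 0.20, 0.049, 0.12),
                  chip_count = c(40, 10, 5, 7, 3))
  h <- chg_chh_heatmap(w)
  expect_equal(nrow(h), 90L)
  cell <- function(cg, ch) h[chg_bin == cg & chh_bin == ch]
  expect_equal(cell(10, 1)$n_windows, 1L)   # (95%, 0.5%)
  expect_equal(cell(10, 1)$mean_chip, 40)
  expect_equal(cell(10, 9)$n_windows, 1L)   # (100%, 25%): closed top edges
  expect_equal(cell(1, 8)$n_windows, 1L)    # CHH exactly 20% -> bin 8
  expect_equal(cell(1, 5)$n_windows, 1L)    # 4.9% -> bin 5
  expect_equal(cell(5, 7)$n_windows, 1L)    # 42%, 12%
  expect_equal(sum(h$n_windows), 5L)
})

test_that("heatmap uses only windows with data on all three marks", {
  w <- data.table(level_CHG = c(0.5, NA, 0.5), level_CHH = c(0.01, 0.01, NA),
                  chip_count = c(10, 10, 10))
  h <- chg_chh_heatmap(w)
  expect_equal(sum(h$n_windows), 1L)
  ## empty input: full grid, all zero
  h0 <- chg_chh_heatmap(w[0])
  expect_equal(nrow(h0), 90L)
  expect_equal(sum(h0$n_windows), 0L)
})

test_that("TSS windows are strand-aware and unique", {
  w <- tile_genome(c(chr1 = 30000), 100)
  genes <- data.table(chrom = "chr1", start = c(12345L, 15000L),
                      end = c(14000L, 20000L), strand = c("+", "-"),
                      feature_id = c("gp", "gm"))
  tw <- tss_window(genes, w)
  expect_equal(tw[gene_id == "gp", .(start, end)], data.table(start = 12300L, end = 12400L))
  ## - strand gene ending at 20000: TSS 19999 -> window [19900, 20000)
  expect_equal(tw[gene_id == "gm", .(start, end)], data.table(start = 19900L, end = 20000L))
  expect_error(tss_window(data.table(chrom = "chr1", start = 1L, end = 10L,
                                     strand = ".", feature_id = "gx"), w),
               "without strand")
  ## every simulated gene maps to exactly one overlapping tile
  man <- simulate_genome(sim_config(seed = 23))
  w2 <- tile_genome(man$chrom_sizes, 100)
  tw2 <- tss_window(man$features[kind == "gene"], w2)
  expect_equal(nrow(tw2), nrow(man$features[kind == "gene"]))
  expect_true(all(tw2$tss >= tw2$start & tw2$tss < tw2$end))
})

test_that("high-TSS gene flags use dataset-derived cutoffs", {
  ## constant CHG: nothing strictly exceeds the quantile of a constant
  w <- make_track_windows(c(chr1 = 30000), chg = 0.5, chip = 5)
  genes <- data.table(chrom = "chr1", start = c(1000L, 9000L),
                      end = c(5000L, 15000L), strand = "+",
                      feature_id = c("g1", "g2"))
  hi <- high_tss_genes(genes, w)
  expect_length(hi$high_chg, 0)
  expect_length(hi$high_k9, 0)
  ## monotone in the quantile
  w2 <- make_track_windows(c(chr1 = 30000), chg = seq(0, 1, length.out = 300),
                           chip = 5)
  hi0 <- high_tss_genes(genes, w2, chg_quantile = 0)
  hi99 <- high_tss_genes(genes, w2, chg_quantile = 0.999)
  expect_true(all(hi99$high_chg %in% hi0$high_chg))
  expect_gte(length(hi0$high_chg), length(hi99$high_chg))
  expect_error(high_tss_genes(genes[0], w), "no genes")
})

test_that("planted single-mark genes stay disjoint, dual-mark genes intersect", {
  cfg <- sim_config(seed = 29)
  man <- simulate_all(cfg)
  w <- tile_genome(man$chrom_sizes, 100)
  w <- weighted_methylation(man$cytosines, w)
  w <- chip_window_counts(man$chip_reads, w)
  hi <- high_tss_genes(man$features[kind == "gene"], w)
  chg_only <- man$tss_high[plant_chg & !plant_k9, gene_id]
  k9_only <- man$tss_high[plant_k9 & !plant_chg, gene_id]
  both <- man$tss_high[plant_chg & plant_k9, gene_id]
  ## planted-both genes populate the intersection
  expect_true(all(both %in% hi$both))
  ## singly planted marks do not produce the other flag
  expect_length(intersect(chg_only, hi$high_k9), 0)
  expect_length(intersect(k9_only, hi$high_chg), 0)
  ## realized cutoff is reported and lies between background and planted levels
  expect_gt(hi$chg_cutoff, 0.05)
  expect_lt(hi$chg_cutoff, 0.95)
})

test_that("RPKM follows the formula and aggregates replicates", {
  expr <- data.table(gene_id = c("a", "b"), length_bp = c(2000L, 1000L),
                     rep1 = c(100L, 0L))
  ## library size 100 reads would not be 1e6; construct exact case:
  expr2 <- data.table(gene_id = c("a", "filler"), length_bp = c(2000L, 1000L),
                      rep1 = c(100L, 999900L))
  rp <- compute_rpkm(expr2)
  expect_equal(rp[gene_id == "a", rpkm], 50)      # 100 / (2 kb * 1 M)
  expect_equal(compute_rpkm(expr)[gene_id == "b", rpkm], 0)
  ## random table equals a spreadsheet-style recomputation
  tab <- withr::with_seed(37, data.table(
    gene_id = sprintf("g%02d", 1:20), length_bp = sample(500:5000, 20),
    r1 = rpois(20, 200), r2 = rpois(20, 300), r3 = rpois(20, 150)))
  rp2 <- compute_rpkm(tab)
  manual <- sapply(1:20, function(i) {
    mean(sapply(c("r1", "r2", "r3"), function(cc)
      tab[[cc]][i] / (tab$length_bp[i] / 1000) / (sum(tab[[cc]]) / 1e6)))
  })
  expect_equal(rp2$rpkm, manual)
  bad <- data.table(gene_id = "a", length_bp = 100L, r1 = 0L)
  expect_error(compute_rpkm(bad), "zero total")
})

test_that("expression groups form five disjoint categories of even size", {
  rp <- data.table(gene_id = sprintf("g%02d", 1:10),
                   rpkm = c(0, 0, 1, 2, 3, 4, 5, 6, 7, 8))
  gr <- expression_groups(rp)
  expect_equal(sum(gr$expr_group == "not_expressed"), 2L)
  expect_equal(as.integer(table(gr$expr_group)[c("Q1", "Q2", "Q3", "Q4")]),
               c(2L, 2L, 2L, 2L))
  ## 9 expressed genes: sizes differ by at most one
  rp2 <- data.table(gene_id = sprintf("g%02d", 1:9), rpkm = 1:9)
  t2 <- table(expression_groups(rp2)$expr_group)[c("Q1", "Q2", "Q3", "Q4")]
  expect_lte(diff(range(t2)), 1)
  ## grouping matches a direct quantile ranking on log-normal draws
  rp3 <- withr::with_seed(43, data.table(gene_id = sprintf("g%03d", 1:200),
                                         rpkm = rlnorm(200)))
  gr3 <- expression_groups(rp3)
  ord <- order(rp3$rpkm, rp3$gene_id)
  want <- paste0("Q", ceiling(4 * seq_len(200) / 200))
  expect_equal(as.character(gr3$expr_group[ord]), want)
  ## partition: every gene in exactly one category
  expect_false(anyNA(gr3$expr_group))
})

test_that("expression crosstab rows are proportions over the five groups", {
  cls <- data.table(gene_id = sprintf("g%02d", 1:10),
                    expr_group = factor(
                      rep(c("not_expressed", "Q1", "Q2", "Q3", "Q4"), each = 2),
                      levels = c("not_expressed", "Q1", "Q2", "Q3", "Q4")),
                    flag_a = rep(c(TRUE, FALSE), 5),
                    flag_b = c(TRUE, TRUE, rep(FALSE, 8)))
  xt <- class_expression_crosstab(cls)
  lv <- c("not_expressed", "Q1", "Q2", "Q3", "Q4")
  expect_equal(unlist(xt[flag == "flag_b", lv, with = FALSE], use.names = FALSE),
               c(1, 0, 0, 0, 0))
  sums <- rowSums(as.matrix(xt[, lv, with = FALSE]))
  expect_equal(sums[xt$n > 0], rep(1, sum(xt$n > 0)), ignore_attr = TRUE)
  ## empty flag: n = 0, proportions undefined
  cls2 <- copy(cls)[, flag_a := FALSE]
  xt2 <- class_expression_crosstab(cls2)
  expect_equal(xt2[flag == "flag_a", n], 0L)
  expect_true(all(is.na(xt2[flag == "flag_a", lv, with = FALSE])))
})
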