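## geometry fixtures: one element on a quiet chromosome, tracks planted by
## position so bin means are predictable

test_that("relative profile maps midpoints to the documented bins", {
  ## element [10000, 14000); windows 100 bp
  el <- data.table(chrom = "chr1", start = 10000L, end = 14000L)
  w <- make_track_windows(c(chr1 = 30000), cg = 1)
  p <- relative_profile(w, el, flank = 1000)
  expect_equal(nrow(p[track == "level_CG"]), 60L)
  ## window with midpoint at the element midpoint lands mid-element
  w2 <- w[start == 11900 | start == 12000]  # midpoints 11950, 12050 straddle 12000
  p2 <- relative_profile(w2, el)
  bins <- p2[track == "level_CG" & n > 0, bin_index]
  expect_true(all(bins %in% 30:31))
  ## window 950 bp upstream: distance -950, near flank start
  w3 <- w[start == 9000]                     # midpoint 9050, d = -950
  p3 <- relative_profile(w3, el)
  expect_equal(p3[track == "level_CG" & n > 0, bin_index], 2L)
  expect_equal(p3[track == "level_CG" & n > 0, mean], 1)
  ## flank <= 0 errors; far windows give empty profile with warning
  expect_error(relative_profile(w, el, flank = 0), "positive")
  expect_warning(relative_profile(w[start == 25000], el), "no window")
})

test_that("relative profile partitions retained pairs over bins", {
  man <- simulate_genome(sim_config(seed = 9))
  w <- make_track_windows(man$chrom_sizes, cg = 0.5)
  tes <- man$features[kind == "TE"]
  p <- relative_profile(w, tes)
  expect_equal(sum(p[track == "level_CG", n]), attr(p, "n_pairs"))
})

test_that("internal segment is invariant to element length for flat signal", {
  ## two elements with very different lengths, constant planted signal
  els <- data.table(chrom = "chr1", start = c(10000L, 40000L),
                    end = c(12000L, 48000L))
  w <- make_track_windows(c(chr1 = 60000), cg = 0.25)
  p <- relative_profile(w, els)
  internal <- p[track == "level_CG" & bin_index %in% 21:40]
  expect_true(all(internal$n > 0))
  expect_true(all(abs(internal$mean - 0.25) < 1e-12))
})

test_that("flank bins mirror for symmetric planted signal", {
  ## element deliberately offset from the window grid so flank midpoints
  ## fall strictly inside bins on both sides
  el <- data.table(chrom = "chr1", start = 9975L, end = 12025L)
  w <- tile_genome(c(chr1 = 22000), 100)
  mid <- (w$start + w$end) / 2
  ## signal depends only on the distance to the nearer element boundary
  d <- pmax(el$start - mid, mid - el$end, 0)
  w[, level_CG := 0.8 - 0.0003 * d]
  w[, `:=`(level_CHG = NA_real_, level_CHH = NA_real_, chip_count = 0)]
  p <- relative_profile(w, el)[track == "level_CG"]
  up <- p[bin_index %in% 1:20][order(bin_index)]       # bin k
  dn <- p[bin_index %in% 41:60][order(-bin_index)]     # bin 61 - k
  ok <- up$n > 0 & dn$n > 0
  expect_gte(sum(ok), 10)
  expect_true(all(abs(up$mean[ok] - dn$mean[ok]) < 0.015))
})

test_that("absolute profiles anchor at TSS with strand flip", {
  ## + strand gene with TSS at 10000: window [9000,9100) has dx = -950
  gp <- data.table(chrom = "chr1", start = 10000L, end = 16000L, strand = "+",
                   feature_id = "gp")
  gm <- data.table(chrom = "chr1", start = 4001L, end = 10001L, strand = "-",
                   feature_id = "gm")  # TSS at 10000
  w <- tile_genome(c(chr1 = 20000), 100)
  w[, level_CG := fifelse(start == 9000, 1, 0)]
  w[, `:=`(level_CHG = NA_real_, level_CHH = NA_real_, chip_count = 0)]
  pp <- absolute_gene_profile(w, gp)$five_prime[track == "level_CG"]
  ## dx = 9050 - 10000 = -950 -> bin 1 + floor(1050/50) = 22
  expect_equal(pp[mean == 1 & n > 0, bin_index], 22L)
  ## - strand gene 950 bp to the LEFT of nothing: window [10900,11000) is
  ## 950 bp upstream of gm's TSS after the flip
  w2 <- copy(w)[, level_CG := fifelse(start == 10900, 1, 0)]
  pm <- absolute_gene_profile(w2, gm)$five_prime[track == "level_CG"]
  expect_equal(pm[mean == 1 & n > 0, bin_index], 22L)
})

test_that("short genes stop contributing beyond their extent", {
  g <- data.table(chrom = "chr1", start = 10000L, end = 11500L, strand = "+",
                  feature_id = "g")  # 1.5 kb gene
  w <- make_track_windows(c(chr1 = 20000), cg = 0.5)
  p <- absolute_gene_profile(w, g)$five_prime[track == "level_CG"]
  ## genic bins beyond 1500 bp into the gene are empty
  expect_true(all(p[bin_center > 1500, n] == 0))
  ## contributing midpoints run -1950..1450 in 100 bp steps: 35 of them,
  ## each in its own 50 bp bin (window spacing leaves alternating bins empty)
  populated <- p[n > 0, bin_center]
  expect_length(populated, 35L)
  expect_lt(max(populated), 1500)
  expect_gt(min(populated), -2000)
})

test_that("5' and 3' plots agree on the shared body for long genes", {
  g <- data.table(chrom = "chr1", start = 10000L, end = 16000L, strand = "+",
                  feature_id = "g")  # 6 kb: 5' genic [0,3k] = 3' genic [-3k,0]
  w <- make_track_windows(c(chr1 = 30000), cg = 0.42)
  pr <- absolute_gene_profile(w, g)
  five_body <- pr$five_prime[track == "level_CG" & bin_center > 0 & n > 0]
  three_body <- pr$three_prime[track == "level_CG" & bin_center < 0 & n > 0]
  expect_equal(unique(five_body$mean), 0.42)
  expect_equal(unique(three_body$mean), 0.42)
  expect_equal(sum(five_body$n), sum(three_body$n))
})

test_that("masking removes genic windows only where masks overlap", {
  g <- data.table(chrom = "chr1", start = 10000L, end = 16000L, strand = "+",
                  feature_id = "g")
  ## planted: intronic-TE-like block [12000,13000) carries high CHG
  w <- tile_genome(c(chr1 = 30000), 100)
  w[, level_CHG := fifelse(start >= 12000 & start < 13000, 0.9, 0.05)]
  w[, `:=`(level_CG = NA_real_, level_CHH = NA_real_, chip_count = 0)]
  mask <- data.table(chrom = "chr1", start = 12000L, end = 13000L)
  un <- absolute_gene_profile(w, g)$five_prime[track == "level_CHG"]
  ma <- masked_profile(w, g, mask)$five_prime[track == "level_CHG"]
  genic_bins <- un[bin_center > 0 & n > 0, bin_index]
  ## masked profile loses exactly the masked windows
  expect_lt(sum(ma[bin_index %in% genic_bins, n]),
            sum(un[bin_index %in% genic_bins, n]))
  expect_true(all(ma[n > 0 & bin_center > 0, abs(mean - 0.05) < 1e-12]))
  expect_gt(mean(un[bin_center > 0 & n > 0, mean]), 0.05)
  ## no masks: identical to the unmasked profile
  ma0 <- masked_profile(w, g, NULL)$five_prime[track == "level_CHG"]
  expect_equal(ma0$mean, un$mean)
  expect_equal(ma0$n, un$n)
})

test_that("exon/intron restriction keeps only the requested genic windows", {
  paths <- write_tiny_annotation()
  feats <- read_features(paths$gff3, paths$te_bed)
  genes <- feats[kind == "gene" & feature_id == "gA"]
  w <- make_track_windows(c(chr1 = 13000), chg = 0.3)
  full <- absolute_gene_profile(w, genes)$five_prime[track == "level_CHG"]
  exon_only <- masked_profile(w, genes, restrict = "exon",
                              features = feats)$five_prime[track == "level_CHG"]
  intron_only <- masked_profile(w, genes, restrict = "intron",
                                features = feats)$five_prime[track == "level_CHG"]
  genic <- full[bin_center > 0, sum(n)]
  expect_lt(exon_only[bin_center > 0, sum(n)], genic)
  expect_lt(intron_only[bin_center > 0, sum(n)], genic)
  ## flank side untouched
  expect_equal(exon_only[bin_center < 0, sum(n)], full[bin_center < 0, sum(n)])
})

test_that("grouped profiles split genes by metadata", {
  g <- data.table(chrom = "chr1", start = c(10000L, 40000L),
                  end = c(16000L, 46000L), strand = "+",
                  feature_id = c("a", "b"), gene_set = c("FGS", "WGS"))
  w <- tile_genome(c(chr1 = 60000), 100)
  w[, level_CG := fifelse(start < 30000, 0.8, 0.2)]  # a-territory high
  w[, `:=`(level_CHG = NA_real_, level_CHH = NA_real_, chip_count = 0)]
  gr <- grouped_profiles(w, g, "gene_set")
  expect_named(gr, c("FGS", "WGS"))
  ma <- gr$FGS$five_prime[track == "level_CG" & n > 0, mean(mean)]
  mb <- gr$WGS$five_prime[track == "level_CG" & n > 0, mean(mean)]
  expect_gt(ma, mb)
  ## single label equals ungrouped
  g2 <- copy(g)[, gene_set := "FGS"]
  gr2 <- grouped_profiles(w, g2, "gene_set")
  un <- absolute_gene_profile(w, g2)
  expect_equal(gr2$FGS$five_prime$mean, un$five_prime$mean)
  expect_error(grouped_profiles(w, g, "nope"), "unknown")
})
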