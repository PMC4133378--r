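test_that("sub-family summaries average overlapping windows once", {
  tes <- rbind(mk_te("chr1", 1000, 1200, "RLG1", "RLG"),
               mk_te("chr1", 5000, 5200, "RLG2", "RLG"))
  w <- tile_genome(c(chr1 = 10000), 100)
  w[, level_CHG := fifelse(start %in% c(1000, 1100), 0.8,
                    fifelse(start %in% c(5000, 5100), 0.9, 0.1))]
  w[, `:=`(level_CG = NA_real_, level_CHH = NA_real_, chip_count = 0)]
  s <- subfamily_summary(w, tes, tracks = "level_CHG")
  expect_equal(s$mean_level_CHG, 0.85)
  expect_equal(s$n_level_CHG, 4L)
  expect_equal(s$n_elements, 2L)
  ## no covered windows: undefined mean, n = 0
  w2 <- copy(w)[, level_CHG := NA_real_]
  s2 <- subfamily_summary(w2, tes, tracks = "level_CHG")
  expect_true(is.na(s2$mean_level_CHG))
  expect_equal(s2$n_level_CHG, 0L)
  expect_error(subfamily_summary(w, tes, group_field = "bogus"), "unknown")
  ## a window overlapping two same-family elements counts once
  tes3 <- rbind(mk_te("chr1", 1000, 1150, "A1", "DTA", "TIR"),
                mk_te("chr1", 1150, 1300, "A2", "DTA", "TIR"))
  s3 <- subfamily_summary(w, tes3, tracks = "level_CHG")
  expect_equal(s3$n_level_CHG, 3L)  # windows 1000,1100,1200 - 1100 shared
})

test_that("flank bands sit 900-1000 bp away and qualify by overlap", {
  tes <- mk_te("chr1", 5000, 7000, "RLG1", "RLG")
  w <- tile_genome(c(chr1 = 10000), 100)
  w[, level_CHG := fifelse(start == 4000, 0.7, fifelse(start == 7900, 0.3, 0.1))]
  w[, `:=`(level_CG = NA_real_, level_CHH = NA_real_, chip_count = 0)]
  fs <- flank_summary(w, tes, tracks = "level_CHG")
  up <- fs[side == "upstream"]
  dn <- fs[side == "downstream"]
  pl <- fs[side == "pooled"]
  ## bands are [4000,4100) and [7900,8000): exactly one window each
  expect_equal(up$n_level_CHG, 1L)
  expect_equal(up$mean_level_CHG, 0.7)
  expect_equal(dn$mean_level_CHG, 0.3)
  expect_equal(pl$mean_level_CHG, 0.5)
  expect_error(flank_summary(w, tes, near = 1000, far = 900), "near < far")
})

test_that("flank band means match a direct recomputation on random data", {
  man <- simulate_genome(sim_config(seed = 13))
  w <- make_track_windows(man$chrom_sizes,
                          cg = withr::with_seed(14, runif(sum(man$chrom_sizes) / 100)))
  tes <- man$features[kind == "TE"]
  fs <- flank_summary(w, tes, tracks = "level_CG")
  ## recompute one sub-family's pooled mean by explicit band overlap
  sub <- tes[te_subfamily == "RLG"]
  bands <- rbind(sub[, .(chrom, s = start - 1000L, e = start - 900L)],
                 sub[, .(chrom, s = end + 900L, e = end + 1000L)])
  sel <- unique(unlist(lapply(seq_len(nrow(bands)), function(i) {
    which(w$chrom == bands$chrom[i] & w$start < bands$e[i] & w$end > bands$s[i])
  })))
  expect_equal(fs[te_subfamily == "RLG" & side == "pooled", mean_level_CG],
               mean(w$level_CG[sel]))
})

test_that("nearest gene distances match the all-pairs oracle", {
  tes <- rbind(mk_te("chr1", 5000, 6000, "t1", "RLG"),
               mk_te("chr1", 6600, 6800, "t2", "DTM", "TIR"),
               mk_te("chr2", 100, 300, "t3", "RLC"))
  genes <- data.table(chrom = c("chr1", "chr1"), start = c(6500L, 6700L),
                      end = c(9000L, 7000L), strand = "+",
                      feature_id = c("g1", "g2"))
  nd <- nearest_gene_distance(tes, genes)
  expect_equal(nd$per_te$distance, c(500, 0, NA))  # t2 overlaps g1; chr2 empty
  man <- simulate_genome(sim_config(seed = 17))
  tes2 <- man$features[kind == "TE"]
  genes2 <- man$features[kind == "gene"]
  nd2 <- nearest_gene_distance(tes2, genes2)
  expect_equal(nd2$per_te$distance, oracle_nearest_distance(tes2, genes2))
  ## per-sub-family mean is the arithmetic mean of member distances
  m <- nd2$per_te[!is.na(distance), .(m = mean(distance)), by = te_subfamily]
  expect_equal(nd2$per_subfamily[order(te_subfamily), mean_distance],
               m[order(te_subfamily), m])
})

test_that("genic TE catalog applies the strict length and containment rules", {
  ann <- toy_genic_annotation()
  res <- genic_te_catalog(ann$tes, ann$features, min_len = 1000)
  expect_equal(res$flagged_genes, "gA")
  expect_equal(nrow(res$catalog), 1L)
  expect_equal(res$catalog$te_id, "teA")
  expect_equal(res$catalog$te_length, 1200L)
  ## monotone in threshold: min_len = 0 is a superset
  res0 <- genic_te_catalog(ann$tes, ann$features, min_len = 0)
  expect_true(all(res$catalog$te_id %in% res0$catalog$te_id))
  expect_true("teB" %in% res0$catalog$te_id)
  ## boundary-spanning long TE is excluded but counted
  tes2 <- rbind(ann$tes, mk_te("chr1", 1300, 2600, "teSpan", "RLG"))
  res2 <- genic_te_catalog(tes2, ann$features, min_len = 1000)
  expect_false("teSpan" %in% res2$catalog$te_id)
  expect_gte(res2$n_boundary_tes, 1L)
})

test_that("catalog recovers the planted host set exactly", {
  man <- simulate_genome(sim_config(seed = 19))
  res <- genic_te_catalog(man$features[kind == "TE"], man$features)
  expect_equal(res$flagged_genes, man$genic_te_hosts)
  expect_equal(sort(res$catalog$te_id), sort(man$intronic_tes$te_id))
})

test_that("genic TE chromatin contrasts the three region classes", {
  ann <- toy_genic_annotation()
  w <- tile_genome(c(chr1 = 50000), 100)
  in_te <- sapply(seq_len(nrow(w)), function(i)
    any(ann$tes$start < w$end[i] & ann$tes$end > w$start[i]))
  w[, level_CHG := fifelse(in_te, 0.9, 0.02)]
  w[, `:=`(level_CG = NA_real_, level_CHH = NA_real_, chip_count = 0)]
  cat_res <- genic_te_catalog(ann$tes, ann$features)
  gc <- genic_te_chromatin(w, cat_res, ann$tes, ann$features, tracks = "level_CHG")
  expect_equal(gc[region_class == "genic_TEs", mean], 0.9)
  expect_equal(gc[region_class == "exons", mean], 0.02)
  expect_equal(gc[region_class == "all_TEs", mean], 0.9)
  ## empty catalog: undefined mean, n = 0
  empty <- genic_te_catalog(ann$tes[te_subfamily == "DTM"], ann$features)
  gc2 <- genic_te_chromatin(w, empty, ann$tes, ann$features, tracks = "level_CHG")
  expect_true(is.na(gc2[region_class == "genic_TEs", mean]))
  expect_equal(gc2[region_class == "genic_TEs", n], 0L)
})

test_that("class enrichment proportions and ratios follow the definitions", {
  catalog <- data.table(te_id = paste0("t", 1:4),
                        te_class = c("LTR", "LTR", "LINE", "TIR"))
  tes <- data.table(feature_id = paste0("x", 1:100),
                    te_class = rep(c("LTR", "LINE", "TIR"), c(50, 5, 45)))
  enr <- class_enrichment_in_genes(catalog, tes)
  expect_equal(enr[te_class == "LTR", genic_prop], 0.5)
  expect_equal(enr[te_class == "LINE", genic_prop], 0.25)
  expect_equal(enr[te_class == "LINE", ratio], 0.25 / 0.05)
  expect_equal(sum(enr$genic_prop), 1, tolerance = 1e-12)
  expect_equal(sum(enr$genome_prop), 1, tolerance = 1e-12)
  ## identical composition: all ratios 1
  enr2 <- class_enrichment_in_genes(
    data.table(te_id = paste0("t", 1:20),
               te_class = rep(c("LTR", "LINE", "TIR"), c(10, 1, 9))),
    data.table(feature_id = paste0("x", 1:40),
               te_class = rep(c("LTR", "LINE", "TIR"), c(20, 2, 18))))
  expect_equal(enr2$ratio, rep(1, 3))
})
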