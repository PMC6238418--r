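test_that("travelling ratio is densities over the defined windows", {
  sl <- c(c1 = 30000)
  g <- gene_models("g1", "c1", 10000, 20000, "+")

  uni <- uniform_tracks(sl, value = 2)
  tru <- travelling_ratio(uni, g)
  expect_equal(tru$tr, 1, tolerance = 1e-12)
  expect_equal(tru$proximal_density, 2)

  # 560 tags over the 280-bp promoter, 0.5 tags/bp over the body
  v <- list(c1 = numeric(30000))
  v$c1[(9970 + 1):10250] <- 2    # proximal sum 560
  v$c1[(10300 + 1):19800] <- 0.5 # body sum 4750 over 9500 bp
  tr <- list(plus = tag_track(v, sl), minus = tag_track(list(c1 = numeric(30000)), sl))
  res <- travelling_ratio(tr, g)
  expect_equal(res$proximal_density, 560 / 280)
  expect_equal(res$body_density, 0.5)
  expect_equal(res$tr, 4)

  # scale invariance: the ratio ignores any per-sample scaling
  v2 <- lapply(v, `*`, 7.3)
  tr2 <- list(plus = tag_track(v2, sl, norm_state = "rpgc"),
              minus = tr$minus)
  expect_equal(travelling_ratio(tr2, g)$tr, res$tr, tolerance = 1e-12)

  # zero body coverage flags the gene unusable
  v3 <- list(c1 = numeric(30000)); v3$c1[(9970 + 1):10250] <- 1
  tr3 <- list(plus = tag_track(v3, sl), minus = tr$minus)
  expect_false(travelling_ratio(tr3, g)$usable)
})

test_that("pause-peak genes show higher travelling ratios than peak-free genes", {
  cfg_peak <- mini_config(seed = 61, per_class = 10)
  cfg_flat <- mini_config(seed = 61, per_class = 10, pause_tags = 0)
  med_tr <- vapply(list(cfg_peak, cfg_flat), function(cfg) {
    sim <- simulate_genome(cfg)
    tags <- simulate_netseq(sim$genes, sim$truth, "control", cfg)
    pair <- build_track(dedup_tags(tags), sim$seqlens)
    median(travelling_ratio(pair, sim$genes)$tr, na.rm = TRUE)
  }, 0)
  expect_gt(med_tr[1], med_tr[2])
})

test_that("antisense quantification reads the opposite strand upstream", {
  sl <- c(c1 = 30000)
  g <- gene_models("g1", "c1", 10000, 20000, "+")
  mk <- function(minus_positions) {
    v <- list(c1 = numeric(30000))
    v$c1[minus_positions + 1] <- 1
    list(plus = tag_track(list(c1 = numeric(30000)), sl),
         minus = tag_track(v, sl))
  }
  ctrl <- mk(seq(9000, 9990, by = 110))  # 10 tags in [9000,10000)
  rec <- antisense_quant(ctrl, ctrl, g)
  expect_equal(rec$antisense_density_control, 0.01)
  expect_equal(rec$log2_fold_change, 0)

  kd <- mk(seq(9000, 9995, by = 50))     # 20 tags
  up <- antisense_quant(ctrl, kd, g)
  down <- antisense_quant(kd, ctrl, g)
  expect_equal(up$log2_fold_change, -down$log2_fold_change)  # antisymmetry
  expect_gt(up$log2_fold_change, 0.9)
})

test_that("antisense gain of 2 gives a median log2FC near 1 at adequate depth", {
  cfg <- mini_config(seed = 62, per_class = 34, duplicate_rate = 0)
  sim <- simulate_genome(cfg)
  pair <- lapply(c(control = "control", kd = "kd"), function(cond) {
    tags <- simulate_netseq(sim$genes, sim$truth, cond, cfg)
    clean <- remove_splicing_intermediates(tags, sim$genes)$kept
    build_track(clean, sim$seqlens)
  })
  rec <- antisense_quant(pair$control, pair$kd, sim$genes)
  tru <- sim$truth[match(rec$gene_id, sim$truth$gene_id), ]
  med <- median(rec$log2_fold_change[tru$bound & tru$class == "up"])
  expect_gte(med, 0.7)
  expect_lte(med, 1.3)
})

test_that("expression summaries scale correctly and quartile the genes", {
  es <- expression_summary(setNames(c(100, 10, 1000, 1), paste0("g", 1:4)),
                           gene_lengths = c(1000, 1000, 1000, 1000))
  expect_equal(es$cpm[1], 100 / sum(c(100, 10, 1000, 1)) * 1e6)
  expect_equal(es$rpkm, es$cpm)  # 1-kb genes

  counts <- matrix(c(100, 900), 2, 1,
                   dimnames = list(c("a", "b"), "s"))
  one <- expression_summary(counts, c(1000, 2000))
  expect_equal(one$cpm, c(1e5, 9e5))
  expect_equal(one$rpkm, c(1e5, 9e5 / 2))
  expect_equal(expression_summary(counts * 2, c(1000, 2000))$rpkm, one$rpkm)

  ties <- expression_summary(setNames(rep(5, 8), paste0("g", 1:8)),
                             rep(100, 8))
  expect_equal(as.integer(table(ties$quantile_class)), rep(2L, 4))
})

test_that("region densities correlate as expected", {
  sl <- c(c1 = 100000)
  set.seed(63)
  base <- rpois(100000, 2)
  ta <- tag_track(list(c1 = as.numeric(base)), sl)
  tneg <- tag_track(list(c1 = as.numeric(max(base) - base)), sl)
  regions <- data.frame(chrom = "c1", start = seq(0, 99000, by = 1000))
  regions$end <- regions$start + 500
  rd <- region_density_matrix(list(a = ta, a2 = ta, neg = tneg), regions,
                              log_transform = FALSE)
  expect_equal(rd$cor["a", "a2"], 1)
  expect_lt(rd$cor["a", "neg"], -0.99)

  tb <- tag_track(list(c1 = as.numeric(rpois(100000, 2))), sl)
  rd2 <- region_density_matrix(list(a = ta, b = tb), regions,
                               log_transform = FALSE)
  expect_lt(abs(rd2$cor["a", "b"]), 0.1)

  flat <- tag_track(list(c1 = rep(1, 100000)), sl)
  rd3 <- region_density_matrix(list(a = ta, z = flat), regions)
  expect_true(is.na(rd3$cor["a", "z"]))
  expect_error(region_density_matrix(list(a = ta), regions[1:2, ]), "3")
})

test_that("gene classification applies the logFC and adjusted-p thresholds", {
  de <- data.frame(gene_id = c("a", "b", "c", "d", "e"),
                   logfc = c(2, 2, 0.1, -3, 1.5),
                   adj_p = c(0.001, 0.02, 0.5, 0.005, 0.03))
  cls <- classify_genes(de, bound_ids = c("a", "c"))
  expect_equal(as.character(cls$de_class), c("up", "other", "unchanged",
                                             "down", "other"))
  expect_equal(cls$bound, c(TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(sum(table(cls$de_class)), nrow(de))  # classes cover all genes
  expect_warning(classify_genes(de, "nope"), "absent")
})

test_that("spike rows concentrated in a 100-bp window are filtered out", {
  n <- 2000
  spiky <- numeric(n); spiky[300:349] <- 5          # all signal in 50 bp
  uniform <- rep(1, n)                               # max 100-bp share 0.05
  planted <- numeric(n); planted[1000:1079] <- 3     # 80-bp spike
  m <- rbind(spiky = spiky, uniform = uniform, planted = planted,
             empty = numeric(n))
  kept <- spike_filter(m)
  expect_setequal(rownames(kept), c("uniform", "empty"))
  expect_setequal(attr(kept, "removed"), c("spiky", "planted"))

  mixed <- uniform; mixed[500:549] <- 3  # spike carries <80% of the total
  expect_equal(nrow(spike_filter(rbind(mixed = mixed))), 1)
})
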