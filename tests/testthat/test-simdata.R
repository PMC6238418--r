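test_that("simulation is byte-identical under a fixed seed", {
  cfg <- mini_config(seed = 5, per_class = 4)
  a <- simulate_genome(cfg)
  b <- simulate_genome(cfg)
  expect_identical(a$genes, b$genes)
  expect_identical(a$truth, b$truth)
  expect_identical(simulate_netseq(a$genes, a$truth, "kd", cfg),
                   simulate_netseq(b$genes, b$truth, "kd", cfg))
  expect_identical(simulate_fragments(a$genes, a$truth, "control", "mnase", cfg),
                   simulate_fragments(b$genes, b$truth, "control", "mnase", cfg))
  expect_identical(simulate_counts(a$genes, a$truth, cfg),
                   simulate_counts(b$genes, b$truth, cfg))
})

test_that("gene placement leaves every promoter isolated by construction", {
  sim <- simulate_genome(mini_config(seed = 6, per_class = 8))
  expect_equal(nrow(filter_isolated_promoters(sim$genes)), nrow(sim$genes))
})

test_that("planted upstream overlaps are exactly the genes the filter drops", {
  cfg <- mini_config(seed = 7, per_class = 6, planted_overlaps = 2)
  sim <- simulate_genome(cfg)
  kept <- filter_isolated_promoters(sim$genes)
  removed <- setdiff(sim$genes$gene_id, kept$gene_id)
  expect_setequal(removed, attr(sim$truth, "planted_nonisolated"))
  expect_length(removed, 2)
})

test_that("promoter GC tracks the configured rate", {
  cfg <- truth_config(seed = 8, gc_promoter = 0.6,
                      class_counts = c(up_bound = 3, up_unbound = 3,
                                       down_bound = 3, down_unbound = 3,
                                       unchanged_bound = 3,
                                       unchanged_unbound = 3))
  sim <- simulate_genome(cfg)
  anchors <- tss_site(sim$genes)
  prof <- gc_profile(sim$genome, anchors, flank = 400)
  n_bases <- nrow(anchors) * 800
  tol <- 4 * sqrt(0.6 * 0.4 / n_bases)
  expect_lt(abs(mean(prof$gc) - 0.6), tol)
})

test_that("duplicate planting matches the configured rate and UMIs dedup exactly", {
  cfg <- mini_config(seed = 9, per_class = 10, duplicate_rate = 0.5)
  tags <- simulate_netseq(simulate_genome(cfg)$genes,
                          simulate_genome(cfg)$truth, "control", cfg)
  n_primary <- sum(!tags$duplicate)
  n_dup <- sum(tags$duplicate)
  expect_lt(abs(n_dup / n_primary - 0.5), 4 * sqrt(0.25 / n_primary))
  dd <- dedup_tags(tags)
  expect_equal(nrow(dd), n_primary)
  expect_false(any(dd$duplicate))
})

test_that("splice-site bases carry no tags when the intermediate rate is zero", {
  cfg <- mini_config(seed = 10, per_class = 8, splice_intermediate_tags = 0)
  sim <- simulate_genome(cfg)
  tags <- simulate_netseq(sim$genes, sim$truth, "control", cfg)
  res <- remove_splicing_intermediates(tags, sim$genes)
  expect_equal(nrow(res$removed), 0)
  expect_equal(nrow(res$kept), nrow(tags))
})

test_that("antisense counts are condition-neutral when the gain is 1", {
  cfg <- mini_config(seed = 12, per_class = 34, antisense_gain = 1,
                     duplicate_rate = 0)
  sim <- simulate_genome(cfg)
  anti_n <- vapply(c("control", "kd"), function(cond) {
    tags <- simulate_netseq(sim$genes, sim$truth, cond, cfg)
    gstr <- sim$genes$strand[match(tags$gene_id, sim$genes$gene_id)]
    sum(tags$kind == "signal" & tags$strand != gstr)
  }, 0)
  expect_gt(poisson.test(anti_n)$p.value, 0.01)
})

test_that("planted dyads are recoverable from mononucleosome midpoints", {
  cfg <- mini_config(seed = 13, per_class = 10, upstream_nucleosome_loss = 0)
  sim <- simulate_genome(cfg)
  fr <- simulate_fragments(sim$genes, sim$truth, "control", "mnase", cfg)
  expect_true(all(fr$length >= 120 & fr$length <= 190))
  mono <- partition_fragments(fr)$mononucleosome
  # 20-bp smoothing, as for occupancy metaplots, stabilises the peak call
  trk <- smooth_track(build_track(mono, sim$seqlens, mode = "midpoint"))
  prof <- metaprofile(trk, tss_site(sim$genes), flank = 300)
  up <- prof[prof$offset < 0, ]
  peak <- up$offset[which.max(up$mean)]
  expect_lte(abs(peak - (-180)), 5)
})

test_that("fragment-length partition reproduces the planted length histogram", {
  cfg <- mini_config(seed = 14, per_class = 5)
  sim <- simulate_genome(cfg)
  fr <- simulate_fragments(sim$genes, sim$truth, "control", "atac", cfg)
  parts <- partition_fragments(fr)
  expect_equal(nrow(parts$subnucleosomal), sum(fr$length < 80))
  expect_equal(nrow(parts$mononucleosome),
               sum(fr$length >= 135 & fr$length <= 170))
})

test_that("count simulation supports planted-effect recovery and TMM centring", {
  cfg <- mini_config(seed = 15, per_class = 50, logfc = c(up = 3, down = -3,
                                                          unchanged = 0),
                     count_meanlog = log(100), count_sdlog = 0)
  sim <- simulate_genome(cfg)
  counts <- simulate_counts(sim$genes, sim$truth, cfg)
  design <- factor(sub("_[0-9]+$", "", colnames(counts)),
                   levels = c("control", "kd"))
  de <- de_call(counts, design)
  cls <- classify_genes(de, character(0))
  up_true <- sim$truth$gene_id[sim$truth$class == "up"]
  recall <- mean(up_true %in% cls$gene_id[cls$de_class == "up"])
  expect_gte(recall, 0.95)

  # a doubled library is absorbed by TMM: null logFCs stay centred at 0
  cfg0 <- mini_config(seed = 16, per_class = 50,
                      logfc = c(up = 0, down = 0, unchanged = 0),
                      libsize_factors = c(2, rep(1, 7)))
  sim0 <- simulate_genome(cfg0)
  de0 <- de_call(simulate_counts(sim0$genes, sim0$truth, cfg0), design)
  expect_lt(abs(median(de0$logfc)), 0.05)
})
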