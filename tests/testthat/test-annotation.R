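test_that("BED parsing applies the strand-aware TSS/TES convention", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t600\tg1\t0\t+",
               "chr1\t100\t600\tg2\t0\t-"), path)
  g <- read_annotation(path)
  expect_equal(g$tss[g$gene_id == "g1"], 100)
  expect_equal(g$tes[g$gene_id == "g1"], 600)
  expect_equal(g$tss[g$gene_id == "g2"], 600)
  expect_equal(g$tes[g$gene_id == "g2"], 100)
})

test_that("malformed BED lines and bad strands are reported by line number", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t600\tg1\t0\t+", "chr1\t700"), path)
  expect_error(read_annotation(path), "line 2")
  writeLines(c("chr1\t100\t600\tg1\t0\t*"), path)
  expect_error(read_annotation(path), "strand")
})

test_that("BED12 write/read round trip preserves coordinates and exons", {
  set.seed(11)
  for (rep in 1:5) {
    n <- 6
    start <- sort(sample.int(50000, n)) * 2
    len <- sample(2000:5000, n)
    exons <- lapply(seq_len(n), function(i) {
      cbind(start = start[i] + c(0, 900, 1800),
            end = start[i] + c(400, 1300, len[i]))
    })
    names(exons) <- paste0("t", seq_len(n))
    g <- gene_models(names(exons), "chrX", start, start + len,
                     sample(c("+", "-"), n, TRUE), exons)
    path <- withr::local_tempfile(fileext = ".bed")
    write_genes_bed(g, path)
    g2 <- read_annotation(path)
    expect_equal(as.data.frame(g2), as.data.frame(g))
    expect_equal(gene_exons(g2), gene_exons(g))
  }
})

test_that("GTF exons convert from 1-based closed to 0-based half-open", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste0("chr1\tsrc\texon\t101\t200\t.\t+\t.\t",
           'gene_id "g1"; transcript_id "t1";'),
    paste0("chr1\tsrc\texon\t301\t400\t.\t+\t.\t",
           'gene_id "g1"; transcript_id "t1";'),
    paste0("chr1\tsrc\texon\t501\t700\t.\t-\t.\t",
           'gene_id "g2"; transcript_id "t2";')), path)
  g <- read_annotation(path)
  ex <- gene_exons(g)[["t1"]]
  expect_equal(unname(ex[, "start"]), c(100, 300))
  expect_equal(unname(ex[, "end"]), c(200, 400))
  expect_equal(g$tss[g$gene_id == "t1"], 100)
  expect_equal(g$tss[g$gene_id == "t2"], 700)  # minus strand: right boundary
})

test_that("derived regions match the window definitions", {
  g <- gene_models("g1", "chr1", 10000, 20000, "+")
  prox <- derive_region(g, "proximal_promoter")
  expect_equal(c(prox$start, prox$end), c(9970, 10250))
  expect_equal(prox$end - prox$start, 280)
  body <- derive_region(g, "gene_body")
  expect_equal(c(body$start, body$end), c(10300, 19800))
  expect_equal(body$end - body$start, (20000 - 10000) - 500)
  anti <- derive_region(g, "antisense_window")
  expect_equal(c(anti$start, anti$end), c(9000, 10000))

  gm <- gene_models("g2", "chr1", 5000, 10000, "-")  # tss boundary = 10000
  antim <- derive_region(gm, "antisense_window")
  expect_equal(c(antim$start, antim$end), c(10000, 11000))
  proxm <- derive_region(gm, "proximal_promoter")
  expect_equal(c(proxm$start, proxm$end), c(9750, 10030))

  tiny <- gene_models("g3", "chr1", 1000, 1400, "+")
  expect_false(derive_region(tiny, "gene_body")$usable)
})

test_that("minus-strand regions are the mirror image of plus-strand regions", {
  set.seed(21)
  L <- 1e6
  for (i in 1:20) {
    s <- sample.int(L - 20000, 1) + 5000
    len <- sample(1500:8000, 1)
    gp <- gene_models("p", "c", s, s + len, "+")
    gm <- gene_models("m", "c", L - (s + len), L - s, "-")
    for (role in c("proximal_promoter", "gene_body", "antisense_window",
                   "tss_flank")) {
      rp <- derive_region(gp, role)
      rm <- derive_region(gm, role)
      if (isTRUE(rp$usable)) {
        expect_equal(rm$start, L - rp$end)
        expect_equal(rm$end, L - rp$start)
      } else {
        expect_false(rm$usable)
      }
    }
  }
})

test_that("promoter isolation matches brute force; subset and idempotent", {
  two <- gene_models(c("a", "b"), "chr1", c(0, 2000), c(1000, 5000),
                     c("+", "+"))
  kept <- filter_isolated_promoters(two)
  expect_equal(kept$gene_id, "a")  # b's upstream window reaches into a

  solo <- gene_models("x", "chr9", 5000, 8000, "+")
  expect_equal(nrow(filter_isolated_promoters(solo)), 1)

  cross <- gene_models(c("a", "b"), c("chr1", "chr2"), c(0, 500),
                       c(1000, 1500), c("+", "+"))
  expect_equal(nrow(filter_isolated_promoters(cross)), 2)

  set.seed(31)
  for (rep in 1:10) {
    n <- 15
    start <- sample.int(60000, n)
    g <- gene_models(paste0("g", seq_len(n)),
                     sample(c("c1", "c2"), n, TRUE),
                     start, start + sample(500:3000, n, TRUE),
                     sample(c("+", "-"), n, TRUE))
    f <- filter_isolated_promoters(g)
    expect_setequal(f$gene_id, brute_isolated(g))
    expect_true(all(f$gene_id %in% g$gene_id))
    expect_equal(filter_isolated_promoters(f)$gene_id, f$gene_id)
  }
})

test_that("gc_profile measures GC content with orientation and N handling", {
  mk <- function(s) Biostrings::DNAStringSet(setNames(s, "c"))
  anchors <- data.frame(chrom = "c", pos = 50, strand = "+")
  expect_true(all(gc_profile(mk(strrep("GC", 100)), anchors, 20)$gc == 1))
  expect_true(all(gc_profile(mk(strrep("AT", 100)), anchors, 20)$gc == 0))
  p4 <- gc_profile(mk(strrep("GATC", 50)), anchors, 20, bin = 4)
  expect_true(all(p4$gc == 0.5))

  withN <- paste0(strrep("G", 60), strrep("N", 20), strrep("G", 60))
  pn <- gc_profile(mk(withN), data.frame(chrom = "c", pos = 70, strand = "+"),
                   10)
  expect_true(all(is.na(pn$gc)))  # all-N window reported missing, not zero

  # lone G at position 60; minus-strand anchor at 50 sees it at offset -10
  seqv <- rep("A", 200); seqv[61] <- "G"
  pm <- gc_profile(mk(paste(seqv, collapse = "")),
                   data.frame(chrom = "c", pos = 50, strand = "-"), 20)
  expect_equal(pm$gc[pm$offset == -10], 1)
  expect_equal(sum(pm$gc), 1)
})
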