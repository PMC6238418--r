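#' Configuration of the synthetic multi-assay experiment
#'
#' Bundles every effect size, rate and layout parameter for the synthetic
#' genome and the four assay simulators (NET-seq, MNase-seq, ATAC-seq,
#' RNA-seq counts). Genes fall into six ground-truth classes — {up, down,
#' unchanged} expression response crossed with {bound, unbound} factor
#' occupancy — and all condition-dependent effects (antisense gain, upstream
#' nucleosome loss, ATAC accessibility gain) are confined to the bound,
#' up-regulated class, mirroring the biology the pipeline is built to detect.
#'
#' @param seed integer master seed; every simulator derives its own stream
#'   from it via \code{stage_seed}.
#' @param class_counts named integer vector of gene counts per class
#'   (up/down/unchanged crossed with bound/unbound).
#' @param logfc planted log2 fold changes (KD vs control) per expression class.
#' @param gene_length_range min/max simulated gene length (bp).
#' @param exons_per_gene exon count per gene model.
#' @param intergenic_gap gap between consecutive gene spans (bp); the default
#'   2600 guarantees at least 2.5 kb upstream clearance by construction so
#'   the promoter-isolation filter is a no-op unless violations are planted.
#' @param chrom,chrom_length chromosome name and length; \code{NULL} length
#'   is auto-sized to fit all genes.
#' @param gc_background,gc_promoter,promoter_gc_halfwidth GC fraction of the
#'   simulated sequence genome-wide and within ±halfwidth of each TSS.
#' @param body_rate NET-seq sense tag rate over the gene span (tags/bp).
#' @param pause_tags expected tags in the promoter-proximal pause peak.
#' @param pause_center,pause_sd Gaussian pause-peak centre (bp downstream of
#'   the TSS, within the first 250 bp) and width.
#' @param antisense_rate baseline antisense tag rate in the 1-kb upstream
#'   window (tags/bp); the default 0.02 gives ~20 expected tags per window.
#' @param antisense_gain multiplier (>= 1) applied to the antisense rate at
#'   bound up-regulated genes in the knockdown condition.
#' @param duplicate_rate probability that a tag receives one PCR-duplicate copy.
#' @param splice_intermediate_tags expected planted splicing-intermediate
#'   tags per exon/intron 3'-end site.
#' @param nucleosome_spacing,first_dyad_offset,n_downstream_nucleosomes
#'   phased downstream dyads at TSS + first_dyad_offset + spacing*(k-1).
#' @param upstream_dyad_offset position of the upstream (−1) dyad relative
#'   to the TSS (negative, bp).
#' @param dyad_fuzz Gaussian SD of fragment midpoints around each dyad (bp).
#' @param frags_per_dyad expected MNase fragments per dyad per gene.
#' @param frag_len_mean,frag_len_sd,frag_len_range mononucleosome fragment
#'   length distribution (normal, clipped).
#' @param upstream_nucleosome_loss fraction in [0,1] by which the upstream
#'   dyad weight is reduced at bound up-regulated genes in the knockdown.
#' @param atac_nfr_per_gene,atac_mono_per_gene expected ATAC short (NFR) and
#'   mononucleosome fragments per gene.
#' @param atac_nfr_gain multiplier on NFR fragment rate at bound
#'   up-regulated genes in the knockdown.
#' @param nfr_len_mean,nfr_len_sd,nfr_len_range ATAC NFR fragment lengths.
#' @param n_reps RNA-seq replicates per condition (>= 2).
#' @param count_meanlog,count_sdlog log-normal distribution of gene baseline
#'   mean counts.
#' @param dispersion negative-binomial dispersion of counts.
#' @param libsize_factors optional per-sample library scale factors (length
#'   2 * n_reps); default all 1.
#' @param planted_overlaps number of genes deliberately given a decoy gene
#'   inside their 2.5-kb upstream window (to exercise the isolation filter).
#' @param simulate_sequence generate the nucleotide sequence (disable for
#'   runs that do not need GC profiles).
#' @return a validated \code{truth_config} list.
#' @export
truth_config <- function(seed = 1,
                         class_counts = c(up_bound = 45, up_unbound = 89,
                                          down_bound = 55, down_unbound = 110,
                                          unchanged_bound = 73,
                                          unchanged_unbound = 145),
                         logfc = c(up = 2, down = -2, unchanged = 0),
                         gene_length_range = c(1500, 3000),
                         exons_per_gene = 3,
                         intergenic_gap = 2600,
                         chrom = "chrS", chrom_length = NULL,
                         gc_background = 0.42, gc_promoter = 0.5,
                         promoter_gc_halfwidth = 500,
                         body_rate = 0.04, pause_tags = 120,
                         pause_center = 40, pause_sd = 15,
                         antisense_rate = 0.02, antisense_gain = 2,
                         duplicate_rate = 0.1, splice_intermediate_tags = 2,
                         nucleosome_spacing = 185, first_dyad_offset = 100,
                         n_downstream_nucleosomes = 3,
                         upstream_dyad_offset = -180, dyad_fuzz = 20,
                         frags_per_dyad = 30, frag_len_mean = 147,
                         frag_len_sd = 10, frag_len_range = c(120, 190),
                         upstream_nucleosome_loss = 0.4,
                         atac_nfr_per_gene = 25, atac_mono_per_gene = 25,
                         atac_nfr_gain = 1.5,
                         nfr_len_mean = 65, nfr_len_sd = 15,
                         nfr_len_range = c(30, 100),
                         n_reps = 4, count_meanlog = log(150),
                         count_sdlog = 1, dispersion = 0.1,
                         libsize_factors = NULL,
                         planted_overlaps = 0,
                         simulate_sequence = TRUE) {
  cfg <- as.list(environment())
  need <- c("up_bound", "up_unbound", "down_bound", "down_unbound",
            "unchanged_bound", "unchanged_unbound")
  if (!all(need %in% names(class_counts)))
    .stopf("class_counts must name all of: %s", paste(need, collapse = ", "))
  rates <- c(duplicate_rate, upstream_nucleosome_loss, gc_background,
             gc_promoter)
  if (any(rates < 0 | rates > 1)) .stopf("rates must lie in [0,1]")
  if (antisense_gain < 1) .stopf("antisense_gain must be >= 1")
  if (n_reps < 2) .stopf("n_reps must be >= 2")
  if (any(class_counts < 0)) .stopf("class_counts must be non-negative")
  cfg$n_genes <- sum(class_counts)
  class(cfg) <- "truth_config"
  cfg
}

#' Read / write a truth_config as YAML
#' @param path YAML file path.
#' @return \code{truth_config_from_yaml} returns a \code{truth_config}.
#' @export
truth_config_from_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  for (nm in c("class_counts", "logfc"))
    if (!is.null(x[[nm]])) x[[nm]] <- unlist(x[[nm]])
  do.call(truth_config, x[setdiff(names(x), "n_genes")])
}

#' @rdname truth_config_from_yaml
#' @param cfg a \code{truth_config}.
#' @export
write_truth_config_yaml <- function(cfg, path) {
  x <- unclass(cfg)
  x$n_genes <- NULL
  yaml::write_yaml(lapply(x, function(v) if (is.null(v)) NULL else v), path)
  invisible(path)
}

.class_levels <- c("up", "down", "unchanged")

#' Simulate a genome, gene set and ground-truth table
#'
#' Places non-overlapping genes along one synthetic chromosome with at least
#' \code{intergenic_gap} bp between spans (>= 2.5 kb upstream clearance by
#' construction), assigns classes at random positions, draws exon/intron
#' structure, and (optionally) samples a nucleotide sequence with elevated GC
#' around each TSS. The truth table records, per gene: class, bound flag,
#' planted logFC, per-condition antisense rates, and planted dyad positions
#' (upstream dyad as a column, full dyad list as the \code{"dyads"}
#' attribute). Fully deterministic given \code{cfg$seed}.
#'
#' @param cfg a \code{truth_config}.
#' @return list with elements \code{genome} (DNAStringSet or NULL),
#'   \code{genes} (\code{gene_models}), \code{truth} (data frame),
#'   \code{seqlens} (named vector).
#' @export
simulate_genome <- function(cfg) {
  .with_seed(stage_seed(cfg$seed, 1L), {
    n <- cfg$n_genes
    lens <- round(runif(n, cfg$gene_length_range[1], cfg$gene_length_range[2]))
    strands <- sample(c("+", "-"), n, replace = TRUE)
    victims <- if (cfg$planted_overlaps > 0) {
      cand <- which(strands == "+")
      if (length(cand) < cfg$planted_overlaps)
        .stopf("not enough + strand genes to plant %d overlaps",
               cfg$planted_overlaps)
      sort(sample(cand, cfg$planted_overlaps))
    } else integer(0)

    margin <- 3000
    cursor <- margin
    start <- numeric(n)
    decoy <- list()
    for (i in seq_len(n)) {
      if (i %in% victims) {
        # decoy needs its own 2.5-kb clearance on the left so that only the
        # victim fails the isolation filter
        cursor <- cursor + 2000
        decoy[[length(decoy) + 1]] <-
          c(start = cursor + 1000, end = cursor + 1800)
        start[i] <- cursor + 2500
      } else {
        start[i] <- cursor
      }
      cursor <- start[i] + lens[i] + cfg$intergenic_gap
    }
    total_len <- cursor - cfg$intergenic_gap + margin
    chrom_length <- if (is.null(cfg$chrom_length)) total_len else cfg$chrom_length
    if (total_len > chrom_length)
      .stopf("genes do not fit: need %d bp, chrom_length is %d",
             total_len, chrom_length)

    gene_id <- sprintf("g%04d", seq_len(n))
    end <- start + lens
    exons <- lapply(seq_len(n), function(i) {
      k <- cfg$exons_per_gene
      if (k <= 1) return(cbind(start = start[i], end = end[i]))
      nseg <- 2L * k - 1L
      w <- runif(nseg)
      minseg <- 100
      extra <- lens[i] - nseg * minseg
      if (extra < 0) return(cbind(start = start[i], end = end[i]))
      seg <- minseg + floor(extra * w / sum(w))
      seg[nseg] <- lens[i] - sum(seg[-nseg])
      b <- start[i] + cumsum(c(0, seg))
      idx <- seq(1, nseg, by = 2)
      cbind(start = b[idx], end = b[idx + 1])
    })
    names(exons) <- gene_id
    genes <- gene_models(gene_id, cfg$chrom, start, end, strands, exons)

    if (length(decoy)) {
      dstart <- vapply(decoy, `[[`, 0, "start")
      dend <- vapply(decoy, `[[`, 0, "end")
      did <- sprintf("decoy%02d", seq_along(decoy))
      dg <- gene_models(did, cfg$chrom, dstart, dend, rep("+", length(decoy)))
      genes <- .rbind_gene_models(genes, dg)
    }

    cls <- rep(names(cfg$class_counts), cfg$class_counts)
    cls <- sample(cls)  # decouple class from genomic position
    expr_class <- sub("_(un)?bound$", "", cls)
    bound <- grepl("_bound$", cls)
    anti_ctrl <- rep(cfg$antisense_rate, n)
    anti_kd <- ifelse(bound & expr_class == "up",
                      cfg$antisense_rate * cfg$antisense_gain,
                      cfg$antisense_rate)
    tssb <- tss_site(genes[seq_len(n), ])$pos
    dir <- ifelse(strands == "+", 1, -1)
    up_dyad <- tssb + dir * cfg$upstream_dyad_offset
    dyads <- lapply(seq_len(n), function(i) {
      down <- tssb[i] + dir[i] * (cfg$first_dyad_offset +
        cfg$nucleosome_spacing * (seq_len(cfg$n_downstream_nucleosomes) - 1))
      list(upstream = up_dyad[i], downstream = down)
    })
    names(dyads) <- gene_id
    truth <- data.frame(gene_id = gene_id, class = expr_class, bound = bound,
                        logfc = unname(cfg$logfc[expr_class]),
                        antisense_rate_control = anti_ctrl,
                        antisense_rate_kd = anti_kd,
                        tss_base = tssb, upstream_dyad = up_dyad,
                        stringsAsFactors = FALSE)
    if (length(decoy)) {
      truth <- rbind(truth, data.frame(
        gene_id = sprintf("decoy%02d", seq_along(decoy)), class = "decoy",
        bound = FALSE, logfc = 0, antisense_rate_control = 0,
        antisense_rate_kd = 0, tss_base = NA_real_,
        upstream_dyad = NA_real_, stringsAsFactors = FALSE))
    }
    attr(truth, "dyads") <- dyads
    attr(truth, "planted_nonisolated") <- gene_id[victims]

    genome <- NULL
    if (isTRUE(cfg$simulate_sequence)) {
      base_probs <- function(gc) c(A = (1 - gc) / 2, C = gc / 2,
                                   G = gc / 2, T = (1 - gc) / 2)
      seq <- sample(names(base_probs(0)), chrom_length, replace = TRUE,
                    prob = base_probs(cfg$gc_background))
      for (i in seq_len(n)) {
        lo <- max(0, tssb[i] - cfg$promoter_gc_halfwidth)
        hi <- min(chrom_length, tssb[i] + cfg$promoter_gc_halfwidth)
        if (hi > lo)
          seq[(lo + 1):hi] <- sample(names(base_probs(0)), hi - lo,
                                     replace = TRUE,
                                     prob = base_probs(cfg$gc_promoter))
      }
      genome <- Biostrings::DNAStringSet(paste(seq, collapse = ""))
      names(genome) <- cfg$chrom
    }
    seqlens <- stats::setNames(chrom_length, cfg$chrom)
    list(genome = genome, genes = genes, truth = truth, seqlens = seqlens)
  })
}

.rbind_gene_models <- function(a, b) {
  ex <- c(gene_exons(a), gene_exons(b))
  df <- rbind(as.data.frame(a), as.data.frame(b))
  o <- order(df$chrom, df$start)
  df <- df[o, , drop = FALSE]
  attr(df, "exons") <- ex[df$gene_id]
  class(df) <- c("gene_models", "data.frame")
  rownames(df) <- NULL
  df
}

# strand-oriented last bases of each exon and intron of every gene
.splice_sites <- function(genes) {
  exons <- gene_exons(genes)
  pos_l <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    ex <- exons[[genes$gene_id[i]]]
    if (is.null(ex) || nrow(ex) == 0) next
    pos_l[[i]] <- if (genes$strand[i] == "+") {
      c(ex[, 2] - 1,
        if (nrow(ex) > 1) ex[-1, 1] - 1)        # intron last base
    } else {
      c(ex[, 1],
        if (nrow(ex) > 1) ex[-nrow(ex), 2])     # intron last base
    }
  }
  nsite <- lengths(pos_l)
  if (sum(nsite) == 0) return(NULL)
  idx <- rep.int(seq_len(nrow(genes)), nsite)
  data.frame(chrom = genes$chrom[idx], pos = unlist(pos_l),
             strand = genes$strand[idx], gene_id = genes$gene_id[idx],
             stringsAsFactors = FALSE)
}

#' Simulate strand-specific NET-seq tags
#'
#' Sense tags are drawn as a per-base Poisson rate over the gene span plus a
#' Gaussian promoter-proximal pause peak inside the first 250 bp downstream
#' of the TSS. Antisense tags are Poisson in the 1-kb upstream window on the
#' opposite strand, with the rate multiplied by \code{antisense_gain} for
#' bound up-regulated genes in the "kd" condition. Splicing-intermediate
#' tags are planted exactly at exon/intron 3'-end bases; genuine signal tags
#' that would coincide with such a base are dropped so the intermediate
#' filter is exactly testable. PCR duplicates are appended as copies with
#' identical (pos, strand, UMI). Every primary tag carries a unique UMI.
#'
#' @param genes \code{gene_models} from \code{simulate_genome}.
#' @param truth truth table from \code{simulate_genome}.
#' @param condition "control" or "kd".
#' @param cfg the \code{truth_config}.
#' @param seed optional integer; defaults to a condition-specific stream
#'   derived from \code{cfg$seed}.
#' @return data frame of tags: chrom, pos, strand, umi, plus ground-truth
#'   columns kind ("signal"/"intermediate"), duplicate (logical) and gene_id;
#'   attribute "condition".
#' @export
simulate_netseq <- function(genes, truth, condition = c("control", "kd"),
                            cfg, seed = NULL) {
  condition <- match.arg(condition)
  if (is.null(seed))
    seed <- stage_seed(cfg$seed, if (condition == "control") 2L else 3L)
  live <- truth$class != "decoy"
  g <- genes[match(truth$gene_id[live], genes$gene_id), , drop = FALSE]
  truth <- truth[live, , drop = FALSE]
  sites <- .splice_sites(genes)
  .with_seed(seed, {
    anti_rate <- if (condition == "kd") truth$antisense_rate_kd
                 else truth$antisense_rate_control
    n <- nrow(g)
    dir <- ifelse(g$strand == "+", 1, -1)
    b <- truth$tss_base
    len <- g$end - g$start
    opp <- ifelse(g$strand == "+", "-", "+")

    # sense body tags: uniform Poisson rate over the gene span
    n_body <- rpois(n, cfg$body_rate * len)
    ib <- rep.int(seq_len(n), n_body)
    body_pos <- g$start[ib] + floor(runif(length(ib)) * len[ib])
    # pause peak: Gaussian within the first 250 bp downstream of the TSS
    n_pause <- rpois(n, cfg$pause_tags)
    ip <- rep.int(seq_len(n), n_pause)
    pp <- round(rnorm(length(ip), b[ip] + dir[ip] * cfg$pause_center,
                      cfg$pause_sd))
    pp <- pmin(pmax(pp, pmin(b[ip], b[ip] + dir[ip] * 249)),
               pmax(b[ip], b[ip] + dir[ip] * 249))
    # antisense tags: uniform in the 1-kb upstream window, opposite strand
    n_anti <- rpois(n, anti_rate * 1000)
    ia <- rep.int(seq_len(n), n_anti)
    ant0 <- ifelse(g$strand == "+", g$tss - 1000, g$tss)
    anti_pos <- ant0[ia] + floor(runif(length(ia)) * 1000)

    pos <- c(body_pos, pp, anti_pos)
    idx <- c(ib, ip, ia)
    strand <- c(g$strand[ib], g$strand[ip], opp[ia])
    kind <- rep("signal", length(pos))

    if (cfg$splice_intermediate_tags > 0 && !is.null(sites)) {
      cnt <- rpois(nrow(sites), cfg$splice_intermediate_tags)
      ii <- rep.int(seq_len(nrow(sites)), cnt)
      pos <- c(pos, sites$pos[ii])
      idx <- c(idx, match(sites$gene_id[ii], g$gene_id))
      strand <- c(strand, sites$strand[ii])
      kind <- c(kind, rep("intermediate", length(ii)))
    }
    # keep planted intermediates the only tags at splice-site bases
    if (!is.null(sites)) {
      skey <- unique(sites$pos * 2 + (sites$strand == "+"))
      drop <- kind == "signal" & (pos * 2 + (strand == "+")) %in% skey
      pos <- pos[!drop]; idx <- idx[!drop]
      strand <- strand[!drop]; kind <- kind[!drop]
    }
    if (length(pos) == 0) .stopf("simulation produced no tags")
    tags <- data.frame(pos = pos, strand = strand, kind = kind,
                       gene_id = g$gene_id[idx], chrom = g$chrom[idx],
                       stringsAsFactors = FALSE)
    tags$umi <- sprintf("u%07d", seq_len(nrow(tags)))
    tags$duplicate <- FALSE
    if (cfg$duplicate_rate > 0) {
      dup <- tags[as.logical(rbinom(nrow(tags), 1, cfg$duplicate_rate)), ,
                  drop = FALSE]
      if (nrow(dup)) {
        dup$duplicate <- TRUE
        tags <- rbind(tags, dup)
      }
    }
    rownames(tags) <- NULL
    tags <- tags[, c("chrom", "pos", "strand", "umi", "kind", "duplicate",
                     "gene_id")]
    attr(tags, "condition") <- condition
    tags
  })
}

.clip_round <- function(x, lo, hi) pmin(pmax(round(x), lo), hi)

#' Simulate paired-end MNase or ATAC fragments
#'
#' MNase: fragment midpoints are drawn with Gaussian fuzz around phased
#' dyads (one upstream dyad plus \code{n_downstream_nucleosomes} downstream
#' dyads per gene); lengths are normal around 147 bp, clipped to the
#' configured range. The upstream dyad weight is multiplied by
#' \code{1 - upstream_nucleosome_loss} for bound up-regulated genes in the
#' "kd" condition. ATAC: a mixture of short nucleosome-free-region (NFR)
#' fragments centred between the upstream and +1 dyads and mononucleosome
#' fragments at the +1 dyad; the NFR rate is multiplied by
#' \code{atac_nfr_gain} for bound up-regulated genes in the knockdown.
#'
#' @inheritParams simulate_netseq
#' @param assay "mnase" or "atac".
#' @return a \code{fragment_set}: data frame chrom, start, end, length plus
#'   ground-truth columns origin and gene_id; attributes assay, condition.
#' @export
simulate_fragments <- function(genes, truth, condition = c("control", "kd"),
                               assay = c("mnase", "atac"), cfg, seed = NULL) {
  condition <- match.arg(condition); assay <- match.arg(assay)
  if (is.null(seed)) {
    k <- if (assay == "mnase") 4L else 6L
    seed <- stage_seed(cfg$seed, k + (condition == "kd"))
  }
  g <- genes[match(truth$gene_id, genes$gene_id), , drop = FALSE]
  dyads <- attr(truth, "dyads")
  .with_seed(seed, {
    parts <- vector("list", nrow(g))
    for (i in seq_len(nrow(g))) {
      if (truth$class[i] == "decoy") next
      affected <- truth$bound[i] && truth$class[i] == "up" && condition == "kd"
      dy <- dyads[[truth$gene_id[i]]]
      if (assay == "mnase") {
        up_w <- if (affected) 1 - cfg$upstream_nucleosome_loss else 1
        centers <- c(dy$upstream, dy$downstream)
        weights <- c(up_w, rep(1, length(dy$downstream)))
        origin <- c("dyad_up", paste0("dyad_down", seq_along(dy$downstream)))
        ns <- rpois(length(centers), cfg$frags_per_dyad * weights)
        mid <- round(rnorm(sum(ns), rep(centers, ns), cfg$dyad_fuzz))
        len <- .clip_round(rnorm(sum(ns), cfg$frag_len_mean, cfg$frag_len_sd),
                           cfg$frag_len_range[1], cfg$frag_len_range[2])
        org <- rep(origin, ns)
      } else {
        nfr_center <- (dy$upstream + dy$downstream[1]) / 2
        n_nfr <- rpois(1, cfg$atac_nfr_per_gene *
                         (if (affected) cfg$atac_nfr_gain else 1))
        n_mono <- rpois(1, cfg$atac_mono_per_gene)
        mid <- round(c(rnorm(n_nfr, nfr_center, 60),
                       rnorm(n_mono, dy$downstream[1], cfg$dyad_fuzz)))
        len <- c(.clip_round(rnorm(n_nfr, cfg$nfr_len_mean, cfg$nfr_len_sd),
                             cfg$nfr_len_range[1], cfg$nfr_len_range[2]),
                 .clip_round(rnorm(n_mono, cfg$frag_len_mean, cfg$frag_len_sd),
                             cfg$frag_len_range[1], cfg$frag_len_range[2]))
        org <- c(rep("nfr", n_nfr), rep("mono", n_mono))
      }
      if (!length(mid)) next
      st <- mid - floor(len / 2)
      parts[[i]] <- data.frame(chrom = g$chrom[i], start = st, end = st + len,
                               length = len, origin = org,
                               gene_id = g$gene_id[i], stringsAsFactors = FALSE)
    }
    fs <- do.call(rbind, parts)
    rownames(fs) <- NULL
    fragment_set(fs, assay = assay, condition = condition)
  })
}

#' Construct a fragment set
#' @param df data frame with chrom, start, end (0-based half-open) and
#'   optionally extra columns; length is (re)computed.
#' @param assay "mnase" or "atac".
#' @param condition free-text condition label.
#' @return a \code{fragment_set} data frame.
#' @export
fragment_set <- function(df, assay = c("mnase", "atac"), condition = "") {
  assay <- match.arg(assay)
  df$length <- df$end - df$start
  if (any(df$length < 1)) .stopf("fragments must have length >= 1")
  attr(df, "assay") <- assay
  attr(df, "condition") <- condition
  class(df) <- c("fragment_set", "data.frame")
  df
}

#' Simulate a two-condition RNA-seq count matrix
#'
#' Negative-binomial counts with gene-wise log-normal baseline means and a
#' fixed dispersion; the knockdown condition mean is the baseline multiplied
#' by 2^planted-logFC. Per-sample library scale factors are applied so TMM
#' normalisation has something to correct.
#'
#' @inheritParams simulate_netseq
#' @param n_reps replicates per condition (defaults to \code{cfg$n_reps}).
#' @return integer matrix genes x samples (control_* then kd_*) with the
#'   applied library factors in attribute "libsize_factors".
#' @export
simulate_counts <- function(genes, truth, cfg, n_reps = cfg$n_reps,
                            seed = NULL) {
  if (is.null(seed)) seed <- stage_seed(cfg$seed, 8L)
  keep <- truth$class != "decoy"
  truth <- truth[keep, , drop = FALSE]
  .with_seed(seed, {
    n <- nrow(truth)
    mu0 <- rlnorm(n, cfg$count_meanlog, cfg$count_sdlog)
    facs <- cfg$libsize_factors
    if (is.null(facs)) facs <- rep(1, 2 * n_reps)
    if (length(facs) != 2 * n_reps)
      .stopf("libsize_factors must have length 2 * n_reps")
    mu <- cbind(matrix(mu0, n, n_reps),
                matrix(mu0 * 2^truth$logfc, n, n_reps))
    mu <- sweep(mu, 2, facs, `*`)
    counts <- matrix(rnbinom(n * 2 * n_reps, mu = mu, size = 1 / cfg$dispersion),
                     n, 2 * n_reps)
    dimnames(counts) <- list(truth$gene_id,
                             c(paste0("control_", seq_len(n_reps)),
                               paste0("kd_", seq_len(n_reps))))
    attr(counts, "libsize_factors") <- facs
    counts
  })
}

#' Tag and fragment TSV/BED writers and readers
#'
#' \code{write_tags_bed} writes NET-seq tags as BED6 (name = UMI, 1-bp
#' intervals); \code{write_fragments_tsv} writes fragments as a 4-column TSV;
#' \code{write_counts_tsv} / \code{read_counts_tsv} round-trip a count
#' matrix with a gene_id first column. All writers gzip when the path ends
#' in ".gz".
#'
#' @param tags,fs,counts objects to write.
#' @param path file path.
#' @name sim_io
NULL

.open_w <- function(path) if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")

#' @rdname sim_io
#' @export
write_tags_bed <- function(tags, path) {
  df <- data.frame(tags$chrom, format(tags$pos, scientific = FALSE, trim = TRUE),
                   format(tags$pos + 1, scientific = FALSE, trim = TRUE),
                   tags$umi, 0L, tags$strand)
  con <- .open_w(path); on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname sim_io
#' @export
read_tags_bed <- function(path) {
  lines <- .read_lines_checked(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 6)
  if (length(bad)) .stopf("malformed BED line %d", bad[1])
  strand <- vapply(fields, `[[`, "", 6)
  bads <- which(!strand %in% c("+", "-"))
  if (length(bads)) .stopf("unknown strand character on line %d", bads[1])
  data.frame(chrom = vapply(fields, `[[`, "", 1),
             pos = as.numeric(vapply(fields, `[[`, "", 2)),
             strand = strand, umi = vapply(fields, `[[`, "", 4),
             stringsAsFactors = FALSE)
}

#' @rdname sim_io
#' @export
write_fragments_tsv <- function(fs, path) {
  con <- .open_w(path); on.exit(close(con))
  write.table(data.frame(chrom = fs$chrom, start = fs$start, end = fs$end,
                         length = fs$length),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname sim_io
#' @param assay,condition labels for the reconstructed fragment set.
#' @export
read_fragments_tsv <- function(path, assay = "mnase", condition = "") {
  df <- read.delim(path, stringsAsFactors = FALSE)
  fragment_set(df[, c("chrom", "start", "end")], assay = assay,
               condition = condition)
}

#' @rdname sim_io
#' @export
write_counts_tsv <- function(counts, path) {
  con <- .open_w(path); on.exit(close(con))
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname sim_io
#' @export
read_counts_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
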