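#' Configure an end-to-end synthetic pipeline run
#'
#' Bundles the synthetic-data configuration with the analysis parameters so
#' that one object fully determines a run. Every parameter is echoed into
#' the run manifest.
#'
#' @param truth a \code{\link{truth_config}}.
#' @param seed master seed for the run; overrides \code{truth$seed} so that
#'   one integer reproduces everything.
#' @param upstream_margin promoter-isolation clearance in bp.
#' @param antisense_window antisense window width in bp.
#' @param antisense_pseudocount density pseudocount (tags/bp) for antisense
#'   fold changes.
#' @param occupancy_halfwidth half-width in bp of the window around the
#'   planted upstream dyad over which nucleosome occupancy is averaged.
#' @param occupancy_pseudocount pseudocount on normalised occupancy density.
#' @param smooth_window MNase track smoothing window in bp.
#' @param run_atac also simulate and analyse ATAC accessibility.
#' @param keep_tracks retain the normalised signal tracks in the result.
#' @param outdir optional directory; when given, per-gene tables and the run
#'   manifest are written as TSV/JSON.
#' @return a \code{run_config} list.
#' @export
run_config <- function(truth = truth_config(), seed = truth$seed,
                       upstream_margin = 2500, antisense_window = 1000,
                       antisense_pseudocount = 1e-4,
                       occupancy_halfwidth = 50,
                       occupancy_pseudocount = 0.01,
                       smooth_window = 20, run_atac = TRUE,
                       keep_tracks = FALSE, outdir = NULL) {
  cfg <- as.list(environment())
  cfg$truth$seed <- seed
  class(cfg) <- "run_config"
  cfg
}

.welch_contrast <- function(metric, truth_cls, bound, classes) {
  rows <- lapply(classes, function(cl) {
    a <- metric[truth_cls == cl & bound]
    b <- metric[truth_cls == cl & !bound]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) < 2 || length(b) < 2)
      return(data.frame(class = cl, n_bound = length(a),
                        n_unbound = length(b), t = NA_real_, p = NA_real_))
    w <- welch_t(a, b)
    data.frame(class = cl, n_bound = length(a), n_unbound = length(b),
               t = w$t, p = w$p)
  })
  do.call(rbind, rows)
}

#' Run the full synthetic multi-assay pipeline
#'
#' Executes simulate → clean → coverage → metrics → stats on one seeded
#' synthetic experiment: genome and truth table; NET-seq tag simulation,
#' deduplication, splicing-intermediate removal, strand-split 1x-normalised
#' tracks; travelling ratios; antisense quantification with knockdown/control
#' fold changes; MNase mononucleosome occupancy at the planted upstream
#' dyad (smoothed, 1x-normalised) with its fold change; optional ATAC NFR
#' accessibility at the promoter; RNA-seq DE calling and gene
#' classification; Welch contrasts of bound versus unbound genes within each
#' ground-truth expression class for the antisense and occupancy fold
#' changes; and a slope comparison (z) of the log nascent-coverage versus
#' log expression regressions of bound and unbound genes. Identical
#' config + seed gives identical output.
#'
#' @param cfg a \code{\link{run_config}}.
#' @return a list of result tables (see details in the vignette) plus a
#'   \code{manifest} recording parameters, seeds and filter counts.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  tc <- cfg$truth
  sim <- simulate_genome(tc)
  genes_iso <- filter_isolated_promoters(sim$genes, cfg$upstream_margin)
  truth <- sim$truth
  keep_ids <- intersect(genes_iso$gene_id,
                        truth$gene_id[truth$class != "decoy"])
  genes <- genes_iso[match(keep_ids, genes_iso$gene_id), , drop = FALSE]
  attr(genes, "exons") <- gene_exons(genes_iso)[keep_ids]
  class(genes) <- c("gene_models", "data.frame")
  tru <- truth[match(keep_ids, truth$gene_id), , drop = FALSE]
  seqlens <- sim$seqlens
  counts_log <- list(n_genes = nrow(sim$genes),
                     n_isolated = nrow(genes))

  ## NET-seq per condition: clean tags, stranded 1x tracks
  net <- list()
  for (cond in c("control", "kd")) {
    tags <- simulate_netseq(sim$genes, truth, cond, tc)
    dd <- dedup_tags(tags)
    spl <- remove_splicing_intermediates(dd, sim$genes)
    counts_log[[paste0("netseq_", cond)]] <-
      list(raw = nrow(tags), duplicates_removed = attr(dd, "n_removed"),
           intermediates_removed = nrow(spl$removed),
           clean = nrow(spl$kept))
    trk <- build_track(spl$kept, seqlens)
    net[[cond]] <- list(plus = normalize_rpgc(trk$plus),
                        minus = normalize_rpgc(trk$minus))
  }

  tr_control <- travelling_ratio(net$control, genes)
  tr_kd <- travelling_ratio(net$kd, genes)
  anchors <- tss_site(genes)
  profiles <- list(
    sense_control = metaprofile(net$control, anchors, flank = 1000),
    sense_kd = metaprofile(net$kd, anchors, flank = 1000),
    antisense_control = metaprofile(net$control, anchors, flank = 1000,
                                    anti_strand = TRUE),
    antisense_kd = metaprofile(net$kd, anchors, flank = 1000,
                               anti_strand = TRUE))
  antisense <- antisense_quant(net$control, net$kd, genes,
                               window = cfg$antisense_window,
                               pseudocount = cfg$antisense_pseudocount)

  ## MNase mononucleosome occupancy at the planted upstream dyad
  occ <- list()
  mnase_tracks <- list()
  for (cond in c("control", "kd")) {
    fr <- simulate_fragments(sim$genes, truth, cond, "mnase", tc)
    mono <- partition_fragments(fr)$mononucleosome
    counts_log[[paste0("mnase_", cond)]] <-
      list(fragments = nrow(fr), mononucleosome = nrow(mono),
           dropped = attr(partition_fragments(fr), "n_dropped"))
    trk <- smooth_track(build_track(mono, seqlens), cfg$smooth_window)
    trk <- normalize_rpgc(trk)
    occ[[cond]] <- region_sum(trk, genes$chrom,
                              tru$upstream_dyad - cfg$occupancy_halfwidth,
                              tru$upstream_dyad + cfg$occupancy_halfwidth) /
      (2 * cfg$occupancy_halfwidth)
    if (cfg$keep_tracks) mnase_tracks[[cond]] <- trk
  }
  eps <- cfg$occupancy_pseudocount
  occupancy <- data.frame(gene_id = genes$gene_id,
                          occupancy_control = occ$control,
                          occupancy_kd = occ$kd,
                          log2_fold_change = log2((occ$kd + eps) /
                                                    (occ$control + eps)),
                          stringsAsFactors = FALSE)

  ## ATAC NFR accessibility at the promoter (optional)
  accessibility <- NULL
  if (isTRUE(cfg$run_atac)) {
    acc <- list()
    for (cond in c("control", "kd")) {
      fr <- simulate_fragments(sim$genes, truth, cond, "atac", tc)
      nfr <- select_atac_nfr(fr)
      counts_log[[paste0("atac_", cond)]] <-
        list(fragments = nrow(fr), nfr = nrow(nfr),
             duplicates_removed = attr(nfr, "n_duplicates"))
      trk <- normalize_rpgc(build_track(nfr, seqlens))
      plus <- genes$strand == "+"
      ws <- ifelse(plus, genes$tss - 250, genes$tss - 100)
      we <- ifelse(plus, genes$tss + 100, genes$tss + 250)
      acc[[cond]] <- region_sum(trk, genes$chrom, ws, we) / (we - ws)
    }
    accessibility <- data.frame(
      gene_id = genes$gene_id,
      accessibility_control = acc$control,
      accessibility_kd = acc$kd,
      log2_fold_change = log2((acc$kd + eps) / (acc$control + eps)),
      stringsAsFactors = FALSE)
  }

  ## RNA-seq counts, DE call, classification
  counts <- simulate_counts(sim$genes, truth, tc)
  design <- factor(sub("_[0-9]+$", "", colnames(counts)),
                   levels = c("control", "kd"))
  de <- de_call(counts, design)
  names(de)[names(de) == "adj_p"] <- "adj_p"
  bound_ids <- truth$gene_id[truth$bound %in% TRUE]
  classes <- suppressWarnings(classify_genes(de, bound_ids))

  ## ground-truth-stratified Welch contrasts (bound vs unbound per class)
  cls_levels <- c("up", "down", "unchanged")
  contrasts <- rbind(
    cbind(metric = "antisense_log2fc",
          .welch_contrast(antisense$log2_fold_change, tru$class, tru$bound,
                          cls_levels)),
    cbind(metric = "occupancy_log2fc",
          .welch_contrast(occupancy$log2_fold_change, tru$class, tru$bound,
                          cls_levels)))
  if (!is.null(accessibility))
    contrasts <- rbind(contrasts,
      cbind(metric = "accessibility_log2fc",
            .welch_contrast(accessibility$log2_fold_change, tru$class,
                            tru$bound, cls_levels)))

  ## slope comparison: log gene-body nascent coverage vs log expression
  expr <- expression_summary(counts[genes$gene_id,
                                    design == "control", drop = FALSE],
                             genes$end - genes$start)
  body_density <- tr_control$body_density
  slopes <- NULL
  sel_b <- tru$bound & tr_control$usable
  sel_u <- !tru$bound & tr_control$usable
  if (sum(sel_b) >= 3 && sum(sel_u) >= 3) {
    fit_b <- loglog_fit(expr$cpm[sel_b], body_density[sel_b])
    fit_u <- loglog_fit(expr$cpm[sel_u], body_density[sel_u])
    slopes <- slope_z(fit_b, fit_u)
  }

  manifest <- list(package_version = as.character(utils::packageVersion("promarch")),
                   seed = cfg$seed,
                   parameters = .manifest_params(cfg),
                   filter_counts = counts_log)
  res <- list(genes = genes, truth = tru,
              travelling_ratio_control = tr_control,
              travelling_ratio_kd = tr_kd,
              profiles = profiles,
              antisense = antisense, occupancy = occupancy,
              accessibility = accessibility,
              de = de, classes = classes, contrasts = contrasts,
              slopes = slopes, manifest = manifest)
  if (cfg$keep_tracks) {
    res$net_tracks <- net
    res$mnase_tracks <- mnase_tracks
  }
  if (!is.null(cfg$outdir)) .write_bundle(res, cfg$outdir)
  res
}

.manifest_params <- function(cfg) {
  p <- unclass(cfg)
  p$truth <- unclass(p$truth)
  p$outdir <- NULL
  rapply(p, function(v) if (is.null(v)) "null" else v, how = "replace")
}

.write_bundle <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name)
    write.table(df, file.path(outdir, paste0(name, ".tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
  wt(res$travelling_ratio_control, "travelling_ratio_control")
  wt(res$travelling_ratio_kd, "travelling_ratio_kd")
  for (nm in names(res$profiles))
    wt(res$profiles[[nm]], paste0("profile_", nm))
  wt(res$antisense, "antisense")
  wt(res$occupancy, "occupancy")
  if (!is.null(res$accessibility)) wt(res$accessibility, "accessibility")
  wt(res$de, "de")
  wt(res$classes, "classes")
  wt(res$contrasts, "contrasts")
  jsonlite::write_json(res$manifest,
                       file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
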