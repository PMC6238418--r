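#' Travelling ratio of RNA polymerase II
#'
#' The travelling ratio is the sense-strand nascent-transcription tag density
#' of the proximal promoter (−30 to +250 bp around the TSS) divided by the
#' density of the gene body (+300 bp downstream of the TSS to −200 bp
#' upstream of the TES). High values indicate promoter-proximal pausing.
#' Densities are summed signal / region length, so the ratio is invariant to
#' any per-sample scaling. Genes too short for the body offsets or with zero
#' body density are flagged unusable (excluded from boxplots downstream).
#' Log transformation is left to callers.
#'
#' @param tracks a plus/minus \code{tag_track} pair (NET-seq sense signal is
#'   read from each gene's own strand).
#' @param genes a \code{gene_models} object (pre-filtered for promoter
#'   isolation).
#' @param ... window parameters passed to \code{\link{derive_region}}.
#' @return data frame gene_id, proximal_density, body_density, tr, usable.
#' @export
travelling_ratio <- function(tracks, genes, ...) {
  prox <- derive_region(genes, "proximal_promoter", ...)
  body <- derive_region(genes, "gene_body", ...)
  sense <- function(reg) {
    vapply(seq_len(nrow(reg)), function(i) {
      tr <- if (genes$strand[i] == "+") tracks$plus else tracks$minus
      region_sum(tr, reg$chrom[i], reg$start[i], reg$end[i])
    }, 0)
  }
  psum <- sense(prox); bsum <- sense(body)
  pd <- psum / (prox$end - prox$start)
  bd <- bsum / (body$end - body$start)
  usable <- body$usable & !is.na(bd) & bd > 0
  data.frame(gene_id = genes$gene_id, proximal_density = pd,
             body_density = bd,
             tr = ifelse(usable, pd / bd, NA_real_),
             usable = usable, stringsAsFactors = FALSE)
}

#' Antisense transcription in the 1-kb window upstream of the TSS
#'
#' Divergent (antisense) transcription is quantified as opposite-strand tag
#' density over the 1,000 bp immediately upstream of each TSS, per
#' condition, with the knockdown-versus-control log2 fold change computed on
#' pseudocounted densities. The default pseudocount is 0.1 tags/kb
#' (1e-4 tags/bp).
#'
#' @param tracks_control,tracks_kd plus/minus track pairs per condition.
#' @param genes a \code{gene_models} object (isolation-filtered).
#' @param window antisense window width in bp.
#' @param pseudocount density pseudocount in tags/bp.
#' @param ... further window parameters for \code{\link{derive_region}}.
#' @return data frame per gene with sense/antisense densities per condition
#'   and log2_fold_change (kd vs control).
#' @export
antisense_quant <- function(tracks_control, tracks_kd, genes, window = 1000,
                            pseudocount = 1e-4, ...) {
  reg <- derive_region(genes, "antisense_window", antisense_width = window, ...)
  dens <- function(tracks, opposite) {
    vapply(seq_len(nrow(reg)), function(i) {
      plus_gene <- genes$strand[i] == "+"
      tr <- if (plus_gene != opposite) tracks$plus else tracks$minus
      region_sum(tr, reg$chrom[i], reg$start[i], reg$end[i])
    }, 0) / (reg$end - reg$start)
  }
  anti_c <- dens(tracks_control, TRUE)
  anti_k <- dens(tracks_kd, TRUE)
  sense_c <- dens(tracks_control, FALSE)
  sense_k <- dens(tracks_kd, FALSE)
  data.frame(gene_id = genes$gene_id,
             antisense_density_control = anti_c,
             antisense_density_kd = anti_k,
             sense_density_control = sense_c,
             sense_density_kd = sense_k,
             log2_fold_change = log2((anti_k + pseudocount) /
                                       (anti_c + pseudocount)),
             stringsAsFactors = FALSE)
}

#' Per-gene expression summaries and RPKM quantile classes
#'
#' CPM and RPKM are computed per sample and averaged across the supplied
#' samples; genes are then split into four equal-count classes (high,
#' medium, low, very_low) by RPKM quartile. Ties are broken by stable rank
#' (first occurrence wins) so the classes always partition the genes into
#' four groups of equal size (±1).
#'
#' @param counts integer matrix (genes x samples) or vector.
#' @param gene_lengths per-gene lengths in bp (> 0), aligned with rows.
#' @return data frame gene_id, cpm, rpkm, quantile_class.
#' @export
expression_summary <- function(counts, gene_lengths) {
  if (is.null(dim(counts))) counts <- matrix(counts, ncol = 1,
                                             dimnames = list(names(counts), "s1"))
  if (any(gene_lengths <= 0)) .stopf("gene lengths must be > 0")
  lib <- colSums(counts)
  if (any(lib == 0)) .stopf("zero library size in column %s",
                            colnames(counts)[which(lib == 0)[1]])
  cpm <- rowMeans(sweep(counts, 2, lib, `/`) * 1e6)
  rpkm <- cpm * 1e3 / gene_lengths
  rk <- rank(rpkm, ties.method = "first")
  q <- ceiling(rk * 4 / length(rk))
  cls <- c("very_low", "low", "medium", "high")[q]
  data.frame(gene_id = rownames(counts) %||% as.character(seq_along(cpm)),
             cpm = cpm, rpkm = rpkm,
             quantile_class = factor(cls, levels = c("high", "medium", "low",
                                                     "very_low")),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Region-by-track density matrix and co-occupancy correlation
#'
#' Computes the mean signal of every track over every region (for example,
#' factor occupancies over gene bodies) and the pairwise Pearson correlation
#' of the (optionally log-transformed) columns. Zero-variance columns yield
#' NA correlations for their pairs.
#'
#' @param tracks named list of unstranded \code{tag_track}s.
#' @param regions data frame with chrom, start, end (>= 3 rows).
#' @param log_transform correlate log2(density + pseudocount) columns.
#' @param pseudocount added before the log.
#' @return list with \code{matrix} (region x track mean densities) and
#'   \code{cor} (track x track Pearson r).
#' @export
region_density_matrix <- function(tracks, regions, log_transform = TRUE,
                                  pseudocount = 0.01) {
  if (nrow(regions) < 3) .stopf("need at least 3 regions")
  m <- vapply(tracks, function(tr)
    region_sum(tr, regions$chrom, regions$start, regions$end) /
      (regions$end - regions$start), numeric(nrow(regions)))
  x <- if (log_transform) log2(m + pseudocount) else m
  sds <- apply(x, 2, sd)
  r <- suppressWarnings(cor(x, use = "pairwise.complete.obs"))
  r[sds == 0, ] <- NA_real_
  r[, sds == 0] <- NA_real_
  diag(r) <- ifelse(sds == 0, NA_real_, 1)
  list(matrix = m, cor = r)
}

#' Classify genes by differential-expression call and factor binding
#'
#' Applies the standard thresholds: "up" when logFC > 1 and adjusted
#' p < 0.01; "down" when logFC < −1 and adjusted p < 0.01; "unchanged" when
#' adjusted p > 0.05; everything else "other". The bound flag is joined from
#' the supplied target list; bound identifiers absent from the table are
#' dropped with a warning.
#'
#' @param de data frame with gene_id, logfc, adj_p (e.g. from
#'   \code{\link{de_call}}).
#' @param bound_ids character vector of factor-bound gene identifiers.
#' @param lfc_threshold,alpha_de,alpha_unchanged thresholds as above.
#' @return data frame gene_id, de_class, bound, label (class x binding).
#' @export
classify_genes <- function(de, bound_ids, lfc_threshold = 1,
                           alpha_de = 0.01, alpha_unchanged = 0.05) {
  missing <- setdiff(bound_ids, de$gene_id)
  if (length(missing))
    .warnf("%d bound gene id(s) absent from the DE table; dropped",
           length(missing))
  sig <- de$adj_p < alpha_de
  cls <- ifelse(sig & de$logfc > lfc_threshold, "up",
         ifelse(sig & de$logfc < -lfc_threshold, "down",
         ifelse(de$adj_p > alpha_unchanged, "unchanged", "other")))
  bound <- de$gene_id %in% bound_ids
  data.frame(gene_id = de$gene_id,
             de_class = factor(cls, levels = c("up", "down", "unchanged",
                                               "other")),
             bound = bound,
             label = paste0(cls, ifelse(bound, "_bound", "_unbound")),
             stringsAsFactors = FALSE)
}

#' Remove anchors dominated by a sub-window spike
#'
#' Promoter-anchored nascent-transcription matrices are contaminated by
#' short non-annotated RNAs (e.g. snoRNAs) that concentrate nearly all of a
#' row's signal in a small interval. A row is removed iff its total is
#' positive and the maximum signal inside any sliding sub-window of
#' \code{subwindow} bp reaches \code{frac_threshold} of the row total. This
#' is a deterministic, seed-free surrogate for cluster-based row filtering.
#'
#' @param anchor_mat matrix from \code{\link{anchor_matrix}} (rows =
#'   anchors, columns = 1-bp offsets).
#' @param subwindow sliding window width in bp.
#' @param frac_threshold fraction of row total (default 0.8).
#' @return the retained matrix; removed row names/indices in attribute
#'   \code{"removed"}.
#' @export
spike_filter <- function(anchor_mat, subwindow = 100, frac_threshold = 0.8) {
  n <- ncol(anchor_mat)
  w <- min(subwindow, n)
  keep <- vapply(seq_len(nrow(anchor_mat)), function(i) {
    v <- anchor_mat[i, ]
    tot <- sum(v)
    if (tot <= 0) return(TRUE)
    cs <- c(0, cumsum(v))
    win <- cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]
    max(win) < frac_threshold * tot
  }, TRUE)
  out <- anchor_mat[keep, , drop = FALSE]
  attr(out, "removed") <- if (!is.null(rownames(anchor_mat)))
    rownames(anchor_mat)[!keep] else which(!keep)
  out
}
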