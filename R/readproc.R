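#' Remove PCR duplicates from NET-seq tags
#'
#' Keeps exactly one tag per (chrom, pos, strand, umi) key — the UMI-aware
#' positional definition of a PCR/RT duplicate. Output is stably ordered by
#' coordinate (chrom, pos, strand, umi). Idempotent.
#'
#' @param tags data frame with chrom, pos, strand, umi (extra columns pass
#'   through from the first occurrence of each key).
#' @return deduplicated tags; the number removed is attached as attribute
#'   \code{"n_removed"}.
#' @export
dedup_tags <- function(tags) {
  if (nrow(tags) == 0) {
    attr(tags, "n_removed") <- 0L
    return(tags)
  }
  o <- order(tags$chrom, tags$pos, tags$strand, tags$umi, method = "radix")
  out <- tags[o, , drop = FALSE]
  n <- nrow(out)
  dup <- c(FALSE, out$chrom[-1] == out$chrom[-n] & out$pos[-1] == out$pos[-n] &
             out$strand[-1] == out$strand[-n] & out$umi[-1] == out$umi[-n])
  out <- out[!dup, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- nrow(tags) - nrow(out)
  out
}

#' Remove splicing-intermediate tags
#'
#' NET-seq co-purifies splicing intermediates: RNAs whose 3' end sits exactly
#' at the last transcribed base of an exon or intron. A tag is removed iff
#' its position equals the strand-oriented last base of any exon or intron of
#' a gene on the same strand and chromosome. Genes without exon structure
#' contribute no removal sites.
#'
#' @param tags data frame with chrom, pos, strand.
#' @param genes a \code{gene_models} object carrying exon structure.
#' @return list with elements \code{kept} and \code{removed}; their union is
#'   the input.
#' @export
remove_splicing_intermediates <- function(tags, genes) {
  sites <- .splice_sites(genes)
  if (is.null(sites) || nrow(sites) == 0)
    return(list(kept = tags, removed = tags[0, , drop = FALSE]))
  chroms <- unique(c(tags$chrom, sites$chrom))
  enc <- function(chrom, pos, strand)
    (match(chrom, chroms) - 1) * 2^34 + pos * 2 + (strand == "+")
  hit <- enc(tags$chrom, tags$pos, tags$strand) %in%
    enc(sites$chrom, sites$pos, sites$strand)
  list(kept = tags[!hit, , drop = FALSE],
       removed = tags[hit, , drop = FALSE])
}

#' Partition fragments into length classes
#'
#' The canonical MNase classes are subnucleosomal transcription-factor-sized
#' fragments (< 80 bp, strict) and mononucleosome fragments (135–170 bp,
#' inclusive at both ends). Classes must be disjoint; fragments matching no
#' class are dropped and their count recorded.
#'
#' @param fs a \code{fragment_set}.
#' @param classes named list of inclusive length bounds \code{c(lo, hi)}.
#'   The default encodes "< 80" as \code{c(1, 79)}.
#' @return named list of \code{fragment_set}s, one per class, with attribute
#'   \code{"n_dropped"}.
#' @export
partition_fragments <- function(fs,
                                classes = list(subnucleosomal = c(1, 79),
                                               mononucleosome = c(135, 170))) {
  b <- do.call(rbind, classes)
  if (any(b[, 1] > b[, 2])) .stopf("class bounds must satisfy lo <= hi")
  if (nrow(b) > 1) {
    o <- order(b[, 1])
    if (any(b[o, 1][-1] <= b[o, 2][-nrow(b)]))
      .stopf("fragment length classes overlap")
  }
  out <- lapply(names(classes), function(nm) {
    lo <- classes[[nm]][1]; hi <- classes[[nm]][2]
    sub <- fs[fs$length >= lo & fs$length <= hi, , drop = FALSE]
    attr(sub, "assay") <- attr(fs, "assay")
    attr(sub, "condition") <- attr(fs, "condition")
    class(sub) <- class(fs)
    sub
  })
  names(out) <- names(classes)
  attr(out, "n_dropped") <- nrow(fs) - sum(vapply(out, nrow, 0L))
  out
}

#' Select nucleosome-free-region (NFR) fragments from ATAC-seq
#'
#' Duplicated fragments (identical chrom/start/end) are removed first, then
#' fragments with length <= \code{max_len} are retained. This fragment-length
#' rule is this package's deterministic NFR definition for ATAC libraries,
#' where sub-nucleosomal fragment length is the standard proxy for
#' transposition inside a nucleosome-free region.
#'
#' @param fs a \code{fragment_set} with assay "atac".
#' @param max_len maximum NFR fragment length in bp (default 100).
#' @return the retained \code{fragment_set}; attributes
#'   \code{"n_duplicates"} and \code{"n_long"} record the removals.
#' @export
select_atac_nfr <- function(fs, max_len = 100) {
  if (!identical(attr(fs, "assay"), "atac"))
    .stopf("select_atac_nfr expects an ATAC fragment set")
  key <- paste(fs$chrom, fs$start, fs$end)
  dedup <- fs[!duplicated(key), , drop = FALSE]
  keep <- dedup$length <= max_len
  out <- dedup[keep, , drop = FALSE]
  attr(out, "assay") <- "atac"
  attr(out, "condition") <- attr(fs, "condition")
  attr(out, "n_duplicates") <- nrow(fs) - nrow(dedup)
  attr(out, "n_long") <- sum(!keep)
  class(out) <- class(fs)
  out
}
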