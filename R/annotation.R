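#' Construct a set of gene models
#'
#' A gene model records the genomic span and exon structure of one transcript
#' unit. Internally every coordinate is 0-based, half-open (BED convention).
#' The transcription start/end sites are stored as half-open boundary
#' coordinates: on the + strand \code{tss = start} and \code{tes = end}; on
#' the − strand \code{tss = end} and \code{tes = start} (the TSS base itself
#' is \code{tss - 1} for − strand genes).
#'
#' @param gene_id character vector of unique identifiers.
#' @param chrom chromosome names.
#' @param start,end 0-based half-open genomic span (start < end).
#' @param strand "+" or "-".
#' @param exons optional named list (by gene_id) of two-column matrices of
#'   0-based half-open exon intervals, sorted and non-overlapping, contained
#'   in the gene span. When omitted each gene becomes a single-exon model
#'   spanning its whole record.
#' @return A \code{gene_models} data frame with columns gene_id, chrom,
#'   start, end, strand, tss, tes, and the exon list stored as the
#'   \code{"exons"} attribute.
#' @export
gene_models <- function(gene_id, chrom, start, end, strand, exons = NULL) {
  start <- as.numeric(start); end <- as.numeric(end)
  gene_id <- as.character(gene_id); chrom <- as.character(chrom)
  strand <- as.character(strand)
  if (anyDuplicated(gene_id)) .stopf("duplicated gene_id values")
  if (!all(strand %in% c("+", "-")))
    .stopf("unknown strand character: %s",
           paste(unique(setdiff(strand, c("+", "-"))), collapse = ","))
  if (any(start >= end)) .stopf("gene span must satisfy start < end")
  if (is.null(exons)) {
    exons <- lapply(seq_along(gene_id), function(i) cbind(start = start[i], end = end[i]))
    names(exons) <- gene_id
  }
  if (!all(gene_id %in% names(exons))) .stopf("exons list missing some gene_id entries")
  exons <- exons[gene_id]
  for (i in seq_along(gene_id)) {
    ex <- exons[[i]]
    if (nrow(ex) == 0) next
    if (is.unsorted(ex[, 1]) || any(ex[, 2] <= ex[, 1]) ||
        (nrow(ex) > 1 && any(ex[-1, 1] < ex[-nrow(ex), 2])))
      .stopf("exons of gene %s are not sorted non-overlapping intervals", gene_id[i])
    if (ex[1, 1] < start[i] || ex[nrow(ex), 2] > end[i])
      .stopf("exons of gene %s extend beyond the gene span", gene_id[i])
  }
  g <- data.frame(gene_id = gene_id, chrom = chrom, start = start, end = end,
                  strand = strand, stringsAsFactors = FALSE)
  g$tss <- ifelse(strand == "+", start, end)
  g$tes <- ifelse(strand == "+", end, start)
  attr(g, "exons") <- exons
  class(g) <- c("gene_models", "data.frame")
  g
}

#' Exon list of a gene model set
#' @param genes a \code{gene_models} object.
#' @return Named list of two-column exon matrices.
#' @export
gene_exons <- function(genes) attr(genes, "exons")

#' TSS base position of each gene
#'
#' Returns the 0-based position of the first transcribed base (the anchor
#' used for TSS-centred metaprofiles): \code{start} for + strand genes and
#' \code{end - 1} for − strand genes.
#'
#' @param genes a \code{gene_models} object.
#' @return data frame with chrom, pos, strand, gene_id.
#' @export
tss_site <- function(genes) {
  data.frame(chrom = genes$chrom,
             pos = ifelse(genes$strand == "+", genes$tss, genes$tss - 1),
             strand = genes$strand, gene_id = genes$gene_id,
             stringsAsFactors = FALSE)
}

.read_lines_checked <- function(path) {
  x <- readLines(path)
  x[nzchar(trimws(x)) & !startsWith(x, "#") & !startsWith(x, "track") &
      !startsWith(x, "browser")]
}

#' Read gene annotation from BED or GTF
#'
#' BED6 records become single-exon gene models; BED12 block structure is used
#' as the exon structure; GTF (Ensembl dialect, 1-based closed coordinates)
#' is read through \pkg{rtracklayer} and exon features are grouped by
#' transcript (falling back to gene_id). All coordinates are converted to
#' 0-based half-open at the boundary.
#'
#' @param path file path (plain or gzipped for BED).
#' @param format "auto" (by extension), "bed" or "gtf".
#' @return A \code{gene_models} object.
#' @export
read_annotation <- function(path, format = c("auto", "bed", "gtf")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- if (ext %in% c("gtf", "gff")) "gtf" else "bed"
  }
  if (format == "gtf") .read_gtf(path) else .read_bed(path)
}

.read_bed <- function(path) {
  lines <- .read_lines_checked(path)
  if (length(lines) == 0) .stopf("no records in %s", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6)) .stopf("malformed BED line %d: fewer than 6 fields",
                          which(nf < 6)[1])
  n12 <- nf >= 12
  if (!(all(n12) || !any(n12)))
    .stopf("malformed BED line %d: mixed BED6/BED12 records", which(n12 != n12[1])[1])
  get <- function(k) vapply(fields, `[[`, "", k)
  chrom <- get(1); start <- suppressWarnings(as.numeric(get(2)))
  end <- suppressWarnings(as.numeric(get(3)))
  name <- get(4); strand <- get(6)
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad)) .stopf("malformed BED line %d: bad coordinates", bad[1])
  bads <- which(!strand %in% c("+", "-"))
  if (length(bads)) .stopf("unknown strand character '%s' on line %d",
                           strand[bads[1]], bads[1])
  if (anyDuplicated(name)) name <- make.unique(name, sep = "_dup")
  exons <- NULL
  if (all(n12)) {
    exons <- lapply(seq_along(fields), function(i) {
      sizes <- as.numeric(strsplit(fields[[i]][11], ",")[[1]])
      offs <- as.numeric(strsplit(fields[[i]][12], ",")[[1]])
      if (length(sizes) != length(offs) || anyNA(sizes) || anyNA(offs))
        .stopf("malformed BED line %d: block fields disagree", i)
      cbind(start = start[i] + offs, end = start[i] + offs + sizes)
    })
    names(exons) <- name
  }
  gene_models(name, chrom, start, end, strand, exons)
}

.read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[!is.na(gr$type) & gr$type == "exon"]
  if (length(ex) == 0) .stopf("no exon features in %s", path)
  ids <- if (!is.null(ex$transcript_id)) as.character(ex$transcript_id)
         else as.character(ex$gene_id)
  if (anyNA(ids)) .stopf("GTF exon feature without transcript_id/gene_id")
  # rtracklayer keeps 1-based closed starts; convert to 0-based half-open
  df <- data.frame(id = ids, chrom = as.character(GenomicRanges::seqnames(ex)),
                   start = GenomicRanges::start(ex) - 1,
                   end = GenomicRanges::end(ex),
                   strand = as.character(GenomicRanges::strand(ex)),
                   stringsAsFactors = FALSE)
  if (any(!df$strand %in% c("+", "-")))
    .stopf("unknown strand character in GTF exon records")
  sp <- split(df, df$id)
  ids <- names(sp)
  exons <- lapply(sp, function(d) {
    m <- cbind(start = d$start, end = d$end)
    m[order(m[, 1]), , drop = FALSE]
  })
  gene_models(ids,
              vapply(sp, function(d) d$chrom[1], ""),
              vapply(sp, function(d) min(d$start), 0),
              vapply(sp, function(d) max(d$end), 0),
              vapply(sp, function(d) d$strand[1], ""),
              exons)
}

#' Write gene models to BED
#'
#' Writes BED12 when exon structure is present (the default constructor gives
#' every model at least one exon), so that a write/read round trip preserves
#' both the span and the exon intervals.
#'
#' @param genes a \code{gene_models} object.
#' @param path output path (".gz" suffix gzips).
#' @export
write_genes_bed <- function(genes, path) {
  exons <- gene_exons(genes)
  lines <- vapply(seq_len(nrow(genes)), function(i) {
    ex <- exons[[genes$gene_id[i]]]
    paste(genes$chrom[i], format(genes$start[i], scientific = FALSE),
          format(genes$end[i], scientific = FALSE), genes$gene_id[i], 0L,
          genes$strand[i],
          format(genes$start[i], scientific = FALSE),
          format(genes$end[i], scientific = FALSE), "0,0,0", nrow(ex),
          paste0(paste(format(ex[, 2] - ex[, 1], scientific = FALSE, trim = TRUE),
                       collapse = ","), ","),
          paste0(paste(format(ex[, 1] - genes$start[i], scientific = FALSE,
                              trim = TRUE), collapse = ","), ","),
          sep = "\t")
  }, "")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Derive an analysis region for each gene
#'
#' Regions are strand-oriented: "downstream" follows the direction of
#' transcription. Supported roles and their defaults:
#' \describe{
#'   \item{proximal_promoter}{−30 bp to +250 bp around the TSS (280 bp).}
#'   \item{gene_body}{+300 bp downstream of the TSS to −200 bp upstream of
#'     the TES; genes too short for these offsets are flagged unusable.}
#'   \item{antisense_window}{the 1,000 bp immediately upstream of the TSS,
#'     on the genomic side opposite to the direction of transcription.}
#'   \item{tss_flank}{a symmetric window of \code{flank} bp either side of
#'     the TSS, for metaprofiles.}
#' }
#'
#' @param genes a \code{gene_models} object.
#' @param role one of the roles above.
#' @param prox_up,prox_down proximal-promoter bounds around the TSS (bp).
#' @param body_start_offset,body_end_offset gene-body trims from TSS / TES (bp).
#' @param antisense_width width of the upstream antisense window (bp).
#' @param flank half-width of the tss_flank window (bp).
#' @return data frame with gene_id, chrom, start, end, strand, role, usable.
#'   Unusable gene bodies carry NA coordinates.
#' @export
derive_region <- function(genes,
                          role = c("proximal_promoter", "gene_body",
                                   "antisense_window", "tss_flank"),
                          prox_up = 30, prox_down = 250,
                          body_start_offset = 300, body_end_offset = 200,
                          antisense_width = 1000, flank = 2000) {
  role <- match.arg(role)
  plus <- genes$strand == "+"
  tss <- genes$tss; tes <- genes$tes
  start <- end <- numeric(nrow(genes))
  usable <- rep(TRUE, nrow(genes))
  if (role == "proximal_promoter") {
    start <- ifelse(plus, tss - prox_up, tss - prox_down)
    end <- ifelse(plus, tss + prox_down, tss + prox_up)
  } else if (role == "gene_body") {
    start <- ifelse(plus, tss + body_start_offset, tes + body_end_offset)
    end <- ifelse(plus, tes - body_end_offset, tss - body_start_offset)
    usable <- start < end
    start[!usable] <- NA_real_; end[!usable] <- NA_real_
  } else if (role == "antisense_window") {
    start <- ifelse(plus, tss - antisense_width, tss)
    end <- ifelse(plus, tss, tss + antisense_width)
  } else {
    start <- tss - flank
    end <- tss + flank
  }
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom, start = start,
             end = end, strand = genes$strand, role = role, usable = usable,
             stringsAsFactors = FALSE)
}

#' Remove genes with another gene within 2.5 kb upstream of their TSS
#'
#' A gene is dropped when its strand-oriented upstream window
#' \code{[TSS − upstream_margin, TSS)} intersects the annotated span of any
#' other gene on the same chromosome (either strand). This isolates promoters
#' so that upstream antisense signal cannot come from a neighbouring
#' transcription unit. With \code{against = "promoter"} the window is tested
#' against other genes' equally-sized upstream windows instead of their full
#' spans (for promoter-sharing bidirectional pairs). The result is
#' deterministic, order-independent, a subset of the input, and idempotent.
#'
#' @param genes a \code{gene_models} object.
#' @param upstream_margin upstream clearance in bp (default 2500).
#' @param against "span" (default) or "promoter".
#' @return the retained \code{gene_models}.
#' @export
filter_isolated_promoters <- function(genes, upstream_margin = 2500,
                                      against = c("span", "promoter")) {
  against <- match.arg(against)
  plus <- genes$strand == "+"
  up_s <- pmax(0, ifelse(plus, genes$tss - upstream_margin, genes$tss))
  up_e <- ifelse(plus, genes$tss, genes$tss + upstream_margin)
  t_s <- if (against == "span") genes$start else up_s
  t_e <- if (against == "span") genes$end else up_e
  keep <- vapply(seq_len(nrow(genes)), function(i) {
    j <- genes$chrom == genes$chrom[i]
    j[i] <- FALSE
    !any(.overlaps(up_s[i], up_e[i], t_s[j], t_e[j]))
  }, TRUE)
  out <- genes[keep, , drop = FALSE]
  attr(out, "exons") <- gene_exons(genes)[out$gene_id]
  class(out) <- c("gene_models", "data.frame")
  out
}

#' Mean GC fraction around a set of anchors
#'
#' For each strand-oriented offset (− strand anchors are orientation-flipped)
#' the mean fraction of G/C among non-N bases across all anchors is
#' computed, optionally averaged into fixed-width offset bins. Offsets whose
#' bases are N in every anchor are reported as NA, not zero.
#'
#' @param genome a named \code{DNAStringSet} (or list of character strings).
#' @param anchors data frame with chrom, pos (0-based anchor base), strand.
#' @param flank half-width of the window in bp; offsets run −flank..flank−1.
#' @param bin offset bin width in bp (default 1).
#' @return data frame with columns offset (bin start) and gc.
#' @export
gc_profile <- function(genome, anchors, flank, bin = 1) {
  seqs <- if (is(genome, "DNAStringSet")) as.character(genome) else
    vapply(genome, as.character, "")
  lens <- nchar(seqs)
  offs <- seq(-flank, flank - 1)
  prof <- matrix(NA_real_, nrow(anchors), 2 * flank)
  kept <- 0L
  for (i in seq_len(nrow(anchors))) {
    ch <- anchors$chrom[i]; p <- anchors$pos[i]
    minus <- anchors$strand[i] == "-"
    s <- if (minus) p - flank + 1 else p - flank
    e <- s + 2 * flank
    if (is.na(lens[ch]) || s < 0 || e > lens[ch]) next
    b <- strsplit(substr(seqs[[ch]], s + 1, e), "")[[1]]
    v <- ifelse(b %in% c("G", "C"), 1, ifelse(b %in% c("A", "T"), 0, NA))
    if (minus) v <- rev(v)
    prof[i, ] <- v
    kept <- kept + 1L
  }
  if (kept == 0L) .stopf("no anchor window lies within the genome sequence")
  grp <- (offs - offs[1]) %/% bin
  gc <- vapply(split(seq_along(offs), grp), function(cols) {
    x <- prof[, cols, drop = FALSE]
    if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  }, 0)
  data.frame(offset = offs[!duplicated(grp)], gc = as.numeric(gc))
}
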