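#' Per-base signal tracks
#'
#' A \code{tag_track} stores one numeric vector of per-bin signal per
#' chromosome together with its bin size, strand, normalisation state and
#' smoothing window. Tracks are "raw" until 1x-depth normalised, after which
#' the genome-wide mean per-bp value is 1.
#'
#' @param values named list (by chrom) of numeric per-bin vectors.
#' @param seqlens named chromosome lengths (bp).
#' @param binsize bin width in bp.
#' @param strand "+", "-" or "." (unstranded).
#' @param norm_state "raw" or "rpgc".
#' @param smooth_window smoothing window in bp, or NA.
#' @return a \code{tag_track} object.
#' @export
tag_track <- function(values, seqlens, binsize = 1, strand = ".",
                      norm_state = "raw", smooth_window = NA_real_) {
  stopifnot(is.list(values), !is.null(names(values)))
  for (ch in names(values)) {
    expect <- ceiling(seqlens[[ch]] / binsize)
    if (length(values[[ch]]) != expect)
      .stopf("track for %s has %d bins, expected %d", ch,
             length(values[[ch]]), expect)
    if (any(values[[ch]] < 0)) .stopf("track values must be >= 0")
  }
  structure(list(values = values, seqlens = seqlens, binsize = binsize,
                 strand = strand, norm_state = norm_state,
                 smooth_window = smooth_window),
            class = "tag_track")
}

#' @export
print.tag_track <- function(x, ...) {
  cat(sprintf("tag_track: %d chrom(s), binsize %d bp, strand %s, %s%s\n",
              length(x$values), x$binsize, x$strand, x$norm_state,
              if (is.na(x$smooth_window)) "" else
                sprintf(", smoothed %g bp", x$smooth_window)))
  invisible(x)
}

.empty_values <- function(seqlens, binsize) {
  v <- lapply(seqlens, function(L) numeric(ceiling(L / binsize)))
  names(v) <- names(seqlens)
  v
}

#' Build signal tracks from tags or fragments
#'
#' NET-seq tags add +1 at their recorded base on their own strand, producing
#' a +/− pair of tracks. Fragments produce one unstranded track, either in
#' coverage mode (+1 on every covered base) or midpoint mode (+1 at
#' \code{floor((start+end)/2)}).
#'
#' @param x a tag data frame (chrom, pos, strand) or a \code{fragment_set}.
#' @param seqlens named chromosome lengths.
#' @param binsize bin width in bp (1 for single-nucleotide analyses).
#' @param mode fragment counting mode, "coverage" or "midpoint".
#' @return for tags, a list with elements \code{plus} and \code{minus}; for
#'   fragments, a single \code{tag_track}.
#' @export
build_track <- function(x, seqlens, binsize = 1,
                        mode = c("coverage", "midpoint")) {
  mode <- match.arg(mode)
  if (!is.null(x$pos)) {
    bad <- which(!(x$chrom %in% names(seqlens)) | x$pos < 0 |
                   x$pos >= seqlens[x$chrom])
    if (length(bad))
      .stopf("tag record %d (%s:%s) lies outside the genome", bad[1],
             x$chrom[bad[1]], format(x$pos[bad[1]], scientific = FALSE))
    ci <- match(x$chrom, names(seqlens))
    one <- function(strand) {
      v <- .empty_values(seqlens, binsize)
      sel <- x$strand == strand
      cis <- ci[sel]
      p <- if (binsize == 1) x$pos[sel] else x$pos[sel] %/% binsize
      for (k in unique(cis))
        v[[k]] <- tabulate(p[cis == k] + 1, nbins = length(v[[k]]))
      tag_track(v, seqlens, binsize, strand)
    }
    return(list(plus = one("+"), minus = one("-")))
  }
  bad <- which(!(x$chrom %in% names(seqlens)) | x$start < 0 |
                 x$end > seqlens[x$chrom])
  if (length(bad))
    .stopf("fragment record %d (%s:%s-%s) lies outside the genome", bad[1],
           x$chrom[bad[1]], x$start[bad[1]], x$end[bad[1]])
  v <- .empty_values(seqlens, binsize)
  ci <- match(x$chrom, names(seqlens))
  if (mode == "midpoint") {
    mid <- (x$start + x$end) %/% 2
    for (k in unique(ci)) {
      p <- mid[ci == k] %/% binsize
      v[[k]] <- tabulate(p + 1, nbins = length(v[[k]]))
    }
  } else {
    if (binsize != 1)
      .stopf("coverage mode requires binsize 1")
    for (k in unique(ci)) {
      sel <- ci == k
      L <- length(v[[k]])
      # +1 over [start, end): difference array then cumulative sum
      add <- tabulate(x$start[sel] + 1, nbins = L + 1)
      rem <- tabulate(x$end[sel] + 1, nbins = L + 1)
      v[[k]] <- cumsum(add - rem)[seq_len(L)]
    }
  }
  tag_track(v, seqlens, binsize)
}

#' Normalise a track to 1x genome coverage (RPGC)
#'
#' Scales all values by \code{effective_genome_size / total_signal_in_bp} so
#' that the genome-wide mean per-bp signal equals 1. Refuses to normalise an
#' already-normalised or empty track.
#'
#' @param track a raw \code{tag_track}.
#' @param effective_genome_size denominator in bp; defaults to the total
#'   track genome length.
#' @return the normalised \code{tag_track} (norm_state "rpgc").
#' @export
normalize_rpgc <- function(track, effective_genome_size = NULL) {
  if (track$norm_state != "raw")
    .stopf("track is already normalised (state: %s)", track$norm_state)
  if (is.null(effective_genome_size))
    effective_genome_size <- sum(unlist(track$seqlens))
  total_bp <- sum(vapply(track$values, sum, 0)) * track$binsize
  if (total_bp <= 0) .stopf("cannot normalise a track with zero total signal")
  scale <- effective_genome_size / total_bp
  track$values <- lapply(track$values, `*`, scale)
  track$norm_state <- "rpgc"
  track
}

#' Smooth a 1-bp track with a centred moving average
#'
#' A window of \code{window} bp is interpreted as a centred window of
#' \code{2*floor(window/2)+1} bins (the default 20 becomes ±10 bp, 21 bins);
#' at chromosome edges the window shrinks to the available bins. Signal away
#' from the edges is conserved exactly.
#'
#' @param track a \code{tag_track} with binsize 1.
#' @param window window size in bp.
#' @return the smoothed \code{tag_track}.
#' @export
smooth_track <- function(track, window = 20) {
  if (track$binsize != 1) .stopf("smoothing requires binsize 1")
  half <- floor(window / 2)
  track$values <- lapply(track$values, function(v) {
    L <- length(v)
    if (L <= 2 * half + 1) {
      lo <- pmax(seq_len(L) - half, 1L)
      hi <- pmin(seq_len(L) + half, L)
      cs <- c(0, cumsum(v))
      return((cs[hi + 1] - cs[lo]) / (hi - lo + 1))
    }
    W <- 2 * half + 1
    cs <- cumsum(v)
    lead <- cs[(half + 1):(2 * half)] / ((half + 1):(2 * half))
    interior <- (cs[W:L] - c(0, cs[seq_len(L - W)])) / W
    trail <- (cs[L] - cs[(L - 2 * half):(L - half - 1)]) / ((2 * half):(half + 1))
    c(lead, interior, trail)
  })
  track$smooth_window <- window
  track
}

# window extraction convention shared by metaprofiles and GC profiles:
# offsets run -flank .. flank-1 with offset 0 at the anchor base; − strand
# anchors are orientation-flipped (reverse offsets, swap strands)
.anchor_window <- function(values, seqlens, chrom, pos, strand, flank) {
  L <- seqlens[[chrom]]
  if (is.null(L)) return(NULL)
  minus <- strand == "-"
  s <- if (minus) pos - flank + 1 else pos - flank
  e <- s + 2 * flank
  if (s < 0 || e > L) return(NULL)
  w <- values[[chrom]][(s + 1):e]
  if (minus) rev(w) else w
}

#' Anchor-by-offset signal matrix
#'
#' Extracts a strand-oriented window of ±\code{flank} bp around each anchor
#' from the appropriate track: for stranded track pairs, the anchor-strand
#' track ("sense") or the opposite track when \code{anti_strand = TRUE};
#' a single unstranded track is used as-is. Anchors whose window leaves the
#' chromosome are skipped (count in attribute \code{"n_skipped"}).
#'
#' @param tracks a \code{tag_track} or a list with elements plus/minus.
#' @param anchors data frame with chrom, pos (0-based anchor base), strand.
#' @param flank half-width in bp; offsets run −flank .. flank−1.
#' @param anti_strand read the strand opposite to each anchor.
#' @return numeric matrix (anchors x offsets) with offsets as colnames and
#'   anchor row names when \code{anchors$gene_id} is present.
#' @export
anchor_matrix <- function(tracks, anchors, flank, anti_strand = FALSE) {
  stranded <- !inherits(tracks, "tag_track")
  if (stranded) stopifnot(all(c("plus", "minus") %in% names(tracks)))
  rows <- vector("list", nrow(anchors))
  for (i in seq_len(nrow(anchors))) {
    tr <- if (!stranded) tracks else {
      want_plus <- (anchors$strand[i] == "+") != anti_strand
      if (want_plus) tracks$plus else tracks$minus
    }
    rows[[i]] <- .anchor_window(tr$values, tr$seqlens, anchors$chrom[i],
                                anchors$pos[i], anchors$strand[i], flank)
  }
  ok <- !vapply(rows, is.null, TRUE)
  m <- do.call(rbind, rows[ok])
  if (is.null(m)) .stopf("no anchor window lies within the genome")
  colnames(m) <- seq(-flank, flank - 1)
  if (!is.null(anchors$gene_id)) rownames(m) <- anchors$gene_id[ok]
  attr(m, "n_skipped") <- sum(!ok)
  m
}

#' TSS-anchored metaprofile
#'
#' Averages the anchor-by-offset matrix column-wise, reporting per-offset
#' mean, standard error and 95% confidence half-width (1.96 x SE), the form
#' in which composite nucleosome-occupancy and nascent-transcription
#' profiles are usually drawn.
#'
#' @inheritParams anchor_matrix
#' @param keep_matrix retain the underlying matrix as attribute "matrix".
#' @return a \code{metaprofile} data frame with columns offset, mean, se,
#'   ci_lo, ci_hi, n.
#' @export
metaprofile <- function(tracks, anchors, flank, anti_strand = FALSE,
                        keep_matrix = FALSE) {
  m <- anchor_matrix(tracks, anchors, flank, anti_strand)
  mu <- colMeans(m)
  se <- apply(m, 2, sd) / sqrt(nrow(m))
  out <- data.frame(offset = as.numeric(colnames(m)), mean = mu, se = se,
                    ci_lo = mu - 1.96 * se, ci_hi = mu + 1.96 * se,
                    n = nrow(m))
  rownames(out) <- NULL
  if (keep_matrix) attr(out, "matrix") <- m
  attr(out, "n_skipped") <- attr(m, "n_skipped")
  class(out) <- c("metaprofile", "data.frame")
  out
}

#' Sum of track signal over a region, and mean density
#'
#' @param track a \code{tag_track} (binsize 1).
#' @param chrom,start,end 0-based half-open region (vectors allowed).
#' @return numeric vector of per-region summed signal.
#' @export
region_sum <- function(track, chrom, start, end) {
  vapply(seq_along(chrom), function(i) {
    if (is.na(start[i]) || is.na(end[i])) return(NA_real_)
    v <- track$values[[chrom[i]]]
    if (is.null(v)) .stopf("unknown chromosome %s", chrom[i])
    s <- max(0, start[i]); e <- min(length(v), end[i])
    if (e <= s) return(NA_real_)
    sum(v[(s + 1):e])
  }, 0)
}

#' Write / read a track as bedGraph
#'
#' Four-column bedGraph with run-length-compressed intervals and values
#' printed to 6 decimal places; zero runs are omitted on write and implied
#' on read. Stranded pairs are conventionally written to separate files
#' suffixed .plus/.minus by the caller.
#'
#' @param track a \code{tag_track} (binsize 1).
#' @param path file path (".gz" gzips).
#' @export
write_bedgraph <- function(track, path) {
  con <- .open_w(path); on.exit(close(con))
  for (ch in names(track$values)) {
    r <- rle(round(track$values[[ch]], 6))
    e <- cumsum(r$lengths)
    s <- e - r$lengths
    keep <- r$values != 0
    if (!any(keep)) next
    writeLines(sprintf("%s\t%d\t%d\t%s", ch, s[keep], e[keep],
                       formatC(r$values[keep], format = "f", digits = 6,
                               drop0trailing = TRUE)), con)
  }
  invisible(path)
}

#' @rdname write_bedgraph
#' @param seqlens named chromosome lengths for the reconstructed track.
#' @param strand,norm_state metadata to attach on read.
#' @export
read_bedgraph <- function(path, seqlens, strand = ".", norm_state = "raw") {
  v <- .empty_values(seqlens, 1)
  lines <- .read_lines_checked(path)
  if (length(lines)) {
    f <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(f) < 4)
    if (length(bad)) .stopf("malformed bedGraph line %d", bad[1])
    ch <- vapply(f, `[[`, "", 1)
    s <- as.numeric(vapply(f, `[[`, "", 2))
    e <- as.numeric(vapply(f, `[[`, "", 3))
    val <- as.numeric(vapply(f, `[[`, "", 4))
    for (i in seq_along(ch)) v[[ch[i]]][(s[i] + 1):e[i]] <- val[i]
  }
  tag_track(v, seqlens, 1, strand, norm_state)
}
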