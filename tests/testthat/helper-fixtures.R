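# shared in-code fixtures and independent oracles

# a handful of hand-placed genes on two chromosomes
toy_genes <- function() {
  gene_models(gene_id = c("gA", "gB", "gC"),
              chrom = c("chr1", "chr1", "chr2"),
              start = c(10000, 40000, 5000),
              end = c(20000, 44000, 9000),
              strand = c("+", "-", "+"))
}

# constant-value stranded track pair
uniform_tracks <- function(seqlens, value = 1) {
  v <- lapply(seqlens, function(L) rep(value, L))
  names(v) <- names(seqlens)
  list(plus = tag_track(v, seqlens), minus = tag_track(v, seqlens))
}

# brute-force pairwise version of the promoter-isolation rule
brute_isolated <- function(genes, margin = 2500) {
  keep <- rep(TRUE, nrow(genes))
  for (i in seq_len(nrow(genes))) {
    t <- genes$tss[i]
    win <- if (genes$strand[i] == "+") c(max(0, t - margin), t)
           else c(t, t + margin)
    for (j in seq_len(nrow(genes))) {
      if (i == j || genes$chrom[i] != genes$chrom[j]) next
      if (win[1] < genes$end[j] && genes$start[j] < win[2]) keep[i] <- FALSE
    }
  }
  genes$gene_id[keep]
}

# step-up definition of Benjamini-Hochberg, written out longhand
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  for (k in seq_len(n)) {
    vals <- vapply(k:n, function(j) n * p[o[j]] / j, 0)
    adj[o[k]] <- min(1, min(vals))
  }
  adj
}

# naive centred moving average with edge shrinkage
brute_smooth <- function(v, half = 10) {
  vapply(seq_along(v), function(i) {
    lo <- max(1, i - half); hi <- min(length(v), i + half)
    mean(v[lo:hi])
  }, 0)
}

# small synthetic experiment used across tests
mini_config <- function(seed = 1, per_class = 10, ...) {
  truth_config(seed = seed,
               class_counts = c(up_bound = per_class, up_unbound = per_class,
                                down_bound = per_class,
                                down_unbound = per_class,
                                unchanged_bound = per_class,
                                unchanged_unbound = per_class),
               simulate_sequence = FALSE, ...)
}
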