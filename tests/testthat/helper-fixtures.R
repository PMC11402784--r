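# Shared fixture builders. Everything is generated in code; no data files.

small_sim <- function(n_genes = 60, seed = 7, ...) {
  cfg <- sim_config(n_genes = n_genes, seed = seed, ...)
  c(generate_transcriptome(cfg), list(cfg = cfg))
}

# a minimal track: one gene, explicit positions/counts
toy_track <- function(gene, pos, count, sample = "s1") {
  tibble::tibble(sample = sample, gene = gene, pos = as.integer(pos),
                 count = as.integer(count))
}

# deterministic uniform expression table
flat_expr <- function(genes, tpm = 1) tibble::tibble(gene = genes, tpm = tpm)

# brute-force positional mean coverage oracle: no smoothing shortcuts, no
# binning tricks -- direct per-position arithmetic
naive_metaprofile <- function(track, regions, expr, span_up, span_down,
                              smooth_window = 20) {
  lib <- sum(track$count)
  offs <- seq(-span_up, span_down)
  profs <- list()
  for (i in seq_len(nrow(regions))) {
    g <- regions$gene[i]
    tpm <- expr$tpm[expr$gene == g]
    v <- numeric(regions$width[i])
    tg <- track[track$gene == g, ]
    for (j in seq_len(nrow(tg))) v[tg$pos[j]] <- tg$count[j] * 1e6 / lib / tpm
    sm <- smooth_profile(v, smooth_window, "triangular")
    profs[[i]] <- sm[regions$pas_start[i] + offs]
  }
  colMeans(do.call(rbind, profs))
}

# independent half-life oracle: dense grid search over lambda (v0 profiled
# out by least squares for fixed lambda)
grid_halflife <- function(t, v, lambdas = exp(seq(log(1e-3), log(20), length.out = 20000))) {
  sse <- vapply(lambdas, function(l) {
    e <- exp(-l * t)
    v0 <- sum(v * e) / sum(e^2)
    sum((v - v0 * e)^2)
  }, numeric(1))
  log(2) / lambdas[which.min(sse)]
}

# brute-force binned-profile oracle: dense vectors, explicit bin edges
naive_binned_profile <- function(track, regions, expr, n_bins = 100) {
  lib <- sum(track$count)
  mat <- matrix(0, nrow(regions), n_bins)
  for (i in seq_len(nrow(regions))) {
    g <- regions$gene[i]
    tpm <- expr$tpm[expr$gene == g]
    v <- numeric(regions$width[i])
    tg <- track[track$gene == g, ]
    for (j in seq_len(nrow(tg))) v[tg$pos[j]] <- tg$count[j] * 1e6 / lib / tpm
    len <- regions$width[i]
    base <- len %/% n_bins; extra <- len %% n_bins
    widths <- rep(base, n_bins) + c(rep(1, extra), rep(0, n_bins - extra))
    hi <- cumsum(widths); lo <- hi - widths + 1
    for (b in seq_len(n_bins)) mat[i, b] <- sum(v[lo[b]:hi[b]]) / widths[b]
  }
  colMeans(mat)
}

# brute-force motif-coverage oracle: explicit substring comparisons,
# per-crosslink loops, no regex and no vectorized coverage masks
naive_motif_coverage <- function(track, sequences, group, half_window, cap = 20) {
  group <- chartr("Uu", "Tt", toupper(group))
  offs <- seq(-half_window, half_window)
  acc <- numeric(length(offs)); wtot <- 0
  for (i in seq_len(nrow(track))) {
    s <- toupper(sequences$seq[sequences$gene == track$gene[i]])
    len <- nchar(s)
    covered <- rep(FALSE, len)
    for (p in seq_len(len)) {
      for (km in group) {
        k <- nchar(km)
        for (st in max(1, p - k + 1):p) {
          if (st + k - 1 <= len && substr(s, st, st + k - 1) == km) {
            covered[p] <- TRUE
          }
        }
      }
    }
    w <- min(track$count[i], cap)
    for (oi in seq_along(offs)) {
      p <- track$pos[i] + offs[oi]
      if (p >= 1 && p <= len && covered[p]) acc[oi] <- acc[oi] + w
    }
    wtot <- wtot + w
  }
  100 * acc / wtot
}
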