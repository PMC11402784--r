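# Normalization of cross-link tracks and every positional summary drawn from
# them: PAS-anchored metaprofiles, whole-transcript binned profiles, per-UTR
# heat maps, binned log2 fold changes and terminal-abundance comparisons.
#
# Normalization order follows the stated pipeline: depth (CPM), then per-gene
# expression (TPM), then smoothing per region, then averaging across regions.

#' Gene-level expression from transcript TPM
#'
#' Sums TPM over the transcripts of each gene within a replicate, then
#' averages the sums across replicates (per condition when present).
#'
#' @param transcript_tpm tibble with `transcript`, `gene`, `replicate`, `tpm`
#'   and optionally `condition`.
#' @return tibble with `gene` (`condition` if supplied) and `tpm`.
#' @export
gene_level_tpm <- function(transcript_tpm) {
  assert_columns(transcript_tpm, c("transcript", "gene", "replicate", "tpm"))
  no_gene <- is.na(transcript_tpm$gene) | transcript_tpm$gene == ""
  if (any(no_gene)) {
    warn(sprintf("%d transcript(s) without a gene id excluded", sum(no_gene)))
    transcript_tpm <- transcript_tpm[!no_gene, , drop = FALSE]
  }
  grp <- intersect(c("gene", "condition"), names(transcript_tpm))
  transcript_tpm %>%
    group_by(across(all_of(c(grp, "replicate")))) %>%
    summarise(tpm = sum(.data$tpm), .groups = "drop") %>%
    group_by(across(all_of(grp))) %>%
    summarise(tpm = mean(.data$tpm), .groups = "drop")
}

# library sizes per sample of a track
track_library_size <- function(track) {
  track %>%
    group_by(.data$sample) %>%
    summarise(library_size = sum(.data$count), .groups = "drop")
}

#' Depth- and expression-normalize a cross-link track
#'
#' Each position's value becomes `count * 1e6 / library_size` (CPM), divided
#' by the gene-level TPM of its gene (CPM per TPM). Genes with zero or missing
#' TPM are dropped with a warning.
#'
#' @param track cross-link track (`sample`, `gene`, `pos`, `count`); a single
#'   sample.
#' @param expr tibble with `gene`, `tpm`.
#' @return the track with added `cpm` and `cpm_per_tpm` columns.
#' @export
normalize_coverage <- function(track, expr) {
  assert_columns(track, c("sample", "gene", "pos", "count"))
  assert_columns(expr, c("gene", "tpm"))
  lib <- sum(track$count)
  if (lib <= 0) abort("track has zero library size")
  out <- track %>%
    left_join(expr %>% select("gene", "tpm"), by = "gene") %>%
    mutate(cpm = .data$count * 1e6 / lib)
  bad <- is.na(out$tpm) | out$tpm <= 0
  if (any(bad)) {
    warn(sprintf("dropping %d position(s) in %d gene(s) with zero/missing TPM",
                 sum(bad), dplyr::n_distinct(out$gene[bad])))
    out <- out[!bad, , drop = FALSE]
  }
  out %>% mutate(cpm_per_tpm = .data$cpm / .data$tpm)
}

# dense normalized coverage vector for one gene over positions 1..width
dense_coverage <- function(track_gene, width, lib, tpm) {
  v <- numeric(width)
  ok <- track_gene$pos >= 1 & track_gene$pos <= width
  v[track_gene$pos[ok]] <- track_gene$count[ok] * 1e6 / lib / tpm
  v
}

#' Anchored metaprofile of normalized cross-link coverage
#'
#' Regions are anchored on the terminal PAS (offsets relative to `pas_start`),
#' the 3' terminus, or a supplied anchor column. Per region the coverage is
#' CPM/TPM-normalized, smoothed (20-nt triangular rolling mean), and the
#' per-offset mean across regions is reported with a bootstrap 95% confidence
#' interval (percentile method; regions are the resampling unit). Regions
#' shorter than the analysis filter or without the full anchor window are
#' dropped (tallied in the `dropped` attribute).
#'
#' @param track single-sample cross-link track.
#' @param regions tibble with `gene`, `width` and `pas_start` (for the PAS
#'   anchor) or `anchor` (anchor position, 1-based).
#' @param expr tibble with `gene`, `tpm`.
#' @param anchor `"pas"`, `"terminus"` or `"custom"` (uses `regions$anchor`).
#' @param span_up,span_down offsets covered upstream/downstream of the anchor.
#' @param min_length minimum region length filter (300 nt for PAS profiles,
#'   500 nt for terminus profiles in the standard analyses).
#' @param min_tpm minimum expression filter.
#' @param smooth_window triangular smoothing window, nt.
#' @param n_boot bootstrap resamples for the CI.
#' @param seed bootstrap seed.
#' @return a `metaprofile` tibble: `offset`, `mean`, `ci_lo`, `ci_hi`, `n`.
#' @export
metaprofile <- function(track, regions, expr, anchor = c("pas", "terminus", "custom"),
                        span_up = 200, span_down = 50, min_length = 300,
                        min_tpm = 0, smooth_window = 20, n_boot = 1000, seed = 1) {
  anchor <- match.arg(anchor)
  assert_columns(track, c("gene", "pos", "count"))
  assert_columns(regions, c("gene", "width"))
  assert_columns(expr, c("gene", "tpm"))
  lib <- sum(track$count)
  if (lib <= 0) abort("track has zero library size")

  regions <- regions %>% left_join(expr %>% select("gene", "tpm"), by = "gene")
  anchor_pos <- switch(anchor,
    pas = regions$pas_start,
    terminus = regions$width,
    custom = regions[["anchor"]]
  )
  if (is.null(anchor_pos)) abort("regions lack the required anchor column")

  pass_filters <- regions$width >= min_length &
    !is.na(regions$tpm) & regions$tpm > 0 & regions$tpm >= min_tpm
  has_window <- !is.na(anchor_pos) & anchor_pos - span_up >= 1 &
    anchor_pos + span_down <= regions$width
  keep <- pass_filters & has_window
  dropped <- c(length_or_tpm = sum(!pass_filters),
               window = sum(pass_filters & !has_window))
  if (!any(keep)) abort("no region survives the metaprofile filters")

  track_by_gene <- split(track %>% select("pos", "count"), track$gene)
  offs <- seq(-span_up, span_down)
  rows <- which(keep)
  prof <- matrix(0, length(rows), length(offs))
  for (r in seq_along(rows)) {
    i <- rows[r]
    tg <- track_by_gene[[regions$gene[i]]]
    v <- if (is.null(tg)) numeric(regions$width[i]) else
      dense_coverage(tg, regions$width[i], lib, regions$tpm[i])
    sm <- smooth_profile(v, smooth_window, "triangular")
    prof[r, ] <- sm[anchor_pos[i] + offs]
  }

  m <- colMeans(prof)
  if (nrow(prof) == 1) {
    lo <- hi <- m
  } else {
    set.seed(seed)
    boots <- matrix(0, n_boot, length(offs))
    for (b in seq_len(n_boot)) {
      boots[b, ] <- colMeans(prof[sample.int(nrow(prof), replace = TRUE), , drop = FALSE])
    }
    lo <- apply(boots, 2, quantile, 0.025)
    hi <- apply(boots, 2, quantile, 0.975)
  }
  out <- tibble(offset = offs, mean = m, ci_lo = lo, ci_hi = hi, n = nrow(prof))
  attr(out, "dropped") <- dropped
  class(out) <- c("metaprofile", class(out))
  out
}

#' Whole-region binned metaprofile
#'
#' Each region is divided into `n_bins` equal-width bins (when the length is
#' not divisible, the leading `length %% n_bins` bins get one extra
#' nucleotide); the bin value is the sum of normalized counts divided by the
#' bin width, averaged across genes. A rolling mean across `smooth_bins` bins
#' is provided for plotting. Regions shorter than `n_bins` nt are flagged and
#' binned with repeated boundaries (bins of width 1, some positions shared).
#'
#' @param track single-sample cross-link track.
#' @param regions tibble with `gene`, `width` and optionally `region_type`
#'   (e.g. 5'UTR / CDS / 3'UTR; profiles are computed per type).
#' @param expr tibble with `gene`, `tpm`.
#' @param n_bins bins per region, default 100.
#' @param smooth_bins rolling-mean window in bins.
#' @return tibble with `region_type` (if present), `bin`, `mean`,
#'   `mean_smoothed`, `n`.
#' @export
transcript_binned_metaprofile <- function(track, regions, expr, n_bins = 100,
                                          smooth_bins = 10) {
  assert_columns(track, c("gene", "pos", "count"))
  assert_columns(regions, c("gene", "width"))
  lib <- sum(track$count)
  if (lib <= 0) abort("track has zero library size")
  regions <- regions %>% left_join(expr %>% select("gene", "tpm"), by = "gene")
  regions <- regions %>% filter(!is.na(.data$tpm), .data$tpm > 0)
  if (any(regions$width < n_bins)) {
    warn(sprintf("%d region(s) shorter than %d nt binned with repeated boundaries",
                 sum(regions$width < n_bins), n_bins))
  }
  track_by_gene <- split(track %>% select("pos", "count"), track$gene)
  has_type <- "region_type" %in% names(regions)
  regions$region_type <- if (has_type) regions$region_type else "region"

  res <- regions %>%
    group_by(.data$region_type) %>%
    dplyr::group_modify(function(df, key) {
      mat <- matrix(0, nrow(df), n_bins)
      for (i in seq_len(nrow(df))) {
        tg <- track_by_gene[[df$gene[i]]]
        v <- if (is.null(tg)) numeric(df$width[i]) else
          dense_coverage(tg, df$width[i], lib, df$tpm[i])
        edges <- bin_edges(df$width[i], n_bins)
        widths <- pmax(edges$hi - edges$lo + 1L, 1L)
        sums <- vapply(seq_len(n_bins), function(b) {
          sum(v[edges$lo[b]:edges$hi[b]])
        }, numeric(1))
        mat[i, ] <- sums / widths
      }
      m <- colMeans(mat)
      tibble(bin = seq_len(n_bins), mean = m,
             mean_smoothed = moving_average(m, smooth_bins), n = nrow(df))
    }) %>%
    ungroup()
  if (!has_type) res$region_type <- NULL
  res
}

# 1-based closed bin edges; leading (len %% n) bins get an extra nucleotide;
# len < n falls back to width-1 bins with repeated boundaries
bin_edges <- function(len, n) {
  if (len >= n) {
    base <- len %/% n
    extra <- len %% n
    widths <- rep(base, n) + c(rep(1L, extra), rep(0L, n - extra))
    hi <- cumsum(widths)
    lo <- hi - widths + 1L
  } else {
    lo <- pmin(seq_len(n), len)
    hi <- lo
  }
  list(lo = as.integer(lo), hi = as.integer(hi))
}

#' Per-UTR smoothed, min-max-normalized signal heat map
#'
#' Per UTR: raw counts are smoothed with a flat moving average (`window`),
#' then min-max normalized to `[0, 1]`. All-zero and constant rows map to
#' all-zero rows (no 0/0). A side column gives per-UTR abundance: total CPM
#' divided by (length x TPM).
#'
#' @param track single-sample cross-link track.
#' @param regions tibble with `gene`, `width`, optionally `pas_start`.
#' @param expr tibble with `gene`, `tpm`.
#' @param window moving-average window, nt.
#' @return a `utr_heatmap` object: list with `matrix` (UTRs x positions,
#'   NA past each UTR's end), `pas` (per-UTR PAS position or NA) and
#'   `abundance` tibble (`gene`, `abundance`).
#' @export
per_utr_heatmap <- function(track, regions, expr, window = 10) {
  assert_columns(track, c("gene", "pos", "count"))
  assert_columns(regions, c("gene", "width"))
  lib <- sum(track$count)
  if (lib <= 0) abort("track has zero library size")
  regions <- regions %>% left_join(expr %>% select("gene", "tpm"), by = "gene")
  track_by_gene <- split(track %>% select("pos", "count"), track$gene)

  max_w <- max(regions$width)
  mat <- matrix(NA_real_, nrow(regions), max_w,
                dimnames = list(regions$gene, NULL))
  abundance <- numeric(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    tg <- track_by_gene[[regions$gene[i]]]
    raw <- numeric(regions$width[i])
    if (!is.null(tg)) {
      ok <- tg$pos >= 1 & tg$pos <= regions$width[i]
      raw[tg$pos[ok]] <- tg$count[ok]
    }
    sm <- moving_average(raw, window)
    rng <- max(sm) - min(sm)
    mat[i, seq_len(regions$width[i])] <- if (rng > 0) (sm - min(sm)) / rng else 0
    tpm <- regions$tpm[i]
    abundance[i] <- if (!is.na(tpm) && tpm > 0) {
      sum(raw) * 1e6 / lib / (regions$width[i] * tpm)
    } else NA_real_
  }
  structure(
    list(
      matrix = mat,
      pas = regions[["pas_start"]] %||% rep(NA_integer_, nrow(regions)),
      abundance = tibble(gene = regions$gene, abundance = abundance)
    ),
    class = "utr_heatmap"
  )
}

#' Binned log2 fold change of cross-link signal between two conditions
#'
#' Per region, raw counts are quantified in `bin_nt` bins over the terminal
#' `span` nt (anchored at the 3' terminus), converted to the percentage of
#' counts within the region, and compared as
#' `log2((pct_b + 1) / (pct_a + 1))`; the pseudocount of 1 handles empty bins
#' and zero-count regions.
#'
#' @param track_a,track_b single-sample cross-link tracks (conditions A and B).
#' @param regions tibble with `gene`, `width`, restricted upstream to the
#'   analysis filters (e.g. minimum length 500 nt).
#' @param bin_nt bin width, nt.
#' @param span terminal span quantified, nt.
#' @return tibble with `gene`, `bin` (1 = 5'-most bin of the span), `pct_a`,
#'   `pct_b`, `log2fc`.
#' @export
binned_log2fc <- function(track_a, track_b, regions, bin_nt = 20, span = 500) {
  assert_columns(regions, c("gene", "width"))
  n_bins <- span %/% bin_nt
  bin_counts <- function(track, gene, width) {
    lo_span <- max(1L, width - span + 1L)
    tg <- track %>% filter(.data$gene == !!gene,
                           .data$pos >= lo_span, .data$pos <= width)
    bins <- pmin((tg$pos - lo_span) %/% bin_nt + 1L, n_bins)
    vapply(seq_len(n_bins), function(b) sum(tg$count[bins == b]), numeric(1))
  }
  purrr::map_dfr(seq_len(nrow(regions)), function(i) {
    g <- regions$gene[i]
    ca <- bin_counts(track_a, g, regions$width[i])
    cb <- bin_counts(track_b, g, regions$width[i])
    pct_a <- if (sum(ca) > 0) 100 * ca / sum(ca) else numeric(n_bins)
    pct_b <- if (sum(cb) > 0) 100 * cb / sum(cb) else numeric(n_bins)
    tibble(gene = g, bin = seq_len(n_bins), pct_a = pct_a, pct_b = pct_b,
           log2fc = log2((pct_b + 1) / (pct_a + 1)))
  })
}

#' Protein-binding abundance at 3'UTR start vs terminus
#'
#' Compares CPM- and TPM-normalized summed cDNA counts in the window
#' immediately downstream of the stop codon (UTR start) and the window
#' upstream of the 3' terminus. Regions are filtered for minimum UTR length,
#' minimum average expression and a minimum cDNA count in both windows in all
#' supplied samples; exclusions are tallied per filter.
#'
#' @param tracks track tibble covering one or more samples.
#' @param regions tibble with `gene`, `width`.
#' @param expr tibble with `gene`, `tpm` (average expression used for the
#'   filter and the normalization).
#' @param window window size, nt, default 300.
#' @param min_length minimum UTR length, default 800 nt.
#' @param min_tpm minimum average TPM, default 1.
#' @param min_cdna minimum cDNA count per window per sample, default 5.
#' @return list with `result` (tibble `gene`, `sample`, `start_norm`,
#'   `terminus_norm`) and `excluded` (named tally per filter).
#' @export
terminal_abundance <- function(tracks, regions, expr, window = 300,
                               min_length = 800, min_tpm = 1, min_cdna = 5) {
  assert_columns(tracks, c("sample", "gene", "pos", "count"))
  assert_columns(regions, c("gene", "width"))
  assert_columns(expr, c("gene", "tpm"))
  regions <- regions %>% left_join(expr %>% select("gene", "tpm"), by = "gene")
  samples <- unique(tracks$sample)
  libs <- track_library_size(tracks)

  len_ok <- regions$width >= max(min_length, 2 * window)
  tpm_ok <- !is.na(regions$tpm) & regions$tpm >= min_tpm

  win_counts <- purrr::map_dfr(seq_len(nrow(regions)), function(i) {
    g <- regions$gene[i]; w <- regions$width[i]
    tg <- tracks %>% filter(.data$gene == !!g)
    purrr::map_dfr(samples, function(s) {
      ts <- tg %>% filter(.data$sample == !!s)
      tibble(
        gene = g, sample = s,
        start_count = sum(ts$count[ts$pos <= window]),
        term_count = sum(ts$count[ts$pos > w - window & ts$pos <= w])
      )
    })
  })
  cdna_ok_tbl <- win_counts %>%
    group_by(.data$gene) %>%
    summarise(cdna_ok = all(.data$start_count >= min_cdna &
                              .data$term_count >= min_cdna), .groups = "drop")
  cdna_ok <- cdna_ok_tbl$cdna_ok[match(regions$gene, cdna_ok_tbl$gene)]

  keep <- len_ok & tpm_ok & cdna_ok
  excluded <- c(
    length = sum(!len_ok),
    expression = sum(len_ok & !tpm_ok),
    cdna = sum(len_ok & tpm_ok & !cdna_ok)
  )

  result <- win_counts %>%
    filter(.data$gene %in% regions$gene[keep]) %>%
    left_join(libs, by = "sample") %>%
    left_join(regions %>% select("gene", "tpm"), by = "gene") %>%
    mutate(
      start_norm = .data$start_count * 1e6 / .data$library_size / .data$tpm,
      terminus_norm = .data$term_count * 1e6 / .data$library_size / .data$tpm
    ) %>%
    select("gene", "sample", "start_norm", "terminus_norm")
  list(result = result, excluded = excluded)
}
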