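# Position-resolved motif quantification: coverage around cross-link sites,
# binned region coverage, trimer valency upstream of the PAS, terminal-PAS
# location, motif-based binding sites and peak merging/overlap.

# per-position logical vector: is this nucleotide covered by any group k-mer?
group_coverage_vector <- function(seq, group_kmers) {
  len <- nchar(seq)
  cov <- logical(len)
  for (km in group_kmers) {
    k <- nchar(km)
    for (st in find_motif_starts(seq, km)) cov[st:(st + k - 1L)] <- TRUE
  }
  cov
}

#' Motif-group coverage around cross-link sites
#'
#' For every offset in `[-half_window, +half_window]` relative to a
#' cross-link, the percentage of cDNA-weighted cross-links whose sequence has
#' a group k-mer covering that offset. cDNA weights are capped at `cap`
#' (default 20) so a few deep sites cannot dominate; the profile is smoothed
#' with a triangular rolling mean of `smooth_window` nt. Offsets falling
#' outside a sequence count as uncovered.
#'
#' @param track cross-link track (`gene`, `pos`, `count`).
#' @param sequences tibble with `gene`, `seq`.
#' @param group character vector of group k-mers (RNA or DNA alphabet).
#' @param half_window profile half-width, nt.
#' @param cap cDNA weight cap.
#' @param smooth_window triangular smoothing window, nt (0 or 1 disables).
#' @return tibble with `offset`, `pct` (smoothed), `pct_raw`.
#' @export
motif_coverage_around_crosslinks <- function(track, sequences, group,
                                             half_window = 300, cap = 20,
                                             smooth_window = 20) {
  if (length(group) == 0) abort("motif group is empty")
  assert_columns(track, c("gene", "pos", "count"))
  assert_columns(sequences, c("gene", "seq"))
  group <- rna_to_dna(group)
  track <- track %>% filter(.data$gene %in% sequences$gene)
  if (nrow(track) == 0) abort("no cross-links on the supplied sequences")

  covs <- lapply(setNames(toupper(sequences$seq), sequences$gene),
                 group_coverage_vector, group_kmers = group)
  n_pos <- 2L * half_window + 1L
  acc <- numeric(n_pos)
  w_tot <- 0
  gi <- match(track$gene, sequences$gene)
  for (i in seq_len(nrow(track))) {
    cov <- covs[[gi[i]]]
    w <- min(track$count[i], cap)
    idx <- (track$pos[i] - half_window):(track$pos[i] + half_window)
    ok <- idx >= 1L & idx <= length(cov)
    hit <- numeric(n_pos)
    hit[ok] <- as.numeric(cov[idx[ok]])
    acc <- acc + w * hit
    w_tot <- w_tot + w
  }
  pct_raw <- 100 * acc / w_tot
  pct <- if (smooth_window > 1) smooth_profile(pct_raw, smooth_window, "triangular") else pct_raw
  tibble(offset = seq(-half_window, half_window), pct = pct, pct_raw = pct_raw)
}

#' Binned motif coverage of sequence regions
#'
#' Scans each region with a 5-nt window; nucleotides under any window matching
#' a group k-mer are marked covered. Regions are split into `bin_nt` bins and
#' the percentage of covered nucleotides per bin is averaged across regions
#' (a final partial bin is normalized by its true length).
#'
#' @param sequences tibble with `gene`, `seq`; `seq` here is the (equal- or
#'   unequal-length) region sequence to scan.
#' @param group character vector of group k-mers.
#' @param bin_nt bin width, 10 or 20 nt.
#' @return tibble with `bin` (1-based), `pct` (mean % covered), `n` regions
#'   contributing.
#' @export
motif_region_coverage <- function(sequences, group, bin_nt = 10) {
  if (length(group) == 0) abort("motif group is empty")
  if (!bin_nt %in% c(10, 20)) warn("bin_nt outside the usual {10, 20}")
  assert_columns(sequences, c("gene", "seq"))
  group <- rna_to_dna(group)

  per_region <- lapply(toupper(sequences$seq), function(s) {
    cov <- group_coverage_vector(s, group)
    len <- length(cov)
    bins <- ceiling(seq_len(len) / bin_nt)
    tapply(cov, bins, function(v) 100 * mean(v))
  })
  max_bins <- max(vapply(per_region, length, integer(1)))
  mat <- matrix(NA_real_, length(per_region), max_bins)
  for (i in seq_along(per_region)) {
    mat[i, seq_along(per_region[[i]])] <- per_region[[i]]
  }
  tibble(
    bin = seq_len(max_bins),
    pct = colMeans(mat, na.rm = TRUE),
    n = colSums(!is.na(mat))
  )
}

#' Locate the terminal canonical PAS in a 3'UTR sequence
#'
#' Returns the 1-based start of the rightmost exact PAS match whose end lies
#' at least 20 nt from the 3' end of the sequence, or `NA` when no valid match
#' exists.
#'
#' @param sequence a single DNA/RNA sequence of length >= 26.
#' @param pas PAS hexamer, default `AATAAA`.
#' @param min_tail minimum distance from the PAS end to the 3' end, nt.
#' @return integer position or `NA_integer_`.
#' @export
locate_terminal_pas <- function(sequence, pas = "AATAAA", min_tail = 20L) {
  sequence <- rna_to_dna(sequence)
  pas <- rna_to_dna(pas)
  len <- nchar(sequence)
  if (len < nchar(pas) + min_tail) return(NA_integer_)
  hits <- find_motif_starts(sequence, pas)
  valid <- hits[hits + nchar(pas) - 1L <= len - min_tail]
  if (length(valid) == 0) NA_integer_ else max(valid)
}

#' Trimer valency upstream of the PAS
#'
#' Counts overlapping occurrences of a trimer within the `window` nt
#' immediately upstream of each region's terminal canonical PAS. Regions with
#' no valid PAS are excluded and reported.
#'
#' @param sequences tibble with `gene`, `seq` and optionally `pas_start`
#'   (located with [locate_terminal_pas()] otherwise).
#' @param trimer the trimer to count (RNA or DNA), e.g. `"AUU"`.
#' @param window upstream window, nt, default 100.
#' @param pas PAS hexamer used when locating.
#' @return tibble with `gene`, `count`; attribute `excluded` lists genes
#'   without a valid PAS.
#' @export
trimer_valency <- function(sequences, trimer = "AUU", window = 100,
                           pas = "AATAAA") {
  assert_columns(sequences, c("gene", "seq"))
  trimer <- rna_to_dna(trimer)
  seqs <- toupper(sequences$seq)
  pas_start <- sequences[["pas_start"]] %||%
    unname(vapply(seqs, locate_terminal_pas, integer(1), pas = pas))
  excluded <- sequences$gene[is.na(pas_start)]
  if (length(excluded) > 0) {
    inform(sprintf("%d region(s) without a valid terminal PAS excluded", length(excluded)))
  }
  keep <- !is.na(pas_start)
  counts <- vapply(unname(which(keep)), function(i) {
    lo <- max(1L, pas_start[i] - window)
    hi <- pas_start[i] - 1L
    if (hi < lo) return(0L)
    length(find_motif_starts(substr(seqs[i], lo, hi), trimer))
  }, integer(1))
  out <- tibble(gene = sequences$gene[keep], count = counts)
  attr(out, "excluded") <- excluded
  out
}

#' Merge cross-link tracks by summing cDNA counts at overlapping positions
#'
#' @param tracks a track tibble covering several samples, or a list of tracks.
#' @return a single-sample track named `merged`.
#' @export
merge_tracks <- function(tracks) {
  if (is.data.frame(tracks)) tracks <- list(tracks)
  merged <- bind_rows(tracks) %>%
    group_by(.data$gene, .data$pos) %>%
    summarise(count = sum(.data$count), .groups = "drop") %>%
    mutate(sample = "merged") %>%
    select("sample", "gene", "pos", "count")
  merged
}

#' Motif-based binding-site assignment
#'
#' A binding site is emitted wherever a group k-mer starts at one of its
#' relevant offsets within `+/- flank` nt of a cross-link in the merged track.
#' Overlapping sites of the same group within a gene are merged; the
#' supporting count is the summed cDNA of the distinct cross-links that
#' contributed to the merged site.
#'
#' @param merged merged cross-link track (`gene`, `pos`, `count`).
#' @param sequences tibble with `gene`, `seq`.
#' @param group character vector of group k-mers.
#' @param relevant_positions named list: for each k-mer, the integer offsets
#'   (k-mer start minus cross-link position) at which it is enriched; a plain
#'   integer vector applies to every k-mer.
#' @param flank search half-width around cross-links, default 20 nt.
#' @return tibble with `gene`, `start`, `end` (1-based closed), `count`.
#' @export
assign_binding_sites <- function(merged, sequences, group, relevant_positions,
                                 flank = 20L) {
  assert_columns(merged, c("gene", "pos", "count"))
  assert_columns(sequences, c("gene", "seq"))
  group <- rna_to_dna(group)
  if (!is.list(relevant_positions)) {
    relevant_positions <- setNames(rep(list(as.integer(relevant_positions)),
                                       length(group)), group)
  } else {
    names(relevant_positions) <- rna_to_dna(names(relevant_positions))
  }

  starts_by_gene <- lapply(setNames(toupper(sequences$seq), sequences$gene),
                           function(s) {
                             lapply(setNames(group, group), find_motif_starts, seq = s)
                           })
  hits <- vector("list", nrow(merged))
  for (i in seq_len(nrow(merged))) {
    g <- merged$gene[i]
    if (is.null(starts_by_gene[[g]])) next
    for (km in group) {
      st <- starts_by_gene[[g]][[km]]
      rel <- relevant_positions[[km]]
      if (is.null(rel) || length(st) == 0) next
      off <- st - merged$pos[i]
      sel <- st[abs(off) <= flank & off %in% rel]
      if (length(sel) > 0) {
        hits[[i]] <- tibble(
          gene = g, start = sel, end = sel + nchar(km) - 1L,
          xl_pos = merged$pos[i], xl_count = merged$count[i]
        )
      }
    }
  }
  hits <- bind_rows(hits)
  if (nrow(hits) == 0) {
    return(tibble(gene = character(), start = integer(), end = integer(),
                  count = integer()))
  }
  hits %>%
    group_by(.data$gene) %>%
    dplyr::group_modify(function(df, key) {
      ir <- IRanges::IRanges(df$start, df$end)
      red <- IRanges::reduce(ir)
      ov <- IRanges::findOverlaps(ir, red)
      df$site <- S4Vectors::subjectHits(ov)
      support <- df %>%
        distinct(.data$site, .data$xl_pos, .data$xl_count) %>%
        group_by(.data$site) %>%
        summarise(count = sum(.data$xl_count), .groups = "drop")
      tibble(
        start = IRanges::start(red), end = IRanges::end(red),
        count = support$count[match(seq_along(red), support$site)]
      )
    }) %>%
    ungroup()
}

#' Merge peaks within sets and classify overlaps across sets
#'
#' Within each input set, overlapping or book-ended peaks are merged. Each
#' merged a-peak is then classified as overlapping b when it intersects a
#' merged b-peak by at least 1 nt (book-ended across sets does not count as
#' overlapping).
#'
#' @param peaks_a,peaks_b tibbles with `gene`, `start`, `end` (1-based
#'   closed, `start <= end`).
#' @return list with `merged_a`, `merged_b` (tibbles) and `overlap` (tibble
#'   of merged a-peaks with logical `overlaps_b`).
#' @export
merge_and_overlap_peaks <- function(peaks_a, peaks_b) {
  merge_one <- function(peaks) {
    assert_columns(peaks, c("gene", "start", "end"))
    if (any(peaks$start > peaks$end)) abort("peak with start > end")
    peaks %>%
      group_by(.data$gene) %>%
      dplyr::group_modify(function(df, key) {
        red <- IRanges::reduce(IRanges::IRanges(df$start, df$end),
                               min.gapwidth = 1L)
        tibble(start = IRanges::start(red), end = IRanges::end(red))
      }) %>%
      ungroup()
  }
  ma <- merge_one(peaks_a)
  mb <- merge_one(peaks_b)
  overlaps <- logical(nrow(ma))
  for (g in unique(ma$gene)) {
    ia <- which(ma$gene == g)
    ib <- which(mb$gene == g)
    if (length(ib) == 0) next
    ov <- IRanges::overlapsAny(
      IRanges::IRanges(ma$start[ia], ma$end[ia]),
      IRanges::IRanges(mb$start[ib], mb$end[ib]),
      minoverlap = 1L
    )
    overlaps[ia] <- ov
  }
  list(merged_a = ma, merged_b = mb,
       overlap = ma %>% mutate(overlaps_b = overlaps))
}

#' Nucleotide composition around the terminal PAS
#'
#' For each offset from `upstream` nt before to `downstream` nt after the PAS
#' start, the percentage of sequences carrying each base. Percentages sum to
#' 100 per offset before smoothing; a 5-nt rolling mean is applied per base.
#' Sequences whose window would run outside the sequence are dropped.
#'
#' @param sequences tibble with `gene`, `seq` and optionally `pas_start`.
#' @param pas PAS hexamer used when `pas_start` is absent.
#' @param upstream,downstream window, nt (offset 0 = PAS start).
#' @param smooth_window rolling-mean width, nt.
#' @return tibble with `offset`, `base`, `pct`, `pct_smoothed`.
#' @export
nucleotide_composition_around_pas <- function(sequences, pas = "AATAAA",
                                              upstream = 100, downstream = 20,
                                              smooth_window = 5) {
  assert_columns(sequences, c("gene", "seq"))
  seqs <- toupper(sequences$seq)
  pas_start <- sequences[["pas_start"]] %||%
    unname(vapply(seqs, locate_terminal_pas, integer(1), pas = pas))
  keep <- !is.na(pas_start) & pas_start > upstream &
    pas_start + downstream - 1L <= nchar(seqs)
  if (!any(keep)) abort("no sequence offers the full window around its PAS")
  windows <- vapply(unname(which(keep)), function(i) {
    substr(seqs[i], pas_start[i] - upstream, pas_start[i] + downstream - 1L)
  }, "")
  mat <- do.call(rbind, strsplit(windows, ""))
  offsets <- seq(-upstream, downstream - 1L)
  out <- purrr::map_dfr(DNA_BASES, function(b) {
    pct <- 100 * colMeans(mat == b)
    tibble(offset = offsets, base = dna_to_rna(b), pct = pct,
           pct_smoothed = smooth_profile(pct, smooth_window, "flat"))
  })
  out
}
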