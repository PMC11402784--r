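# Positional k-mer enrichment at cross-link sites and the bespoke motif-group
# clustering: substring-Jaccard sequence distance and Euclidean rank distance,
# each standard-scaled then min-max-scaled, combined by Pythagorean addition,
# re-compared by correlation distance and clustered with UPGMA.

#' Positional k-mer enrichment around cross-link sites
#'
#' For every k-mer, compares its occurrence frequency within `+/- half_window`
#' nt of the observed cross-link sites against `n_shuffle` seeded draws of the
#' same number of positions placed uniformly within the same 3'UTRs. The
#' enrichment score is the z-score of the observed window count against the
#' shuffled background; the p-value is the empirical permutation probability
#' `(1 + #[background >= observed]) / (n_shuffle + 1)`, so its floor is
#' `1/(n_shuffle + 1)`. Relevant positions of a k-mer are the offsets at which
#' its observed occurrence exceeds the background mean by more than two
#' background s.d.
#'
#' @param track cross-link track tibble (`gene`, `pos`, `count`); sites are
#'   used unweighted.
#' @param sequences tibble with `gene`, `seq` (3'UTR sequences the track lives
#'   on).
#' @param k k-mer length, default 5.
#' @param half_window window half-width around cross-links, nt.
#' @param n_shuffle background draws.
#' @param seed seed for the background placement.
#' @return a `kmer_stats` tibble: `kmer` (RNA alphabet), `score`, `p`, `rank`
#'   (unique, by decreasing score then k-mer), `obs`, and `relevant_offsets`
#'   (integer list-column of offsets, relative to the cross-link, of the
#'   k-mer start).
#' @export
kmer_enrichment <- function(track, sequences, k = 5, half_window = 20,
                            n_shuffle = 100, seed = 1) {
  assert_columns(track, c("gene", "pos"))
  assert_columns(sequences, c("gene", "seq"))
  track <- track %>% filter(.data$gene %in% sequences$gene)
  if (nrow(track) == 0) abort("track is empty on the supplied sequence space")
  n_sites <- nrow(track)
  widen <- 1L
  if (n_sites < 50) {
    warn(sprintf("only %d cross-link sites; widening background draws", n_sites))
    widen <- as.integer(ceiling(100 / n_sites))
  }

  kmers <- all_kmers(k)
  n_k <- length(kmers)
  offsets <- seq(-half_window, half_window - (k - 1L))
  n_off <- length(offsets)

  # per-gene vector of k-mer ids at each start position (NA where no k-mer fits)
  seqs <- toupper(sequences$seq)
  names(seqs) <- sequences$gene
  kmer_ids <- lapply(seqs, function(s) {
    len <- nchar(s)
    if (len < k) return(integer(0))
    starts <- seq_len(len - k + 1L)
    chars <- strsplit(s, "")[[1]]
    code <- match(chars, DNA_BASES) - 1L     # NA for ambiguous bases
    id <- integer(length(starts))
    for (j in seq_len(k)) id <- id * 4L + code[starts + j - 1L]
    id + 1L                                   # 1-based k-mer id; NA-propagating
  })
  gene_len <- vapply(seqs, nchar, integer(1))

  # flatten the per-gene id vectors so window counting is fully vectorized
  ids_len <- vapply(kmer_ids, length, integer(1))
  ids_offset <- c(0L, cumsum(ids_len))[seq_along(kmer_ids)]
  names(ids_offset) <- names(kmer_ids)
  glob_ids <- unlist(kmer_ids, use.names = FALSE)

  count_windows <- function(genes, positions) {
    # occurrence matrix [kmer x offset] for k-mer starts at position + offset
    acc <- matrix(0L, n_k, n_off)
    gi <- match(genes, names(kmer_ids))
    base <- ids_offset[gi]
    lim <- ids_len[gi]
    for (oi in seq_len(n_off)) {
      st <- positions + offsets[oi]
      ok <- st >= 1L & st <= lim
      ids <- glob_ids[base[ok] + st[ok]]
      acc[, oi] <- acc[, oi] + tabulate(ids[!is.na(ids)], nbins = n_k)
    }
    acc
  }

  obs <- count_windows(track$gene, track$pos)

  set.seed(seed)
  bg_tot <- matrix(0, n_shuffle, n_k)
  bg_off_sum <- matrix(0, n_k, n_off)
  bg_off_sumsq <- matrix(0, n_k, n_off)
  site_genes <- rep(track$gene, widen)
  lens <- gene_len[site_genes]
  for (s in seq_len(n_shuffle)) {
    rand_pos <- 1L + as.integer(floor(runif(length(site_genes)) * lens))
    cnt <- count_windows(site_genes, rand_pos) / widen
    bg_tot[s, ] <- rowSums(cnt)
    bg_off_sum <- bg_off_sum + cnt
    bg_off_sumsq <- bg_off_sumsq + cnt^2
  }

  obs_tot <- rowSums(obs)
  mu <- colMeans(bg_tot)
  sdv <- apply(bg_tot, 2, sd)
  z <- ifelse(sdv > 0, (obs_tot - mu) / sdv, ifelse(obs_tot > mu, Inf, 0))
  z[obs_tot == 0 & mu == 0] <- 0
  p_emp <- vapply(seq_len(n_k), function(j) {
    (1 + sum(bg_tot[, j] >= obs_tot[j])) / (n_shuffle + 1)
  }, numeric(1))
  p_emp[obs_tot == 0] <- 1

  off_mu <- bg_off_sum / n_shuffle
  off_sd <- sqrt(pmax(bg_off_sumsq / n_shuffle - off_mu^2, 0))
  relevant <- lapply(seq_len(n_k), function(j) {
    offsets[obs[j, ] > off_mu[j, ] + 2 * off_sd[j, ] & obs[j, ] > 0]
  })

  out <- tibble(
    kmer = dna_to_rna(kmers), score = z, p = p_emp, obs = obs_tot,
    relevant_offsets = relevant
  ) %>%
    arrange(desc(.data$score), .data$kmer) %>%
    mutate(rank = row_number())
  class(out) <- c("kmer_stats", class(out))
  out
}

#' Substring-Jaccard distance between two k-mers
#'
#' Each k-mer is expanded into the set of all its contiguous substrings of
#' length strictly less than k (duplicates collapsed; e.g. the trimer `UGA`
#' yields `U`, `G`, `A`, `UG`, `GA`). The distance is one minus the Jaccard
#' similarity of the two substring sets.
#'
#' @param kmer_a,kmer_b k-mers of equal length (RNA or DNA alphabet).
#' @return distance in `[0, 1]`.
#' @export
substring_jaccard_distance <- function(kmer_a, kmer_b) {
  if (nchar(kmer_a) == 0 || nchar(kmer_b) == 0) abort("k-mers must be non-empty")
  if (nchar(kmer_a) != nchar(kmer_b)) abort("k-mers must have equal length")
  sa <- kmer_substrings(rna_to_dna(kmer_a))
  sb <- kmer_substrings(rna_to_dna(kmer_b))
  1 - length(intersect(sa, sb)) / length(union(sa, sb))
}

kmer_substrings <- function(kmer) {
  k <- nchar(kmer)
  unique(unlist(lapply(seq_len(k - 1L), function(len) {
    vapply(seq_len(k - len + 1L), function(i) substr(kmer, i, i + len - 1L), "")
  })))
}

#' Pairwise substring-Jaccard distance matrix
#' @param kmers character vector of equal-length k-mers.
#' @return symmetric matrix with zero diagonal.
#' @export
jaccard_distance_matrix <- function(kmers) {
  n <- length(kmers)
  subs <- lapply(rna_to_dna(kmers), kmer_substrings)
  m <- matrix(0, n, n, dimnames = list(kmers, kmers))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      d <- 1 - length(intersect(subs[[i]], subs[[j]])) /
        length(union(subs[[i]], subs[[j]]))
      m[i, j] <- d; m[j, i] <- d
    }
  }
  m
}

#' Euclidean distance matrix between per-sample k-mer ranks
#'
#' Each k-mer is embedded as its vector of ranks across samples; distances are
#' Euclidean.
#'
#' @param ranks tibble with `sample`, `kmer`, `rank`.
#' @return symmetric matrix over the k-mers present in every sample.
#' @export
rank_distance_matrix <- function(ranks) {
  assert_columns(ranks, c("sample", "kmer", "rank"))
  wide <- ranks %>%
    select("sample", "kmer", "rank") %>%
    tidyr::pivot_wider(names_from = "sample", values_from = "rank")
  mat <- as.matrix(wide[-1])
  rownames(mat) <- wide$kmer
  mat <- mat[complete.cases(mat), , drop = FALSE]
  as.matrix(stats::dist(mat))
}

#' Combine two distance matrices by Pythagorean addition
#'
#' Off-diagonal entries of each matrix are standard-scaled (zero mean, unit
#' s.d.) and then min-max-scaled to `[0, 1]`; the combined entry is
#' `sqrt(a^2 + b^2)`. Symmetry and the zero diagonal are preserved. A constant
#' matrix scales to all zeros, so the combination then equals the other
#' matrix's scaled values.
#'
#' @param rank_matrix,jaccard_matrix symmetric matrices of the same shape with
#'   zero diagonals.
#' @return combined symmetric distance matrix.
#' @export
combine_distances <- function(rank_matrix, jaccard_matrix) {
  check_sym <- function(m, what) {
    if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8))) {
      abort(sprintf("%s must be symmetric", what))
    }
  }
  if (!all(dim(rank_matrix) == dim(jaccard_matrix))) abort("matrices must share a shape")
  check_sym(rank_matrix, "rank_matrix")
  check_sym(jaccard_matrix, "jaccard_matrix")

  scale_offdiag <- function(m) {
    v <- m[lower.tri(m)]
    if (length(v) == 0 || sd(v) == 0) {
      sc <- rep(0, length(v))
    } else {
      sc <- (v - mean(v)) / sd(v)
      sc <- (sc - min(sc)) / (max(sc) - min(sc))
    }
    out <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
    out[lower.tri(out)] <- sc
    out + t(out)
  }
  a <- scale_offdiag(rank_matrix)
  b <- scale_offdiag(jaccard_matrix)
  sqrt(a^2 + b^2)
}

#' Cluster k-mers into motif groups
#'
#' Rows of the combined distance matrix are treated as a feature embedding;
#' pairwise correlation distances (`1 - cor`) between rows feed UPGMA
#' (average-linkage) hierarchical clustering, and the tree is cut into
#' `n_clusters` groups. K-mers whose embedding row is constant (correlation
#' undefined) are set aside as singleton groups with a warning. Input row
#' order never changes the result: rows are canonicalized to lexicographic
#' k-mer order before clustering. With `merge_wgg = TRUE`, two G-rich clusters
#' (both with a majority of members containing `GG`) are merged post hoc into
#' a single WGG group.
#'
#' @param combined combined distance matrix from [combine_distances()] with
#'   k-mer dimnames.
#' @param n_clusters number of groups to cut, default 4.
#' @param merge_wgg merge the two G-rich clusters into one WGG group.
#' @return a `motif_groups` tibble: `kmer`, `group` (integer), `name` (WGG /
#'   GAU / AUU / other, suffixed when duplicated). Groups are disjoint and
#'   cover the input k-mers.
#' @export
cluster_kmers <- function(combined, n_clusters = 4, merge_wgg = FALSE) {
  kmers <- rownames(combined)
  if (is.null(kmers)) abort("combined matrix needs k-mer dimnames")
  if (length(kmers) < n_clusters) abort("need at least n_clusters k-mers")
  ord <- order(kmers)
  combined <- combined[ord, ord, drop = FALSE]
  kmers <- kmers[ord]

  const_row <- apply(combined, 1, function(r) sd(r) == 0)
  groups <- integer(length(kmers))
  if (any(const_row)) {
    warn(sprintf("%d k-mer(s) with constant embedding rows assigned singleton clusters",
                 sum(const_row)))
  }
  live <- which(!const_row)
  if (length(live) >= 2) {
    cmat <- 1 - stats::cor(t(combined[live, , drop = FALSE]))
    hc <- hclust(as.dist(cmat), method = "average")
    k_live <- min(n_clusters, length(live))
    groups[live] <- cutree(hc, k = k_live)
  } else if (length(live) == 1) {
    groups[live] <- 1L
  }
  # singletons get fresh group ids after the clustered ones
  n_used <- max(groups, 0L)
  groups[const_row] <- n_used + seq_len(sum(const_row))

  out <- tibble(kmer = kmers, group = groups) %>%
    group_by(.data$group) %>%
    mutate(name = name_motif_group(.data$kmer)) %>%
    ungroup()

  if (merge_wgg) {
    grich <- out %>%
      group_by(.data$group) %>%
      summarise(gg = mean(grepl("GG", rna_to_dna(.data$kmer))), .groups = "drop") %>%
      filter(.data$gg > 0.5)
    if (nrow(grich) >= 2) {
      tops <- grich$group[order(-grich$gg)][1:2]
      out <- out %>%
        mutate(
          group = ifelse(.data$group %in% tops, min(tops), .data$group),
          name = ifelse(.data$group == min(tops), "WGG", .data$name)
        )
    } else {
      inform("merge_wgg requested but fewer than two G-rich clusters found; nothing merged")
    }
  }
  # disambiguate duplicated names
  out <- out %>%
    group_by(.data$name) %>%
    mutate(name = if (dplyr::n_distinct(.data$group) > 1) {
      paste0(.data$name, "_", match(.data$group, unique(.data$group)))
    } else .data$name) %>%
    ungroup() %>%
    arrange(.data$group, .data$kmer)
  class(out) <- c("motif_groups", class(out))
  out
}

# heuristic signature naming of one cluster's members
name_motif_group <- function(kmers) {
  d <- rna_to_dna(kmers)
  frac <- function(pat) mean(grepl(pat, d))
  if (frac("GG") > 0.5) {
    "WGG"
  } else if (frac("GAT") > 0.4) {
    "GAU"
  } else if (frac("ATT|TTA|TAT") > 0.5) {
    "AUU"
  } else {
    "other"
  }
}
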