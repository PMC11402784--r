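# Feature engineering over 3'UTRs and the regulation-group gating applied to
# differential-expression results before any 3'UTR feature analysis.

#' Assign regulation groups from a differential-expression table
#'
#' Down/up calls require `padj < 0.05` and a fold change of at least 1.5
#' (`|log2FC| >= log2(1.5)`) with the matching sign; the control group
#' requires `padj >= 0.05` and `|log2FC| < 0.5`. All three groups are then
#' filtered to protein-coding genes with a 3'UTR of at least 100 nt and an
#' expression level of at least 5 TPM in at least one of the designated
#' conditions. Everything else is `excluded`.
#'
#' @param de tibble with `gene`, `log2fc`, `padj` (and optionally `biotype`;
#'   taken from `annotation` otherwise).
#' @param annotation tibble with `gene`, `utr_length` and `biotype`.
#' @param tpm tibble with `gene`, `condition`, `tpm` (replicate-level rows are
#'   averaged per condition first).
#' @param conditions conditions in which the TPM filter may be satisfied;
#'   default all conditions present in `tpm`.
#' @param min_utr_length,min_tpm filter thresholds.
#' @return tibble with `gene` and `class` in
#'   `down` / `up` / `control` / `excluded`.
#' @export
assign_regulation_groups <- function(de, annotation, tpm,
                                     conditions = NULL,
                                     min_utr_length = 100, min_tpm = 5) {
  assert_columns(de, c("gene", "log2fc", "padj"))
  assert_columns(annotation, c("gene", "utr_length", "biotype"))
  assert_columns(tpm, c("gene", "condition", "tpm"))
  conditions <- conditions %||% unique(tpm$condition)

  expr_ok <- tpm %>%
    filter(.data$condition %in% conditions) %>%
    group_by(.data$gene, .data$condition) %>%
    summarise(tpm = mean(.data$tpm), .groups = "drop") %>%
    group_by(.data$gene) %>%
    summarise(expr_ok = any(.data$tpm >= min_tpm), .groups = "drop")

  lfc_min <- log2(1.5)
  de %>%
    select(-dplyr::any_of(c("biotype", "utr_length"))) %>%
    left_join(annotation %>% select("gene", "utr_length", "biotype"), by = "gene") %>%
    left_join(expr_ok, by = "gene") %>%
    mutate(
      raw_class = dplyr::case_when(
        .data$padj < 0.05 & .data$log2fc <= -lfc_min ~ "down",
        .data$padj < 0.05 & .data$log2fc >= lfc_min ~ "up",
        .data$padj >= 0.05 & abs(.data$log2fc) < 0.5 ~ "control",
        TRUE ~ "excluded"
      ),
      pass_filters = !is.na(.data$biotype) & .data$biotype == "protein_coding" &
        !is.na(.data$utr_length) & .data$utr_length >= min_utr_length &
        !is.na(.data$expr_ok) & .data$expr_ok,
      class = ifelse(.data$raw_class != "excluded" & .data$pass_filters,
                     .data$raw_class, "excluded")
    ) %>%
    select("gene", "class")
}

#' Simple sequence features of 3'UTRs
#'
#' G+C content, the 16 overlapping dinucleotide frequencies (summing to 1 per
#' row) and the width in nt; an optional per-gene conservation score column is
#' appended when supplied. Rows whose sequence contains no unambiguous base
#' are rejected.
#'
#' @param records tibble with `gene`, `seq`.
#' @param conservation optional tibble with `gene`, `conservation`.
#' @return tibble with `gene`, `gc`, `din_AA` ... `din_TT`, `width` (and
#'   `conservation` if supplied).
#' @export
compute_simple_features <- function(records, conservation = NULL) {
  assert_columns(records, c("gene", "seq"))
  seqs <- toupper(records$seq)
  n_acgt <- nchar(gsub("[^ACGT]", "", seqs))
  if (any(n_acgt == 0)) {
    warn(sprintf("rejecting %d sequence(s) with only ambiguous bases: %s",
                 sum(n_acgt == 0),
                 paste(head(records$gene[n_acgt == 0], 5), collapse = ", ")))
    records <- records[n_acgt > 0, , drop = FALSE]
    seqs <- seqs[n_acgt > 0]
  }
  if (nrow(records) == 0) abort("no sequences left after rejecting ambiguous-only rows")
  x <- Biostrings::DNAStringSet(seqs)
  base_freq <- Biostrings::letterFrequency(x, DNA_BASES)
  gc <- rowSums(base_freq[, c("C", "G"), drop = FALSE]) / rowSums(base_freq)
  din <- Biostrings::dinucleotideFrequency(x)
  din <- din / pmax(rowSums(din), 1)
  colnames(din) <- paste0("din_", colnames(din))
  out <- bind_cols(
    tibble(gene = records$gene, gc = unname(gc)),
    as_tibble(din),
    tibble(width = nchar(seqs))
  )
  if (!is.null(conservation)) {
    assert_columns(conservation, c("gene", "conservation"))
    out <- left_join(out, conservation, by = "gene")
  }
  out
}

#' Per-3'UTR mean cross-link signal of one or more tracks
#'
#' For every track sample, the per-UTR mean of per-nucleotide cDNA counts
#' (sum of counts divided by UTR width). UTRs absent from a track get 0.
#'
#' @param track cross-link track tibble (`sample`, `gene`, `pos`, `count`).
#' @param records tibble with `gene`, `width`.
#' @return tibble with `gene` and one `clip_<sample>` column per sample.
#' @export
aggregate_track_features <- function(track, records) {
  assert_columns(track, c("sample", "gene", "pos", "count"))
  assert_columns(records, c("gene", "width"))
  if (nrow(track) > 0 && !all(track$gene %in% records$gene)) {
    warn("track contains genes absent from the records; they are ignored")
  }
  samples <- unique(track$sample)
  if (length(samples) == 0) samples <- "track"
  sums <- track %>%
    filter(.data$gene %in% records$gene) %>%
    group_by(.data$sample, .data$gene) %>%
    summarise(total = sum(.data$count), .groups = "drop")
  grid <- tidyr::crossing(sample = samples,
                          records %>% select("gene", "width")) %>%
    left_join(sums, by = c("sample", "gene")) %>%
    mutate(mean_signal = dplyr::coalesce(.data$total, 0L) / .data$width)
  grid %>%
    mutate(sample = paste0("clip_", .data$sample)) %>%
    select("gene", "sample", "mean_signal") %>%
    tidyr::pivot_wider(names_from = "sample", values_from = "mean_signal")
}

#' Assemble a stability feature matrix
#'
#' Joins simple sequence features, track-derived features and any external
#' per-UTR score columns, attaches the stability label, drops rows with
#' missing values and removes zero-variance feature columns.
#'
#' @param records UTR records tibble.
#' @param labels tibble with `gene`, `label` (two classes).
#' @param tracks optional cross-link track (possibly several samples).
#' @param external optional tibble of additional per-gene score columns
#'   (first column `gene`).
#' @return tibble with `gene`, `label` and feature columns.
#' @export
build_feature_matrix <- function(records, labels, tracks = NULL, external = NULL) {
  assert_columns(labels, c("gene", "label"))
  X <- compute_simple_features(records)
  if (!is.null(tracks)) {
    X <- left_join(X, aggregate_track_features(tracks, records), by = "gene")
  }
  if (!is.null(external)) X <- left_join(X, external, by = "gene")
  X <- inner_join(labels, X, by = "gene")
  X <- X[complete.cases(X), , drop = FALSE]
  feats <- setdiff(names(X), c("gene", "label"))
  keep <- vapply(X[feats], function(col) stats::var(col) > 0, logical(1))
  dropped <- feats[!keep]
  if (length(dropped) > 0) {
    inform(sprintf("dropping %d zero-variance feature(s): %s",
                   length(dropped), paste(head(dropped, 5), collapse = ", ")))
  }
  X %>% select(all_of(c("gene", "label", feats[keep])))
}
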