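# Ground-truthed synthetic data: 3'UTR sequences, cross-link tracks,
# conversion kinetics and expression/DE tables. Coordinates are 1-based and
# strand is "+" throughout the simulator; BED I/O converts to 0-based
# half-open at the boundary.

AUU_FAMILY_5MERS <- c("ATTAT", "TTATT", "ATTTA", "TATTT", "ATTAA", "TTATA")

#' Generate a synthetic 3'UTR transcriptome with ground truth
#'
#' Each simulated gene gets one plus-strand 3'UTR containing exactly one
#' terminal canonical PAS whose end lies at least 20 nt from the 3' end.
#' AUU-family 5-mers are planted in the `terminal_window` nt upstream of the
#' PAS with a per-class Poisson rate, so down-class UTRs carry elevated AUU
#' valency. Background composition is i.i.d. with the configured G+C.
#'
#' @param cfg a [sim_config()].
#' @return a list with
#'   * `records`: tibble with `gene`, `class`, `width`, `seq`, `pas_start`
#'     (1-based start of the planted PAS);
#'   * `truth`: a `sim_truth` object — tibbles `genes` (true class, per-condition
#'     half-life, PAS), `motifs` (planted motif positions) and `hotspots`
#'     (true cross-link hotspot centers per condition).
#' @export
generate_transcriptome <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(derive_seed(cfg$seed, "transcriptome"))

  classes <- c("down", "up", "control")
  n_per <- allocate_counts(cfg$n_genes, cfg$class_proportions[classes])
  class_vec <- rep(classes, n_per)
  gene_ids <- sprintf("gene%05d", seq_len(cfg$n_genes))

  widths <- sample(seq(cfg$utr_length_range[1], cfg$utr_length_range[2]),
                   cfg$n_genes, replace = TRUE)
  base_probs <- c(A = (1 - cfg$gc) / 2, C = cfg$gc / 2, G = cfg$gc / 2, T = (1 - cfg$gc) / 2)

  seqs <- character(cfg$n_genes)
  pas_starts <- integer(cfg$n_genes)
  motif_rows <- vector("list", cfg$n_genes)

  for (i in seq_len(cfg$n_genes)) {
    len <- widths[i]
    s <- sample(DNA_BASES, len, replace = TRUE, prob = base_probs)
    # terminal PAS: end sits 20-30 nt from the 3' end
    tail_choices <- 20:min(30L, len - cfg$terminal_window - 6L)
    tail_len <- tail_choices[sample.int(length(tail_choices), 1)]
    pas_start <- len - tail_len - 6L + 1L

    # plant AUU-family motifs in the terminal window upstream of the PAS
    n_motif <- rpois(1, cfg$planted_motif_rates[[class_vec[i]]])
    slot_lo <- pas_start - cfg$terminal_window
    slot_hi <- pas_start - 5L
    starts <- integer(0)
    if (n_motif > 0) {
      starts <- sort(sample(seq(slot_lo, slot_hi), min(n_motif, slot_hi - slot_lo + 1)))
      kmers <- sample(AUU_FAMILY_5MERS, length(starts), replace = TRUE)
      for (j in seq_along(starts)) {
        s[starts[j]:(starts[j] + 4L)] <- strsplit(kmers[j], "")[[1]]
      }
      motif_rows[[i]] <- tibble(gene = gene_ids[i], start = starts, kmer = kmers)
    }
    s[pas_start:(pas_start + 5L)] <- strsplit(cfg$pas_motif, "")[[1]]
    seq_str <- paste(s, collapse = "")

    # scrub every non-planted PAS match so the terminal one is unique
    repeat {
      hits <- setdiff(find_motif_starts(seq_str, cfg$pas_motif), pas_start)
      if (length(hits) == 0) break
      for (h in hits) substr(seq_str, h + 2L, h + 2L) <- "C"
    }
    seqs[i] <- seq_str
    pas_starts[i] <- pas_start
  }

  records <- tibble(
    gene = gene_ids, class = class_vec, width = widths,
    seq = seqs, pas_start = pas_starts
  )

  hl_naive <- runif(cfg$n_genes, cfg$halflife_range[1], cfg$halflife_range[2])
  hl_primed <- ifelse(class_vec == "down", hl_naive / cfg$destabilization_factor, hl_naive)

  motifs <- bind_rows(motif_rows)
  if (nrow(motifs) == 0) motifs <- tibble(gene = character(), start = integer(), kmer = character())

  # hotspots: uniform in the naive condition; in the primed (+MEK) condition
  # the down-class hotspots sit on the planted terminal AUU motifs
  hot_naive <- tibble(
    gene = rep(gene_ids, each = 2),
    condition = "naive",
    pos = as.integer(unlist(lapply(widths, function(w) sample(seq_len(w), 2))))
  )
  down_motifs <- motifs %>% filter(gene %in% gene_ids[class_vec == "down"])
  hot_primed <- bind_rows(
    hot_naive %>% filter(!gene %in% unique(down_motifs$gene)),
    tibble(gene = down_motifs$gene, condition = "naive", pos = down_motifs$start + 2L)
  ) %>% mutate(condition = "primed")
  hotspots <- bind_rows(hot_naive, hot_primed) %>% arrange(.data$condition, .data$gene, .data$pos)

  truth <- structure(
    list(
      genes = tibble(
        gene = gene_ids, class = class_vec, width = widths, pas_start = pas_starts,
        halflife_naive = hl_naive, halflife_primed = hl_primed
      ),
      motifs = motifs,
      hotspots = hotspots,
      seed = cfg$seed
    ),
    class = "sim_truth"
  )
  list(records = records, truth = truth)
}

#' Simulate a per-nucleotide cross-link track
#'
#' Counts are drawn from a mixture of a uniform background and hotspot windows
#' (`+/- hotspot_halfwidth` around the truth hotspot centers of the requested
#' condition). In the primed (MEK-activated) condition the down-class hotspots
#' coincide with the planted terminal AUU motifs, so the regulator signal
#' relocates toward 3'UTR termini. The expected total cDNA count is
#' `crosslink_depth * n_genes`.
#'
#' @param records,truth output of [generate_transcriptome()].
#' @param condition `"naive"` or `"primed"`.
#' @param cfg the [sim_config()] used for generation.
#' @param sample_id sample name stored in the track.
#' @return a cross-link track: tibble with `sample`, `condition`, `gene`,
#'   `pos` (1-based), `count`.
#' @export
simulate_crosslinks <- function(records, truth, condition, cfg,
                                sample_id = paste0("clip_", condition)) {
  if (!condition %in% c("naive", "primed")) {
    abort(sprintf("unknown condition tag '%s' (expected 'naive' or 'primed')", condition))
  }
  stopifnot(inherits(truth, "sim_truth"))
  set.seed(derive_seed(cfg$seed, paste0("crosslinks_", condition, "_", sample_id)))

  hs <- truth$hotspots %>% filter(.data$condition == !!condition)
  hs_by_gene <- split(hs$pos, hs$gene)

  rows <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    g <- records$gene[i]
    len <- records$width[i]
    n <- rpois(1, cfg$crosslink_depth)
    if (n == 0) next
    from_bg <- runif(n) < cfg$background_weight
    pos <- integer(n)
    if (any(from_bg)) pos[from_bg] <- sample(seq_len(len), sum(from_bg), replace = TRUE)
    n_hot <- sum(!from_bg)
    if (n_hot > 0) {
      centers <- hs_by_gene[[g]]
      ctr <- centers[sample.int(length(centers), n_hot, replace = TRUE)]
      offsets <- seq(-cfg$hotspot_halfwidth, cfg$hotspot_halfwidth)
      jitter <- offsets[sample.int(length(offsets), n_hot, replace = TRUE)]
      pos[!from_bg] <- pmin(pmax(ctr + jitter, 1L), len)
    }
    tab <- table(pos)
    rows[[i]] <- tibble(
      gene = g, pos = as.integer(names(tab)), count = as.integer(tab)
    )
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) out <- tibble(gene = character(), pos = integer(), count = integer())
  tibble(sample = sample_id, condition = condition) %>%
    tidyr::crossing(out) %>%
    select("sample", "condition", "gene", "pos", "count") %>%
    arrange(.data$gene, .data$pos)
}

#' Simulate metabolic-labeling conversion time courses
#'
#' Normalized conversion at chase time `t` is `exp(-lambda * t)` plus additive
#' Gaussian noise truncated at 0, where `lambda = ln(2) / true half-life` of
#' the gene in the given condition.
#'
#' @param truth a `sim_truth`.
#' @param timepoints chase times in hours; must include 0 and be non-negative.
#' @param cfg the [sim_config()].
#' @param conditions conditions to simulate.
#' @return tibble with `gene`, `condition`, `time_h`, `value`.
#' @export
simulate_slamseq <- function(truth, timepoints = c(0, 1, 2, 6, 12, 24), cfg,
                             conditions = c("naive", "primed")) {
  stopifnot(inherits(truth, "sim_truth"))
  if (any(timepoints < 0)) abort("timepoints must be non-negative")
  if (!0 %in% timepoints) abort("timepoints must include 0")
  timepoints <- sort(unique(timepoints))
  set.seed(derive_seed(cfg$seed, "slamseq"))

  purrr::map_dfr(conditions, function(cond) {
    hl <- truth$genes[[paste0("halflife_", cond)]]
    lam <- log(2) / hl
    tidyr::crossing(gene = truth$genes$gene, time_h = timepoints) %>%
      left_join(tibble(gene = truth$genes$gene, lambda = lam), by = "gene") %>%
      mutate(
        condition = cond,
        value = pmax(0, exp(-.data$lambda * .data$time_h) +
                       rnorm(dplyr::n(), 0, cfg$noise_sd))
      ) %>%
      select("gene", "condition", "time_h", "value")
  })
}

#' Simulate expression (TPM) and differential-expression tables
#'
#' TPM values are log-normal (shifted so every gene clears the 5-TPM
#' expression filter); the DE table is constructed so that truth-down genes
#' pass the downregulated thresholds (`log2FC <= -log2(1.5)`, `padj < 0.05`),
#' truth-up genes the upregulated thresholds, and truth-control genes the
#' control gate (`|log2FC| < 0.5`, `padj >= 0.05`).
#'
#' @param truth a `sim_truth`.
#' @param cfg the [sim_config()].
#' @param n_reps replicates per condition.
#' @return list with `tpm` (tibble `gene`, `condition`, `replicate`, `tpm`) and
#'   `de` (tibble `gene`, `log2fc`, `padj`, `biotype`).
#' @export
simulate_expression_and_de <- function(truth, cfg, n_reps = 2) {
  stopifnot(inherits(truth, "sim_truth"))
  set.seed(derive_seed(cfg$seed, "expression"))
  genes <- truth$genes

  log2fc <- dplyr::case_when(
    genes$class == "down" ~ -runif(nrow(genes), log2(1.5), 3),
    genes$class == "up" ~ runif(nrow(genes), log2(1.5), 3),
    TRUE ~ runif(nrow(genes), -0.49, 0.49)
  )
  padj <- ifelse(genes$class == "control",
                 runif(nrow(genes), 0.05, 1),
                 10^runif(nrow(genes), -8, log10(0.049)))
  de <- tibble(gene = genes$gene, log2fc = log2fc, padj = padj,
               biotype = "protein_coding")

  base <- 5 + rlnorm(nrow(genes), meanlog = log(30), sdlog = 0.6)
  tpm <- tidyr::crossing(
    tibble(gene = genes$gene, base = base, log2fc = log2fc),
    condition = c("naive", "primed"), replicate = seq_len(n_reps)
  ) %>%
    mutate(
      mu = ifelse(.data$condition == "primed", .data$base * 2^.data$log2fc, .data$base),
      tpm = .data$mu * rlnorm(dplyr::n(), 0, 0.05)
    ) %>%
    select("gene", "condition", "replicate", "tpm")

  list(tpm = tpm, de = de)
}

#' Write / read ground truth as plain TSV
#'
#' Three TSV files (`<prefix>_genes.tsv`, `<prefix>_motifs.tsv`,
#' `<prefix>_hotspots.tsv`), each with a `# seed:` header comment. Reading
#' them back reconstructs the `sim_truth` losslessly.
#'
#' @param truth a `sim_truth`.
#' @param prefix path prefix for the three files.
#' @return `write_truth()` returns the file paths invisibly; `read_truth()`
#'   returns a `sim_truth`.
#' @export
write_truth <- function(truth, prefix) {
  stopifnot(inherits(truth, "sim_truth"))
  paths <- paste0(prefix, "_", c("genes", "motifs", "hotspots"), ".tsv")
  for (i in seq_along(paths)) {
    tab <- truth[[c("genes", "motifs", "hotspots")[i]]]
    writeLines(sprintf("# seed: %d", truth$seed), paths[i])
    suppressMessages(readr::write_tsv(tab, paths[i], append = TRUE, col_names = TRUE))
  }
  invisible(paths)
}

#' @rdname write_truth
#' @export
read_truth <- function(prefix) {
  paths <- paste0(prefix, "_", c("genes", "motifs", "hotspots"), ".tsv")
  seed <- as.integer(sub("# seed: ", "", readLines(paths[1], n = 1)))
  tabs <- lapply(paths, function(p) {
    readr::read_tsv(p, comment = "#", show_col_types = FALSE,
                    progress = FALSE)
  })
  structure(
    list(
      genes = tabs[[1]] %>% mutate(across(all_of(c("width", "pas_start")), as.integer)),
      motifs = tabs[[2]] %>% mutate(across(all_of("start"), as.integer)),
      hotspots = tabs[[3]] %>% mutate(across(all_of("pos"), as.integer)),
      seed = seed
    ),
    class = "sim_truth"
  )
}
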