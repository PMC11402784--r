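# End-to-end orchestration: simulate -> half-lives -> regulation groups ->
# features/boosted classifier -> motif groups -> metaprofiles -> sequence
# model -> report. One global seed fans out to fixed per-stage seeds so
# toggling a stage never shifts another stage's randomness.

PIPELINE_STAGES <- c("slamseq", "groups", "gbm", "motifs", "clip", "seqmodel")

#' Default pipeline configuration
#'
#' @param sim named list of [sim_config()] overrides.
#' @param stages named logical vector enabling stages (missing stages default
#'   to `TRUE`; `seqmodel` defaults to `FALSE` because it is by far the most
#'   expensive stage).
#' @param params named list of per-stage parameter blocks.
#' @param seed global seed.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(sim = list(), stages = list(), params = list(),
                            seed = 1L) {
  cfg <- list(sim = sim, stages = stages, params = params, seed = seed)
  errs <- validate_config(cfg)
  if (length(errs) > 0) {
    abort(paste0("invalid pipeline configuration:\n",
                 paste("-", errs, collapse = "\n")))
  }
  stage_flags <- setNames(rep(TRUE, length(PIPELINE_STAGES)), PIPELINE_STAGES)
  stage_flags["seqmodel"] <- FALSE
  stage_flags[names(cfg$stages)] <- unlist(cfg$stages)
  cfg$stages <- as.list(stage_flags)
  cfg$sim_config <- do.call(sim_config, c(cfg$sim, list(seed = derive_seed(seed, "sim"))))
  structure(cfg, class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Accepts a YAML file path or a configuration list and enumerates every
#' schema violation (unknown keys, unknown stages, invalid simulation
#' parameters) without running anything.
#'
#' @param config path to a YAML file or a configuration list.
#' @return character vector of error messages; empty when the configuration
#'   is valid.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    config <- tryCatch(yaml::read_yaml(config), error = function(e) e)
    if (inherits(config, "error")) {
      return(sprintf("unparseable configuration file: %s", conditionMessage(config)))
    }
  }
  errs <- character(0)
  known <- c("sim", "stages", "params", "seed", "sim_config")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0) {
    errs <- c(errs, sprintf("unknown top-level key(s): %s", paste(unknown, collapse = ", ")))
  }
  if (!is.null(config$stages)) {
    bad <- setdiff(names(config$stages), PIPELINE_STAGES)
    if (length(bad) > 0) {
      errs <- c(errs, sprintf("unknown stage key(s): %s", paste(bad, collapse = ", ")))
    }
  }
  if (!is.null(config$seed) && (!is.numeric(config$seed) || length(config$seed) != 1)) {
    errs <- c(errs, "seed must be a single number")
  }
  if (!is.null(config$sim)) {
    bad <- setdiff(names(config$sim), names(formals(sim_config)))
    if (length(bad) > 0) {
      errs <- c(errs, sprintf("unknown simulation key(s): %s", paste(bad, collapse = ", ")))
    }
    sim_try <- tryCatch(
      {do.call(sim_config, config$sim[setdiff(names(config$sim), "")]); NULL},
      error = function(e) conditionMessage(e)
    )
    if (!is.null(sim_try)) errs <- c(errs, sprintf("simulation: %s", sim_try))
  }
  if (!is.null(config$params)) {
    bad <- setdiff(names(config$params), PIPELINE_STAGES)
    if (length(bad) > 0) {
      errs <- c(errs, sprintf("unknown parameter block(s): %s", paste(bad, collapse = ", ")))
    }
  }
  errs
}

stage_manifest <- function(dir, stage, params, seed, outputs) {
  manifest <- list(
    stage = stage, parameters = params, seed = seed,
    outputs = lapply(outputs, function(x) {
      list(value = class(x)[1], hash = rlang::hash(x))
    })
  )
  path <- file.path(dir, sprintf("manifest_%s.json", stage))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  manifest
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes the enabled stages in dependency order, writing per-stage JSON
#' manifests (parameters, seed, output hashes) and a collated `report.md`
#' under `out_dir`. Rerunning with the same configuration reproduces
#' identical manifests for the deterministic stages.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory, created if missing.
#' @return (invisibly) a named list with the results of every stage that ran.
#' @export
run_pipeline <- function(config, out_dir = tempfile("poised_run_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- config$params
  res <- list()
  report <- c("# Pipeline report", "")

  # --- simulation (always) ------------------------------------------------
  scfg <- config$sim_config
  sim <- generate_transcriptome(scfg)
  tracks <- list(
    naive = simulate_crosslinks(sim$records, sim$truth, "naive", scfg),
    primed = simulate_crosslinks(sim$records, sim$truth, "primed", scfg)
  )
  exprs <- simulate_expression_and_de(sim$truth, scfg)
  write_utr_fasta(sim$records, file.path(out_dir, "utrs.fa"))
  write_truth(sim$truth, file.path(out_dir, "truth"))
  write_crosslink_bed(bind_rows(tracks), file.path(out_dir, "crosslinks.bed"),
                      seed = scfg$seed)
  write_table_tsv(exprs$tpm, file.path(out_dir, "tpm.tsv"), seed = scfg$seed)
  write_table_tsv(exprs$de, file.path(out_dir, "de.tsv"), seed = scfg$seed)
  res$sim <- sim
  stage_manifest(out_dir, "simulate", unclass(scfg), scfg$seed,
                 list(records = sim$records, truth = sim$truth$genes))
  report <- c(report, sprintf("- simulate: %d genes (%s)", nrow(sim$records),
                              paste(names(table(sim$records$class)),
                                    table(sim$records$class),
                                    sep = "=", collapse = ", ")))

  expr_naive <- exprs$tpm %>%
    filter(.data$condition == "naive") %>%
    group_by(.data$gene) %>% summarise(tpm = mean(.data$tpm), .groups = "drop")

  # --- half-lives ---------------------------------------------------------
  if (isTRUE(config$stages$slamseq)) {
    pp <- p$slamseq %||% list()
    series <- simulate_slamseq(sim$truth, pp$timepoints %||% c(0, 1, 2, 6, 12, 24), scfg)
    fits <- fit_halflife(series)
    kept <- filter_fits(fits, pp$r2_min %||% 0.6)
    n_top <- pp$n_top %||% sum(sim$truth$genes$class == "down")
    classes <- rank_delta_halflife(
      fits %>% filter(.data$condition == "naive", .data$gene %in% kept),
      fits %>% filter(.data$condition == "primed", .data$gene %in% kept),
      n_top = n_top
    )
    res$slamseq <- list(fits = fits, kept = kept, classes = classes)
    write_table_tsv(fits, file.path(out_dir, "halflife_fits.tsv"), seed = scfg$seed)
    write_table_tsv(classes, file.path(out_dir, "stability_classes.tsv"), seed = scfg$seed)
    stage_manifest(out_dir, "slamseq", pp, scfg$seed,
                   list(fits = fits, classes = classes))
    recov <- mean(sim$truth$genes$gene[sim$truth$genes$class == "down"] %in%
                    classes$gene[classes$label == "decreased"])
    report <- c(report, sprintf(
      "- slamseq: %d/%d fits kept (R2 gate), down-class label recovery %.1f%%",
      length(kept), dplyr::n_distinct(fits$gene), 100 * recov))
  }

  # --- regulation groups --------------------------------------------------
  if (isTRUE(config$stages$groups)) {
    annotation <- sim$records %>%
      transmute(gene = .data$gene, utr_length = .data$width,
                biotype = "protein_coding")
    groups <- assign_regulation_groups(exprs$de, annotation, exprs$tpm)
    res$groups <- groups
    write_table_tsv(groups, file.path(out_dir, "regulation_groups.tsv"), seed = scfg$seed)
    stage_manifest(out_dir, "groups", list(), scfg$seed, list(groups = groups))
    report <- c(report, sprintf("- groups: %s",
                                paste(names(table(groups$class)), table(groups$class),
                                      sep = "=", collapse = ", ")))
  }

  # --- features + boosted classifier -------------------------------------
  if (isTRUE(config$stages$gbm)) {
    if (is.null(res$slamseq)) {
      abort("stage 'gbm' needs stage 'slamseq' (stability labels); enable it")
    }
    pp <- p$gbm %||% list()
    labels <- res$slamseq$classes %>%
      transmute(gene = .data$gene,
                label = ifelse(.data$label == "decreased", "decreased",
                               "stable_or_increased"))
    X <- build_feature_matrix(sim$records, labels, tracks = bind_rows(tracks))
    model <- train_stability_classifier(
      X, split_seed = derive_seed(config$seed, "gbm"),
      grid = gbm_grid(full = isTRUE(pp$full_grid)),
      cv_repeats = pp$cv_repeats %||% 5
    )
    res$gbm <- model
    write_table_tsv(tidy(model), file.path(out_dir, "gbm_importance.tsv"), seed = config$seed)
    stage_manifest(out_dir, "gbm",
                   c(pp, model$best_params), derive_seed(config$seed, "gbm"),
                   list(glance = glance(model)))
    report <- c(report, sprintf("- gbm: hold-out AUROC %.3f, accuracy %.3f, MCC %.3f",
                                model$eval$auroc, model$eval$accuracy, model$eval$mcc))
  }

  # --- motif groups -------------------------------------------------------
  if (isTRUE(config$stages$motifs)) {
    pp <- p$motifs %||% list()
    stats_by_sample <- purrr::imap(tracks, function(tr, nm) {
      kmer_enrichment(tr, sim$records, k = pp$k %||% 5,
                      n_shuffle = pp$n_shuffle %||% 100,
                      seed = derive_seed(config$seed, paste0("kmer_", nm))) %>%
        mutate(sample = nm)
    })
    top <- bind_rows(stats_by_sample) %>%
      filter(.data$p < 0.05) %>%
      distinct(.data$kmer) %>% pull("kmer")
    enriched <- bind_rows(stats_by_sample) %>% filter(.data$kmer %in% top)
    if (length(top) >= (pp$n_clusters %||% 4)) {
      jac <- jaccard_distance_matrix(top)
      rnk <- rank_distance_matrix(enriched)
      common <- intersect(rownames(jac), rownames(rnk))
      comb <- combine_distances(rnk[common, common], jac[common, common])
      groups <- cluster_kmers(comb, n_clusters = pp$n_clusters %||% 4)
      res$motifs <- list(stats = enriched, groups = groups)
      write_table_tsv(groups, file.path(out_dir, "motif_groups.tsv"), seed = config$seed)
      stage_manifest(out_dir, "motifs", pp, config$seed, list(groups = groups))
      report <- c(report, sprintf("- motifs: %d enriched k-mers in %d groups",
                                  length(common), dplyr::n_distinct(groups$group)))
    } else {
      report <- c(report, "- motifs: too few enriched k-mers to cluster")
    }
  }

  # --- metaprofiles -------------------------------------------------------
  if (isTRUE(config$stages$clip)) {
    pp <- p$clip %||% list()
    regs <- sim$records %>% select("gene", "width", "pas_start", "class")
    prof <- purrr::map(
      setNames(c("down", "control"), c("down", "control")),
      function(cl) {
        metaprofile(
          tracks$primed, regs %>% filter(.data$class == cl), expr_naive,
          anchor = "pas", span_up = pp$span_up %||% 100, span_down = pp$span_down %||% 20,
          min_length = pp$min_length %||% 130,
          n_boot = pp$n_boot %||% 1000,
          seed = derive_seed(config$seed, paste0("meta_", cl))
        )
      }
    )
    res$clip <- prof
    write_table_tsv(bind_rows(purrr::imap(prof, ~mutate(.x, class = .y))),
                    file.path(out_dir, "metaprofile_pas.tsv"), seed = config$seed)
    stage_manifest(out_dir, "clip", pp, config$seed, prof)
    report <- c(report, sprintf(
      "- clip: mean terminal coverage down %.3g vs control %.3g (CPM/TPM)",
      mean(prof$down$mean[prof$down$offset < 0]),
      mean(prof$control$mean[prof$control$offset < 0])))
  }

  # --- sequence model -----------------------------------------------------
  if (isTRUE(config$stages$seqmodel)) {
    pp <- p$seqmodel %||% list()
    recs <- sim$records %>% filter(.data$class %in% c("up", "down"))
    ds <- encode_and_split(recs, seed = derive_seed(config$seed, "seqsplit"))
    cfg_nn <- do.call(seq_model_config,
                      c(pp, list(seed = derive_seed(config$seed, "seqmodel"))))
    model <- train_seq_classifier(ds, cfg_nn)
    res$seqmodel <- model
    stage_manifest(out_dir, "seqmodel", unclass(cfg_nn),
                   derive_seed(config$seed, "seqmodel"),
                   list(metrics = model$metrics))
    report <- c(report, sprintf("- seqmodel: test AUROC %.3f, accuracy %.3f",
                                model$metrics$auroc, model$metrics$accuracy))
  } else {
    report <- c(report, "- seqmodel: disabled (not run)")
  }

  writeLines(report, file.path(out_dir, "report.md"))
  res$out_dir <- out_dir
  invisible(res)
}
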