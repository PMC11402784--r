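# Synthetic-data generator: ground truth, determinism, planted signal.

test_that("class proportions are exact on divisible n and config is validated", {
  cfg <- sim_config(n_genes = 6, seed = 1)
  sim <- generate_transcriptome(cfg)
  expect_equal(unname(table(sim$records$class)[c("down", "up", "control")]),
               rep(2L, 3), ignore_attr = TRUE)
  expect_error(sim_config(utr_length_range = c(100, 200), terminal_window = 100),
               "terminal window")
  expect_error(sim_config(class_proportions = c(down = 0.5, up = 0.5, control = 0.5)),
               "sum to 1")
})

test_that("every UTR carries exactly one terminal canonical PAS >= 20 nt from the 3' end", {
  sim <- small_sim(n_genes = 50, seed = 3)
  for (i in seq_len(nrow(sim$records))) {
    s <- sim$records$seq[i]
    hits <- gregexpr("(?=AATAAA)", s, perl = TRUE)[[1]]
    valid <- hits[hits + 5 <= nchar(s) - 20]
    expect_identical(as.integer(valid), sim$records$pas_start[i])
  }
})

test_that("planted motif truth lies inside the terminal window and drives trimer counts", {
  cfg <- sim_config(n_genes = 2000,
                    planted_motif_rates = c(down = 8, up = 2.4, control = 3),
                    seed = 11)
  sim <- generate_transcriptome(cfg)
  m <- dplyr::left_join(sim$truth$motifs,
                        sim$records[, c("gene", "pas_start", "width")], by = "gene")
  expect_true(all(m$start >= m$pas_start - cfg$terminal_window))
  expect_true(all(m$start + 4 <= m$width))
  # planted count recovers the Poisson rate (Monte-Carlo mean over 2,000 genes)
  per_gene <- dplyr::count(m, .data$gene)
  per_gene <- dplyr::left_join(sim$records[, c("gene", "class")], per_gene, by = "gene")
  per_gene$n[is.na(per_gene$n)] <- 0
  mean_down <- mean(per_gene$n[per_gene$class == "down"])
  expect_lt(abs(mean_down - 8), 0.5)
})

test_that("identical seeds give byte-identical FASTA and truth files", {
  dir <- withr::local_tempdir()
  for (run in 1:2) {
    sim <- small_sim(n_genes = 20, seed = 5)
    write_utr_fasta(sim$records, file.path(dir, sprintf("r%d.fa", run)))
    write_truth(sim$truth, file.path(dir, sprintf("r%d", run)))
  }
  expect_identical(readLines(file.path(dir, "r1.fa")),
                   readLines(file.path(dir, "r2.fa")))
  for (part in c("genes", "motifs", "hotspots")) {
    expect_identical(readLines(file.path(dir, sprintf("r1_%s.tsv", part))),
                     readLines(file.path(dir, sprintf("r2_%s.tsv", part))))
  }
})

test_that("truth round-trips losslessly through TSV", {
  sim <- small_sim(n_genes = 15, seed = 9)
  dir <- withr::local_tempdir()
  write_truth(sim$truth, file.path(dir, "t"))
  back <- read_truth(file.path(dir, "t"))
  expect_equal(back$genes, sim$truth$genes)
  expect_equal(back$motifs, sim$truth$motifs)
  expect_equal(back$hotspots, sim$truth$hotspots)
  expect_identical(back$seed, sim$truth$seed)
})

test_that("cross-link simulation respects the mixture, depth and condition contract", {
  sim <- small_sim(n_genes = 30, seed = 2, background_weight = 0)
  tr <- simulate_crosslinks(sim$records, sim$truth, "naive", sim$cfg)
  hs <- sim$truth$hotspots[sim$truth$hotspots$condition == "naive", ]
  for (i in seq_len(nrow(tr))) {
    centers <- hs$pos[hs$gene == tr$gene[i]]
    expect_true(min(abs(tr$pos[i] - centers)) <= sim$cfg$hotspot_halfwidth)
  }
  expect_error(simulate_crosslinks(sim$records, sim$truth, "mek", sim$cfg),
               "unknown condition")

  cfg0 <- sim_config(n_genes = 10, crosslink_depth = 0, seed = 2)
  sim0 <- generate_transcriptome(cfg0)
  tr0 <- simulate_crosslinks(sim0$records, sim0$truth, "naive", cfg0)
  expect_identical(nrow(tr0), 0L)
  p <- withr::local_tempfile(fileext = ".bed")
  write_crosslink_bed(tr0, p)
  expect_identical(nrow(read_crosslink_bed(p)), 0L)
})

test_that("primed-condition signal relocates to down-class terminal windows", {
  cfg <- sim_config(n_genes = 500, seed = 13)
  sim <- generate_transcriptome(cfg)
  tr <- simulate_crosslinks(sim$records, sim$truth, "primed", cfg)
  term_mean <- function(classes) {
    recs <- sim$records[sim$records$class %in% classes, ]
    vapply(seq_len(nrow(recs)), function(i) {
      tg <- tr[tr$gene == recs$gene[i], ]
      lo <- recs$pas_start[i] - 100
      sum(tg$count[tg$pos >= lo & tg$pos < recs$pas_start[i]])
    }, numeric(1))
  }
  wt <- stats::wilcox.test(term_mean("down"), term_mean("control"),
                           alternative = "greater")
  expect_lt(wt$p.value, 0.01)
})

test_that("conversion kinetics follow the closed form and the truth table is exact", {
  cfg <- sim_config(n_genes = 12, noise_sd = 0, destabilization_factor = 2, seed = 4)
  sim <- generate_transcriptome(cfg)
  ss <- simulate_slamseq(sim$truth, timepoints = c(0, 1, 2), cfg = cfg)
  t0 <- ss[ss$time_h == 0, ]
  expect_true(all(t0$value == 1))
  one <- ss[ss$time_h == 1 & ss$condition == "naive", ]
  lam <- log(2) / sim$truth$genes$halflife_naive[match(one$gene, sim$truth$genes$gene)]
  expect_equal(one$value, exp(-lam), tolerance = 1e-12)
  down <- sim$truth$genes[sim$truth$genes$class == "down", ]
  expect_equal(down$halflife_primed, down$halflife_naive / 2)
  other <- sim$truth$genes[sim$truth$genes$class != "down", ]
  expect_equal(other$halflife_primed, other$halflife_naive)
  expect_error(simulate_slamseq(sim$truth, timepoints = c(-1, 0, 1), cfg = cfg),
               "non-negative")
  expect_error(simulate_slamseq(sim$truth, timepoints = c(1, 2), cfg = cfg),
               "include 0")
})

test_that("expression/DE tables are consistent with the truth classes", {
  sim <- small_sim(n_genes = 45, seed = 6)
  ex <- simulate_expression_and_de(sim$truth, sim$cfg)
  expect_true(all(ex$tpm$tpm > 0))
  expect_equal(nrow(dplyr::distinct(ex$tpm, condition, replicate)), 4L)
  ann <- dplyr::tibble(gene = sim$records$gene, utr_length = sim$records$width,
                       biotype = "protein_coding")
  groups <- assign_regulation_groups(ex$de, ann, ex$tpm)
  merged <- dplyr::left_join(groups, sim$truth$genes[, c("gene", "class")],
                             by = "gene", suffix = c("_called", "_true"))
  expect_true(all(merged$class_called[merged$class_true == "down"] == "down"))
  expect_true(all(merged$class_called[merged$class_true == "control"] == "control"))
})

test_that("sim configuration round-trips through YAML", {
  cfg <- sim_config(n_genes = 33, gc = 0.41, seed = 17)
  p <- withr::local_tempfile(fileext = ".yml")
  write_sim_config(cfg, p)
  back <- read_sim_config(p)
  expect_equal(unclass(back), unclass(cfg))
})
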