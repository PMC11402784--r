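# Cross-link track normalization and positional summaries.

test_that("gene-level TPM sums transcripts then averages replicates", {
  tt <- tibble::tibble(
    transcript = c("t1", "t2", "t1", "t2"),
    gene = "g1", replicate = c(1, 1, 2, 2), tpm = c(3, 7, 3, 7)
  )
  expect_equal(gene_level_tpm(tt)$tpm, 10)
  reps <- tibble::tibble(transcript = "t1", gene = "g1",
                         replicate = c(1, 2), tpm = c(8, 12))
  expect_equal(gene_level_tpm(reps)$tpm, 10)
  expect_warning(out <- gene_level_tpm(
    tibble::tibble(transcript = c("t1", "t2"), gene = c("g1", NA),
                   replicate = 1, tpm = c(1, 5))), "without a gene id")
  expect_identical(out$gene, "g1")
})

test_that("normalization is CPM then per-TPM with exact arithmetic", {
  tr <- toy_track("g1", pos = 10, count = 5)
  tr$count <- 5L
  tr2 <- dplyr::bind_rows(tr, toy_track("g1", pos = 99, count = 499995))
  out <- normalize_coverage(tr2, flat_expr("g1", tpm = 5))
  expect_equal(out$cpm[out$pos == 10], 10)
  expect_equal(out$cpm_per_tpm[out$pos == 10], 2)
  # doubling the library halves every value
  doubled <- dplyr::bind_rows(tr2, toy_track("g1", pos = 50, count = 500000))
  out2 <- normalize_coverage(doubled, flat_expr("g1", tpm = 5))
  expect_equal(out2$cpm[out2$pos == 10], 5)
  expect_warning(normalize_coverage(tr2, flat_expr("g1", tpm = 0)), "zero/missing")
})

test_that("summed CPM over a track is one million", {
  sim <- small_sim(n_genes = 40, seed = 15)
  tr <- simulate_crosslinks(sim$records, sim$truth, "naive", sim$cfg)
  out <- normalize_coverage(tr, flat_expr(sim$records$gene))
  expect_equal(sum(out$cpm), 1e6, tolerance = 1e-6)
})

test_that("triangular smoothing normalizes, preserves constants, handles edges", {
  expect_equal(smooth_profile(rep(1, 40), 20), rep(1, 40))
  expect_equal(smooth_profile(c(5, 1, 9, 2), 1), c(5, 1, 9, 2))
  imp <- c(rep(0, 20), 1, rep(0, 20))
  sm <- smooth_profile(imp, 7)
  expect_equal(sum(sm[15:27]), 1, tolerance = 1e-12)   # kernel mass preserved
  expect_equal(sm[19], sm[23])                         # symmetric spread
  expect_warning(out <- smooth_profile(1:5, 10), "exceeds")
  expect_equal(out, 1:5)
})

test_that("metaprofile equals its naive per-position oracle on a 3-gene fixture", {
  set.seed(16)
  regions <- tibble::tibble(
    gene = c("g1", "g2", "g3"), width = c(400L, 420L, 380L),
    pas_start = c(350L, 360L, 320L)
  )
  track <- purrr::map_dfr(seq_len(3), function(i) {
    toy_track(regions$gene[i], pos = sample(regions$width[i], 30),
              count = sample(1:9, 30, TRUE))
  })
  expr <- tibble::tibble(gene = regions$gene, tpm = c(2, 5, 9))
  mp <- metaprofile(track, regions, expr, anchor = "pas", span_up = 200,
                    span_down = 50, min_length = 300, n_boot = 50, seed = 1)
  oracle <- naive_metaprofile(track, regions, expr, 200, 50)
  expect_equal(mp$mean, oracle, tolerance = 1e-9)
  expect_true(all(mp$ci_lo <= mp$mean + 1e-12 & mp$mean <= mp$ci_hi + 1e-12))
})

test_that("metaprofile degenerate cases: single region, disjoint halves, filters", {
  regions <- tibble::tibble(gene = "g1", width = 400L, pas_start = 350L)
  track <- toy_track("g1", pos = c(100, 200, 340), count = c(2, 3, 4))
  expr <- flat_expr("g1")
  mp <- metaprofile(track, regions, expr, anchor = "pas", n_boot = 10, seed = 2)
  expect_true(all(mp$ci_lo == mp$mean & mp$ci_hi == mp$mean))  # CI width 0
  expect_equal(mp$n[1], 1L)

  # two regions with disjoint half-signals: mean is the elementwise average
  regions2 <- tibble::tibble(gene = c("a", "b"), width = 400L,
                             pas_start = 300L)
  half1 <- toy_track("a", pos = 150, count = 10)
  half2 <- toy_track("b", pos = 320, count = 10)
  both <- dplyr::bind_rows(half1, half2)
  mp2 <- metaprofile(both, regions2, flat_expr(c("a", "b")), anchor = "pas",
                     n_boot = 10, seed = 3)
  pa <- metaprofile(both, regions2[1, ], flat_expr("a"), anchor = "pas",
                    n_boot = 10, seed = 3)
  pb <- metaprofile(both, regions2[2, ], flat_expr("b"), anchor = "pas",
                    n_boot = 10, seed = 3)
  expect_equal(mp2$mean, (pa$mean + pb$mean) / 2, tolerance = 1e-12)

  expect_error(metaprofile(track, regions, expr, anchor = "pas",
                           min_length = 1000), "no region survives")
})

test_that("bootstrap CIs are seed-reproducible and shrink with replication", {
  set.seed(17)
  base <- tibble::tibble(gene = paste0("g", 1:6), width = 400L, pas_start = 350L)
  track <- purrr::map_dfr(base$gene, function(g) {
    toy_track(g, pos = sample(400, 25), count = sample(1:5, 25, TRUE))
  })
  expr <- flat_expr(base$gene)
  m1 <- metaprofile(track, base, expr, anchor = "pas", n_boot = 200, seed = 4)
  m2 <- metaprofile(track, base, expr, anchor = "pas", n_boot = 200, seed = 4)
  expect_equal(m1, m2)
  # replicate every region 4x: CI width should drop roughly like 1/sqrt(n)
  rep4 <- purrr::map_dfr(0:3, function(k) {
    dplyr::mutate(base, gene = paste0(.data$gene, "_", k))
  })
  track4 <- purrr::map_dfr(0:3, function(k) {
    dplyr::mutate(track, gene = paste0(.data$gene, "_", k))
  })
  m4 <- metaprofile(track4, rep4, flat_expr(rep4$gene), anchor = "pas",
                    n_boot = 200, seed = 4)
  ratio <- mean(m4$ci_hi - m4$ci_lo) / mean(m1$ci_hi - m1$ci_lo)
  expect_lt(ratio, 0.75)
})

test_that("TPM scaling is exactly inverse in normalized coverage", {
  regions <- tibble::tibble(gene = "g1", width = 300L, pas_start = 250L)
  track <- toy_track("g1", pos = c(50, 240), count = c(5, 8))
  m1 <- metaprofile(track, regions, flat_expr("g1", 2), anchor = "pas",
                    n_boot = 10, seed = 5)
  m3 <- metaprofile(track, regions, flat_expr("g1", 6), anchor = "pas",
                    n_boot = 10, seed = 5)
  expect_equal(m1$mean, 3 * m3$mean, tolerance = 1e-12)
})

test_that("binned whole-region profiles honor the bin-width rules", {
  regions <- tibble::tibble(gene = "g1", width = 100L)
  uniform <- toy_track("g1", pos = 1:100, count = 2)
  out <- transcript_binned_metaprofile(uniform, regions, flat_expr("g1"))
  expect_equal(nrow(out), 100L)
  expect_lt(diff(range(out$mean)), 1e-9)          # flat signal, flat bins
  # 130-nt region: first 30 bins get 2 nt, later bins 1 nt
  r2 <- tibble::tibble(gene = "g2", width = 130L)
  t2 <- toy_track("g2", pos = 1:130, count = 1)
  out2 <- transcript_binned_metaprofile(t2, r2, flat_expr("g2"))
  expect_lt(diff(range(out2$mean)), 1e-9)         # per-width normalization
  # all signal in the last decile lands in bins 91..100
  t3 <- toy_track("g3", pos = 91:100, count = 3)
  out3 <- transcript_binned_metaprofile(t3, tibble::tibble(gene = "g3", width = 100L),
                                        flat_expr("g3"))
  expect_true(all(out3$mean[out3$bin >= 91] > 0))
  expect_true(all(out3$mean[out3$bin < 91] == 0))
  expect_warning(transcript_binned_metaprofile(
    toy_track("g4", pos = 5, count = 1),
    tibble::tibble(gene = "g4", width = 60L), flat_expr("g4")),
    "repeated boundaries")
})

test_that("per-UTR heat maps min-max rows with the degenerate-row convention", {
  regions <- tibble::tibble(gene = c("g1", "g2", "g3"), width = 3L,
                            pas_start = NA_integer_)
  tr <- dplyr::bind_rows(
    toy_track("g1", pos = 1:3, count = c(2, 4, 6)),
    toy_track("g3", pos = 1:3, count = c(5, 5, 5))
  )
  hm <- per_utr_heatmap(tr, regions, flat_expr(regions$gene), window = 1)
  expect_equal(unname(hm$matrix["g1", 1:3]), c(0, 0.5, 1))
  expect_equal(unname(hm$matrix["g2", 1:3]), c(0, 0, 0))  # all-zero row
  expect_equal(unname(hm$matrix["g3", 1:3]), c(0, 0, 0))  # constant row
  expect_equal(hm$abundance$abundance[1], sum(c(2, 4, 6)) * 1e6 / sum(tr$count) / 3)
})

test_that("binned log2 fold changes use percentage-plus-one arithmetic", {
  regions <- tibble::tibble(gene = "g1", width = 100L)
  a <- toy_track("g1", pos = c(10, 50), count = c(5, 5))
  same <- binned_log2fc(a, a, regions, bin_nt = 20, span = 100)
  expect_true(all(same$log2fc == 0))
  expect_equal(nrow(same), 5L)
  # empty bin in both conditions: log2(1/1) = 0
  expect_true(all(same$log2fc[same$pct_a == 0 & same$pct_b == 0] == 0))
  # percentages 3 vs 1 per mille... explicit: pct_a = 1, pct_b = 3 -> log2(2)
  b100 <- toy_track("g1", pos = c(rep(10, 1), rep(30, 99)), count = 1)
  b2 <- toy_track("g1", pos = c(rep(10, 3), rep(30, 97)), count = 1)
  out <- binned_log2fc(b100, b2, regions, bin_nt = 20, span = 100)
  expect_equal(out$log2fc[out$bin == 1], log2((3 + 1) / (1 + 1)))
})

test_that("terminal abundance reproduces hand-enumerated survivors", {
  # 5 UTRs engineered so exactly 2 survive:
  # u1 ok; u2 too short (700 nt); u3 low TPM; u4 only 4 cDNAs in the start
  # window of one sample; u5 ok
  regions <- tibble::tibble(gene = paste0("u", 1:5),
                            width = c(900L, 700L, 900L, 900L, 1000L))
  expr <- tibble::tibble(gene = regions$gene, tpm = c(5, 5, 0.5, 5, 5))
  mk <- function(gene, start_n, term_n, sample) {
    dplyr::bind_rows(
      toy_track(gene, pos = seq_len(start_n), count = 1, sample = sample),
      toy_track(gene, pos = regions$width[regions$gene == gene] - seq_len(term_n) + 1,
                count = 1, sample = sample)
    )
  }
  tracks <- dplyr::bind_rows(
    purrr::map_dfr(paste0("u", c(1, 2, 3, 5)), mk, start_n = 6, term_n = 6, sample = "s1"),
    purrr::map_dfr(paste0("u", c(1, 2, 3, 5)), mk, start_n = 7, term_n = 7, sample = "s2"),
    mk("u4", 6, 6, "s1"), mk("u4", 4, 9, "s2")
  )
  out <- terminal_abundance(tracks, regions, expr)
  expect_setequal(unique(out$result$gene), c("u1", "u5"))
  expect_equal(unname(out$excluded), c(1L, 1L, 1L))
  expect_equal(sum(out$excluded), 3L)
})
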