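# Positional motif quantification, PAS location, binding sites, peaks.

test_that("motif coverage around cross-links matches the worked single-site case", {
  seq <- paste0(strrep("C", 30), "ATTAT", strrep("C", 30))
  sequences <- tibble::tibble(gene = "g1", seq = seq)
  track <- toy_track("g1", pos = 26, count = 1)  # k-mer starts at offset +5
  prof <- motif_coverage_around_crosslinks(track, sequences, c("AUUAU"),
                                           half_window = 10, smooth_window = 0)
  covered <- prof$offset[prof$pct_raw == 100]
  expect_identical(covered, 5:9)
  expect_true(all(prof$pct_raw[!prof$offset %in% 5:9] == 0))
})

test_that("cDNA weights are capped and empty groups rejected", {
  seq <- paste0(strrep("C", 20), "ATTAT", strrep("C", 20))
  sequences <- tibble::tibble(gene = "g1", seq = seq)
  deep <- toy_track("g1", pos = 21, count = 100)
  capped <- toy_track("g1", pos = 21, count = 20)
  p1 <- motif_coverage_around_crosslinks(deep, sequences, "AUUAU",
                                         half_window = 5, smooth_window = 0)
  p2 <- motif_coverage_around_crosslinks(capped, sequences, "AUUAU",
                                         half_window = 5, smooth_window = 0)
  expect_equal(p1$pct_raw, p2$pct_raw)
  expect_error(motif_coverage_around_crosslinks(deep, sequences, character(0)),
               "empty")
  none <- motif_coverage_around_crosslinks(deep, sequences, "GGGGG",
                                           half_window = 5, smooth_window = 0)
  expect_true(all(none$pct_raw == 0))
})

test_that("coverage profiles stay in [0, 100] and smoothing fixes constants", {
  sim <- small_sim(n_genes = 25, seed = 14)
  tr <- simulate_crosslinks(sim$records, sim$truth, "primed", sim$cfg)
  prof <- motif_coverage_around_crosslinks(tr, sim$records,
                                           dna_to_rna(poised:::AUU_FAMILY_5MERS),
                                           half_window = 50)
  expect_true(all(prof$pct >= 0 & prof$pct <= 100))
  expect_equal(smooth_profile(rep(3.3, 50), 20, "triangular"), rep(3.3, 50))
})

test_that("binned region coverage matches a hand overlay", {
  # ATTATTATTT: AUUAU matches at 1 and 4, covering nucleotides 1..8 of 10
  out <- motif_region_coverage(tibble::tibble(gene = "r1", seq = "ATTATTATTT"),
                               group = "AUUAU", bin_nt = 10)
  expect_equal(out$pct, 80)
  full <- motif_region_coverage(tibble::tibble(gene = "r1", seq = "ATTAT"),
                                group = "AUUAU", bin_nt = 10)
  expect_equal(full$pct, 100)  # partial bin normalized by its true length
  none <- motif_region_coverage(tibble::tibble(gene = "r1", seq = strrep("G", 30)),
                                group = "AUUAU", bin_nt = 10)
  expect_true(all(none$pct == 0))
})

test_that("terminal PAS location follows the rightmost-valid rule", {
  # two matches: the 3'-most valid one wins
  s <- paste0("AATAAA", strrep("C", 30), "AATAAA", strrep("C", 25))
  expect_equal(locate_terminal_pas(s), 37L)
  # match only 10 nt from the end: invalid
  s2 <- paste0(strrep("C", 30), "AATAAA", strrep("C", 10))
  expect_true(is.na(locate_terminal_pas(s2)))
  expect_true(is.na(locate_terminal_pas(strrep("C", 60))))
  # RNA alphabet accepted
  s3 <- paste0(strrep("C", 30), "AAUAAA", strrep("C", 20))
  expect_equal(locate_terminal_pas(s3, pas = "AAUAAA"), 31L)
})

test_that("trimer valency counts overlapping occurrences upstream of the PAS", {
  s <- paste0(strrep("G", 20), "ATTATTATTT", "AATAAA", strrep("C", 20))
  out <- trimer_valency(tibble::tibble(gene = "g1", seq = s), trimer = "AUU")
  expect_equal(out$count, 3L)  # offsets 0, 3, 6 in the planted stretch
  s2 <- paste0(strrep("A", 40), "AATAAA", strrep("C", 20))
  out2 <- trimer_valency(tibble::tibble(gene = "g2", seq = s2), trimer = "AUU")
  expect_equal(out2$count, 0L)
  expect_message(
    out3 <- trimer_valency(tibble::tibble(gene = "g3", seq = strrep("C", 80)),
                           trimer = "AUU"),
    "excluded")
  expect_equal(nrow(out3), 0L)
  expect_identical(attr(out3, "excluded"), "g3")
})

test_that("binding sites require a relevant offset within the flank and merge", {
  seq <- paste0(strrep("C", 30), "ATTAT", strrep("C", 30))  # k-mer at 31
  sequences <- tibble::tibble(gene = "g1", seq = seq)
  merged <- merge_tracks(toy_track("g1", pos = 28, count = 4))
  # offset +3 relevant -> one site spanning the k-mer
  sites <- assign_binding_sites(merged, sequences, "AUUAU",
                                relevant_positions = list(AUUAU = 3L))
  expect_equal(nrow(sites), 1L)
  expect_equal(c(sites$start, sites$end, sites$count), c(31, 35, 4))
  # cross-link 25 nt away: outside the +/-20 flank
  far <- merge_tracks(toy_track("g1", pos = 6, count = 2))
  expect_equal(nrow(assign_binding_sites(far, sequences, "AUUAU",
                                         relevant_positions = 0:20)), 0L)
  # two cross-links 4 nt apart sharing one k-mer: one merged site, counts summed
  two <- merge_tracks(toy_track("g1", pos = c(29, 33), count = c(2, 3)))
  merged_sites <- assign_binding_sites(two, sequences, "AUUAU",
                                       relevant_positions = -10:10)
  expect_equal(nrow(merged_sites), 1L)
  expect_equal(merged_sites$count, 5)
})

test_that("merging tracks sums cDNA counts at overlapping positions", {
  a <- toy_track("g1", pos = c(5, 9), count = c(2, 1), sample = "a")
  b <- toy_track("g1", pos = c(5, 12), count = c(4, 7), sample = "b")
  m <- merge_tracks(dplyr::bind_rows(a, b))
  expect_equal(m$count[m$pos == 5], 6)
  expect_equal(sum(m$count), 14)
})

test_that("peak merging is book-ended within sets but not across sets", {
  # half-open [10,20) + [20,30) in BED terms = closed [11,20] + [21,30]
  a <- tibble::tibble(gene = "g1", start = c(11L, 21L), end = c(20L, 30L))
  b <- tibble::tibble(gene = "g1", start = 20L, end = 25L)
  res <- merge_and_overlap_peaks(a, b)
  expect_equal(nrow(res$merged_a), 1L)
  expect_equal(c(res$merged_a$start, res$merged_a$end), c(11L, 30L))
  expect_true(res$overlap$overlaps_b)   # >= 1 nt intersection
  # across sets, book-ended does not count as overlapping
  c1 <- tibble::tibble(gene = "g1", start = 11L, end = 20L)
  c2 <- tibble::tibble(gene = "g1", start = 21L, end = 30L)
  res2 <- merge_and_overlap_peaks(c1, c2)
  expect_false(res2$overlap$overlaps_b)
  expect_error(merge_and_overlap_peaks(tibble::tibble(gene = "g", start = 5L, end = 2L), b),
               "start > end")
})

test_that("nucleotide composition sums to 100 per offset and handles pure cases", {
  all_a <- tibble::tibble(gene = c("x", "y"),
                          seq = c(paste0(strrep("A", 120), "AATAAA", strrep("A", 20)),
                                  paste0(strrep("A", 150), "AATAAA", strrep("A", 20))))
  comp <- nucleotide_composition_around_pas(all_a)
  a_rows <- comp[comp$base == "A" & comp$offset < 0, ]
  expect_true(all(a_rows$pct == 100))
  sums <- tapply(comp$pct, comp$offset, sum)
  expect_true(all(abs(sums - 100) < 1e-9))

  two <- tibble::tibble(
    gene = c("p", "q"),
    seq = c(paste0(strrep("A", 120), "AATAAA", strrep("C", 20)),
            paste0(strrep("T", 120), "AATAAA", strrep("C", 20)))
  )
  comp2 <- nucleotide_composition_around_pas(two)
  at_m50 <- comp2[comp2$offset == -50, ]
  expect_equal(sort(at_m50$pct), c(0, 0, 50, 50))
  expect_error(nucleotide_composition_around_pas(
    tibble::tibble(gene = "z", seq = strrep("C", 300))), "no sequence")
})
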