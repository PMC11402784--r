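# Sequence dataset encoding, the network machinery, and attribution
# summaries. Full-scale training behavior is exercised separately in the
# acceptance suite; here a tiny planted task keeps the checks fast.

tiny_planted_records <- function(n = 120, len = 60, seed = 5) {
  set.seed(seed)
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
  }, "")
  cls <- rep(c("up", "down"), each = n / 2)
  planted <- integer(n)
  for (i in which(cls == "down")) {
    p <- sample(seq_len(len - 9), 1)
    substr(seqs[i], p, p + 7) <- "ATTATTAT"
    planted[i] <- p
  }
  tibble::tibble(gene = paste0("g", seq_len(n)), seq = seqs, class = cls,
                 planted = planted)
}

test_that("one-hot encoding follows the A/C/G/T/N scheme with all-zero padding", {
  recs <- tibble::tibble(
    gene = c(paste0("f", 1:49), "long"),
    seq = c(rep("ACGTN", 49), strrep("A", 50)),
    class = rep(c("up", "down"), 25)
  )
  ds <- encode_and_split(recs, max_keep_quantile = 0.95, seed = 1)
  # the single longest sequence is dropped, all others are 5 nt, padded equal
  expect_equal(dim(ds$x)[1], 49L)
  expect_equal(dim(ds$x)[2], 5L)
  expect_equal(ds$x[1, 1, ], c(1, 0, 0, 0))
  expect_equal(ds$x[1, 2, ], c(0, 1, 0, 0))
  expect_equal(ds$x[1, 3, ], c(0, 0, 1, 0))
  expect_equal(ds$x[1, 4, ], c(0, 0, 0, 1))
  expect_equal(ds$x[1, 5, ], c(0, 0, 0, 0))   # N row
  expect_equal(ds$y[1, ], c(up = 1, down = 0))
})

test_that("the stratified split is exactly 66:17:17 with padding rows zero", {
  recs <- tibble::tibble(
    gene = paste0("g", 1:100),
    seq = replicate(100, paste(sample(c("A", "C", "G", "T"), sample(30:50, 1),
                                      TRUE), collapse = "")),
    class = rep(c("up", "down"), 50)
  )
  ds <- encode_and_split(recs, max_keep_quantile = 1, seed = 2)
  expect_equal(unname(table(ds$split)), c(66L, 17L, 17L), ignore_attr = TRUE)
  # class balance preserved within each split portion
  for (s in levels(ds$split)) {
    frac_down <- mean(ds$y[ds$split == s, 2])
    expect_equal(frac_down, 0.5, tolerance = 0.06)
  }
  # padded tails are all-zero
  for (i in c(1, 50)) {
    len <- ds$length[i]
    if (len < dim(ds$x)[2]) {
      expect_true(all(ds$x[i, (len + 1):dim(ds$x)[2], ] == 0))
    }
  }
  ds2 <- encode_and_split(recs, max_keep_quantile = 1, seed = 2)
  expect_identical(ds$split, ds2$split)       # seeded determinism
  expect_error(encode_and_split(recs[recs$class == "up", ]), "two classes")
})

test_that("softmax outputs are probabilities and short inputs are rejected", {
  recs <- tiny_planted_records(60, len = 40, seed = 6)
  ds <- encode_and_split(recs, seed = 3)
  cfg <- seq_model_config(filters = 8, gru_units = 8, dense_units = 8,
                          max_epochs = 1, seed = 4)
  m <- train_seq_classifier(ds, cfg)
  pr <- predict(m, ds)
  expect_true(all(abs(rowSums(pr) - 1) < 1e-9))
  expect_true(all(pr >= 0 & pr <= 1))
  tiny <- list(x = array(0, c(4, 8, 4)), y = diag(2)[c(1, 2, 1, 2), ],
               split = factor(rep(c("train", "val", "test", "train"))),
               length = rep(8L, 4), classes = c("up", "down"))
  class(tiny) <- "seq_dataset"
  expect_error(train_seq_classifier(tiny, seq_model_config(pool = 3)),
               "pooling-stack minimum")
})

test_that("training on the tiny planted task is deterministic under one seed", {
  recs <- tiny_planted_records(80, len = 40, seed = 7)
  ds <- encode_and_split(recs, seed = 5)
  cfg <- seq_model_config(filters = 8, gru_units = 8, dense_units = 8,
                          max_epochs = 3, seed = 6)
  m1 <- train_seq_classifier(ds, cfg)
  m2 <- train_seq_classifier(ds, cfg)
  expect_equal(m1$metrics, m2$metrics)
  expect_equal(m1$params, m2$params)
})

test_that("attribution has the input shape and vanishes on the all-N baseline", {
  recs <- tiny_planted_records(60, len = 40, seed = 8)
  ds <- encode_and_split(recs, seed = 7)
  cfg <- seq_model_config(filters = 8, gru_units = 8, dense_units = 8,
                          max_epochs = 2, seed = 8)
  m <- train_seq_classifier(ds, cfg)
  idx <- which(ds$split == "test")
  attr <- attribute(m, ds, class = "down", idx = idx, n_steps = 4)
  expect_equal(dim(attr), c(length(idx), dim(ds$x)[2], 4L))
  expect_true(all(is.finite(attr)))
  # all-N input: attribution is exactly zero (input x gradient with x = 0)
  blank <- array(0, c(2, dim(ds$x)[2], 4))
  attr0 <- attribute(m, blank, class = "down", n_steps = 4)
  expect_true(all(attr0 == 0))
})

test_that("trimer summary of an all-ones attribution equals trimer occupancy", {
  recs <- tibble::tibble(
    gene = paste0("g", 1:50),
    seq = c(rep("AAAA", 25), rep("ACGTAC", 25)),
    class = rep(c("up", "down"), 25)
  )
  ds <- encode_and_split(recs, max_keep_quantile = 1, seed = 9)
  ones <- array(0, dim = dim(ds$x))
  for (i in seq_len(dim(ds$x)[1])) {
    ones[i, seq_len(ds$length[i]), ] <- ds$x[i, seq_len(ds$length[i]), ]
  }
  out <- summarize_trimer_importance(ones, ds, n_bins = 10)
  # uniform per-position score 1 -> every observed trimer scores exactly 1
  expect_true(all(abs(out$score - 1) < 1e-12))
  # occupancy oracle: trimers actually present, with their occurrence counts
  occupancy <- table(unlist(lapply(ds$gene, function(g) {
    s <- recs$seq[recs$gene == g]
    vapply(seq_len(nchar(s) - 2), function(j) substr(s, j, j + 2), "")
  })))
  expect_setequal(unique(out$trimer),
                  poised:::dna_to_rna(names(occupancy)))
  got <- tapply(out$n, out$trimer, sum)
  expect_equal(as.integer(got[poised:::dna_to_rna(names(occupancy))]),
               as.integer(occupancy), ignore_attr = TRUE)
  # "AAAA" with scores 1,1,1,1 -> only trimer AAA, profile value 1
  single <- out[out$trimer == "AAA", ]
  expect_true(all(single$score == 1))
})

test_that("positional importance bins by relative position and is order invariant", {
  recs <- tiny_planted_records(60, len = 50, seed = 10)
  ds <- encode_and_split(recs, max_keep_quantile = 1, seed = 10)
  n <- dim(ds$x)[1]
  attr <- array(0, dim = dim(ds$x))
  # concentrate attribution in the last 10% of every sequence
  for (i in seq_len(n)) {
    len <- ds$length[i]
    tail_idx <- seq(ceiling(0.91 * len), len)
    attr[i, tail_idx, ] <- ds$x[i, tail_idx, ]
  }
  pi1 <- positional_importance(attr, ds, n_bins = 100)
  mass_tail <- sum(pi1$score[pi1$bin >= 91])
  expect_gt(mass_tail, 0)
  expect_equal(sum(pi1$score[pi1$bin < 91]), 0)
  # zero attributions -> zero heat map
  zero <- positional_importance(array(0, dim = dim(ds$x)), ds)
  expect_true(all(zero$score == 0))
  # permuting sequence order leaves the summary unchanged
  perm <- sample(n)
  ds_perm <- ds
  ds_perm$x <- ds$x[perm, , , drop = FALSE]
  ds_perm$length <- ds$length[perm]
  ds_perm$gene <- ds$gene[perm]
  pi2 <- positional_importance(attr[perm, , , drop = FALSE], ds_perm, n_bins = 100)
  expect_equal(pi2, pi1)
})
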