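# Gradient-based additive attribution for the sequence classifier
# (integrated gradients along the path from the all-N baseline, which is the
# all-zero input under this one-hot scheme), plus the trimer and positional
# summaries of nucleotide-level importance.

#' Per-nucleotide attribution for one prediction class
#'
#' Integrated gradients of the chosen class logit with an all-N (all-zero)
#' baseline: `attr = x * mean_k d logit / d input` evaluated at `alpha_k * x`
#' for midpoints `alpha_k = (k - 0.5) / n_steps`. Attributions are additive
#' per nucleotide; the all-N input attributes (exactly) zero everywhere.
#'
#' @param model a `seq_classifier`.
#' @param dataset a `seq_dataset` (or one-hot array).
#' @param class attributed prediction class, `"down"` (default) or `"up"`.
#' @param idx sequence indices to attribute, default all.
#' @param n_steps path steps, default 16.
#' @param batch_size sequences per forward/backward batch.
#' @return array (sequences x positions x 4) of attribution scores, same
#'   shape as the encoded input.
#' @export
attribute <- function(model, dataset, class = c("down", "up"), idx = NULL,
                      n_steps = 16, batch_size = 64) {
  class <- match.arg(class)
  stopifnot(inherits(model, "seq_classifier"))
  x <- if (is.array(dataset)) dataset else dataset$x
  idx <- idx %||% seq_len(dim(x)[1])
  cls_col <- if (class == "down") 2L else 1L
  cfg <- model$config

  out <- array(0, dim = c(length(idx), dim(x)[2], dim(x)[3]))
  for (lo in seq(1L, length(idx), by = batch_size)) {
    sel <- idx[lo:min(lo + batch_size - 1L, length(idx))]
    xb <- x[sel, , , drop = FALSE]
    acc <- array(0, dim = dim(xb))
    for (k in seq_len(n_steps)) {
      alpha <- (k - 0.5) / n_steps
      fwd <- nn_forward(model$params, cfg, xb * alpha)
      dlogits <- matrix(0, dim(xb)[1], 2L)
      dlogits[, cls_col] <- 1
      bwd <- nn_backward(model$params, cfg, fwd, dlogits, want_input_grad = TRUE)
      acc <- acc + bwd$dinput
    }
    out[lo:(lo + length(sel) - 1L), , ] <- xb * acc / n_steps
  }
  out
}

# collapse the 4 channels to one score per position (one-hot input means only
# the observed base's channel is nonzero after multiplying by the input)
position_scores <- function(attr_i, len) {
  rowSums(attr_i)[seq_len(len)]
}

#' Trimer importance summarized over relative position
#'
#' Slides a 3-nt window (step 1) over each unpadded attributed sequence,
#' assigns the window's mean nucleotide score to the trimer present there,
#' bins window positions into 100 length-relative bins, and reports the mean
#' score per trimer per bin across all occurrences and sequences.
#'
#' @param attr attribution array from [attribute()].
#' @param dataset the `seq_dataset` the attributions belong to (provides
#'   sequences and unpadded lengths).
#' @param idx sequence indices attributed (same as passed to [attribute()]).
#' @param n_bins relative-position bins, default 100.
#' @return tibble with `trimer`, `bin`, `score` (mean), `n` (occurrences).
#'   Trimers never observed are absent.
#' @export
summarize_trimer_importance <- function(attr, dataset, idx = NULL, n_bins = 100) {
  stopifnot(inherits(dataset, "seq_dataset"))
  idx <- idx %||% seq_len(dim(attr)[1])
  stopifnot(length(idx) == dim(attr)[1])

  pieces <- vector("list", length(idx))
  for (r in seq_along(idx)) {
    i <- idx[r]
    len <- dataset$length[i]
    if (len < 3) next
    sc <- position_scores(attr[r, , , drop = FALSE][1, , ], len)
    seq_chars <- decode_onehot(dataset$x[i, seq_len(len), ])
    starts <- seq_len(len - 2L)
    win_mean <- (sc[starts] + sc[starts + 1L] + sc[starts + 2L]) / 3
    trimer <- substring(paste(seq_chars, collapse = ""), starts, starts + 2L)
    keep <- !grepl("N", trimer)
    bin <- pmin(ceiling(starts / len * n_bins), n_bins)
    pieces[[r]] <- tibble(trimer = dna_to_rna(trimer[keep]), bin = bin[keep],
                          score = win_mean[keep])
  }
  bind_rows(pieces) %>%
    group_by(.data$trimer, .data$bin) %>%
    summarise(score = mean(.data$score), n = dplyr::n(), .groups = "drop")
}

decode_onehot <- function(xmat) {
  hit <- xmat %*% seq_len(4)
  chars <- c(DNA_BASES, "N")[ifelse(rowSums(xmat) == 0, 5L, hit)]
  chars
}

#' Positional importance heat-map rows per nucleotide
#'
#' Normalizes each sequence's nucleotide-level scores to its own length
#' (100 length-relative bins), sums the scores within each bin, and averages
#' per nucleotide identity across sequences.
#'
#' @inheritParams summarize_trimer_importance
#' @return tibble with `base`, `bin`, `score`.
#' @export
positional_importance <- function(attr, dataset, idx = NULL, n_bins = 100) {
  stopifnot(inherits(dataset, "seq_dataset"))
  idx <- idx %||% seq_len(dim(attr)[1])
  stopifnot(length(idx) == dim(attr)[1])

  acc <- matrix(0, 4L, n_bins, dimnames = list(DNA_BASES, NULL))
  cnt <- 0L
  for (r in seq_along(idx)) {
    i <- idx[r]
    len <- dataset$length[i]
    sc <- position_scores(attr[r, , , drop = FALSE][1, , ], len)
    base <- decode_onehot(dataset$x[i, seq_len(len), ])
    bin <- pmin(ceiling(seq_len(len) / len * n_bins), n_bins)
    for (b in DNA_BASES) {
      sel <- base == b
      if (any(sel)) {
        sums <- tapply(sc[sel], factor(bin[sel], levels = seq_len(n_bins)), sum)
        sums[is.na(sums)] <- 0
        acc[b, ] <- acc[b, ] + sums
      }
    }
    cnt <- cnt + 1L
  }
  purrr::map_dfr(DNA_BASES, function(b) {
    tibble(base = dna_to_rna(b), bin = seq_len(n_bins), score = acc[b, ] / cnt)
  })
}
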