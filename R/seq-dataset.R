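# Sequence dataset preparation for the 3'UTR stability classifier: length
# trimming, one-hot encoding with N padding, and a fixed stratified
# train/validation/test split.

ONE_HOT <- rbind(
  A = c(1, 0, 0, 0), C = c(0, 1, 0, 0),
  G = c(0, 0, 1, 0), T = c(0, 0, 0, 1)
)

#' One-hot encode and split 3'UTR sequences
#'
#' Drops the longest `1 - max_keep_quantile` fraction of sequences, right-pads
#' the rest with N to a uniform length (N rows are all-zero, so padding
#' carries no signal), one-hot encodes (A/C/G/T as unit vectors), turns the
#' two classes into a binary class matrix (`up` = \[1,0\], `down` = \[0,1\])
#' and assigns a seeded, stratified 66:17:17 train/validation/test split with
#' preserved class balance.
#'
#' @param records tibble with `gene`, `seq` and `class` (values `up`/`down`).
#' @param max_keep_quantile length quantile above which sequences are
#'   excluded, default 0.95.
#' @param seed split seed.
#' @param split integer proportions for train/val/test.
#' @return a `seq_dataset`: list with `x` (array N x L x 4), `y` (N x 2
#'   class matrix), `split` (factor train/val/test), `gene`, `length`
#'   (unpadded lengths), `classes`.
#' @export
encode_and_split <- function(records, max_keep_quantile = 0.95, seed = 1,
                             split = c(train = 66, val = 17, test = 17)) {
  assert_columns(records, c("gene", "seq", "class"))
  classes <- sort(unique(records$class))
  if (length(classes) < 2) abort("two classes are required")
  if (length(classes) > 2) abort("more than two classes supplied")
  if (nrow(records) < 50) abort("at least 50 sequences are required")

  lens <- nchar(records$seq)
  cutoff <- quantile(lens, max_keep_quantile, type = 1)
  keep <- lens <= cutoff
  records <- records[keep, , drop = FALSE]
  lens <- lens[keep]
  max_len <- max(lens)

  n <- nrow(records)
  x <- array(0, dim = c(n, max_len, 4L))
  for (i in seq_len(n)) {
    chars <- strsplit(toupper(records$seq[i]), "")[[1]]
    known <- chars %in% rownames(ONE_HOT)
    if (any(known)) {
      x[i, which(known), ] <- ONE_HOT[chars[known], , drop = FALSE]
    }
  }
  # class matrix: up = [1, 0], down = [0, 1]
  is_down <- records$class == "down"
  y <- cbind(up = as.numeric(!is_down), down = as.numeric(is_down))

  split_assign <- stratified_three_way_split(records$class, split, seed)

  structure(
    list(x = x, y = y, split = split_assign, gene = records$gene,
         length = lens, classes = c("up", "down")),
    class = "seq_dataset"
  )
}

# exact three-way totals via largest remainder, stratified by class with
# per-class largest-remainder allocation reconciled to the global totals
stratified_three_way_split <- function(labels, split, seed) {
  set.seed(seed)
  n <- length(labels)
  totals <- allocate_counts(n, split)
  names(totals) <- names(split)
  out <- character(n)
  remaining <- totals
  classes <- unique(labels)
  for (ci in seq_along(classes)) {
    idx <- sample(which(labels == classes[ci]))
    if (ci == length(classes)) {
      counts <- remaining
    } else {
      counts <- allocate_counts(length(idx), split)
      counts <- pmin(counts, remaining)
      # hand any shortfall to the largest remaining bucket
      short <- length(idx) - sum(counts)
      while (short > 0) {
        j <- which.max(remaining - counts)
        counts[j] <- counts[j] + 1L
        short <- short - 1L
      }
    }
    out[idx] <- rep(names(split), counts)
    remaining <- remaining - counts
  }
  factor(out, levels = names(split))
}
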