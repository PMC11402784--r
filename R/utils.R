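#' @importFrom rlang %||% abort warn inform
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join inner_join bind_rows bind_cols n across all_of row_number
#'   desc pull distinct rename count slice transmute case_when coalesce
#' @importFrom tibble tibble as_tibble
#' @importFrom stats rnorm runif rpois rlnorm pnorm sd cor quantile median
#'   setNames predict hclust cutree as.dist complete.cases
#' @importFrom utils head tail
NULL

DNA_BASES <- c("A", "C", "G", "T")

# RNA motif vocabulary at the user surface, DNA internally (U == T).
rna_to_dna <- function(x) chartr("Uu", "Tt", toupper(x))
dna_to_rna <- function(x) chartr("Tt", "Uu", toupper(x))

#' Rolling-mean smoothing with triangular or flat kernel
#'
#' Centered weighted rolling mean. The triangular kernel rises linearly to the
#' window center; edge positions where the kernel would run off the profile are
#' filled with the nearest valid smoothed value, so a constant input maps to
#' the same constant.
#'
#' @param x numeric vector.
#' @param window kernel width in positions (>= 1). `window = 1` is the identity.
#' @param shape `"triangular"` or `"flat"`.
#' @return numeric vector of `length(x)`.
#' @export
smooth_profile <- function(x, window = 20, shape = c("triangular", "flat")) {
  shape <- match.arg(shape)
  stopifnot(is.numeric(x), window >= 1)
  window <- as.integer(window)
  if (window == 1L) return(as.numeric(x))
  if (window > length(x)) {
    warn("smoothing window exceeds profile length; returning unsmoothed values")
    return(as.numeric(x))
  }
  w <- if (shape == "triangular") pmin(seq_len(window), rev(seq_len(window))) else rep(1, window)
  w <- w / sum(w)
  sm <- as.numeric(stats::filter(x, w, sides = 2))
  # nearest-valid fill at both ends
  ok <- which(!is.na(sm))
  sm[seq_len(ok[1] - 1)] <- sm[ok[1]]
  lastok <- ok[length(ok)]
  if (lastok < length(sm)) sm[(lastok + 1):length(sm)] <- sm[lastok]
  sm
}

# moving average with window w (flat), same edge rule
moving_average <- function(x, window = 10) smooth_profile(x, window = window, shape = "flat")

# overlapping occurrence starts of `pattern` in `seq` (1-based)
find_motif_starts <- function(seq, pattern) {
  m <- gregexpr(paste0("(?=", pattern, ")"), seq, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

# all k-mers over the DNA alphabet
all_kmers <- function(k) {
  do.call(paste0, expand.grid(rep(list(DNA_BASES), k), stringsAsFactors = FALSE)[, k:1, drop = FALSE])
}

# largest-remainder allocation of n items to fractions p (sums to n exactly)
allocate_counts <- function(n, p) {
  raw <- n * p / sum(p)
  out <- floor(raw)
  rem <- n - sum(out)
  if (rem > 0) {
    idx <- order(raw - out, decreasing = TRUE)[seq_len(rem)]
    out[idx] <- out[idx] + 1
  }
  as.integer(out)
}

# derive a per-stage 32-bit seed from a global seed and a stage label, so that
# toggling one stage never shifts another stage's stream
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.double(seed) * 48271 + h * 7919) %% 2147483647)
}

assert_columns <- function(df, cols, what = deparse(substitute(df))) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    abort(sprintf("%s is missing required column(s): %s", what, paste(miss, collapse = ", ")))
  }
  invisible(df)
}
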