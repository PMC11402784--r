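# Half-life estimation from normalized conversion time courses. Inputs are
# already background-subtracted, chase-normalized conversion fractions; the
# raw-count normalization applied upstream by the mapping pipeline is outside
# this module's boundary.

#' Fit exponential decay half-lives per gene and condition
#'
#' Fits `v(t) = v0 * exp(-lambda * t)` by nonlinear least squares
#' (Levenberg-Marquardt, [minpack.lm::nlsLM()]) separately for every
#' gene/condition series. `v0` is free; starting values are `v0 =` the value
#' at the earliest time and `lambda = ln(2) / median positive timepoint`, with
#' `lambda` bounded in `(1e-6, 100)` per hour. R-squared is computed against
#' the mean of the observed values (`1 - SS_res / SS_tot`).
#'
#' A fit is flagged `converged = FALSE` when the optimizer fails, the series
#' carries no decay information (all-zero values or zero variance) or the
#' fitted rate collapses onto the lower bound.
#'
#' @param series tibble with `gene`, `condition`, `time_h`, `value`; every
#'   series needs at least 3 timepoints, strictly increasing and including 0.
#' @return tibble with `gene`, `condition`, `lambda`, `halflife_h`
#'   (`= ln(2)/lambda`), `r2`, `converged`.
#' @export
fit_halflife <- function(series) {
  assert_columns(series, c("gene", "condition", "time_h", "value"))
  if (any(!is.finite(series$value)) || any(series$value < 0)) {
    abort("conversion values must be finite and non-negative")
  }
  series %>%
    group_by(.data$gene, .data$condition) %>%
    summarise(fit = list(fit_one_series(.data$time_h, .data$value)),
              .groups = "drop") %>%
    tidyr::unnest_wider("fit")
}

fit_one_series <- function(t, v) {
  ord <- order(t)
  t <- t[ord]; v <- v[ord]
  if (length(t) < 3) abort("each series needs at least 3 timepoints")
  if (anyDuplicated(t)) abort("timepoints must be strictly increasing")
  if (t[1] != 0) abort("timepoints must include 0")

  failed <- list(lambda = NA_real_, halflife_h = NA_real_, r2 = NA_real_,
                 converged = FALSE)
  ss_tot <- sum((v - mean(v))^2)
  if (all(v == 0) || ss_tot == 0) return(failed)

  lam0 <- log(2) / max(median(t[t > 0]), 1e-3)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ v0 * exp(-lambda * t),
      start = list(v0 = max(v[1], 1e-3), lambda = lam0),
      lower = c(v0 = 0, lambda = 1e-6), upper = c(v0 = Inf, lambda = 100),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(failed)
  lam <- unname(stats::coef(fit)[["lambda"]])
  r2 <- 1 - sum(stats::resid(fit)^2) / ss_tot
  if (lam <= 1e-5) {
    return(list(lambda = lam, halflife_h = log(2) / lam, r2 = r2, converged = FALSE))
  }
  list(lambda = lam, halflife_h = log(2) / lam, r2 = r2, converged = TRUE)
}

#' Keep genes whose decay fits pass in every condition
#'
#' @param fits output of [fit_halflife()] covering one or more conditions.
#' @param r2_min minimum model R-squared, default 0.6.
#' @return character vector of gene ids converged with `r2 > r2_min` in every
#'   condition present in `fits`.
#' @export
filter_fits <- function(fits, r2_min = 0.6) {
  assert_columns(fits, c("gene", "condition", "r2", "converged"))
  n_cond <- dplyr::n_distinct(fits$condition)
  if (n_cond < 1) abort("fits must cover at least one condition")
  fits %>%
    group_by(.data$gene) %>%
    summarise(
      keep = dplyr::n() == n_cond && all(.data$converged & .data$r2 > r2_min),
      .groups = "drop"
    ) %>%
    filter(.data$keep) %>%
    pull("gene")
}

#' Rank genes by half-life change and label the extremes
#'
#' Computes per-gene delta half-life (condition B minus condition A, hours),
#' sorts, and labels the `n_top` most-decreased and `n_top` most-increased
#' genes. Ties are broken lexicographically by gene id so the labeling is
#' deterministic.
#'
#' @param fits_a,fits_b [fit_halflife()] outputs for the two conditions
#'   (single condition each), already restricted to genes passing
#'   [filter_fits()].
#' @param n_top genes to label per class.
#' @return a `stability_classes` tibble with `gene`, `delta_h`, `label`
#'   (`decreased` / `increased`; unlabeled genes in between are omitted).
#'   If `2 * n_top` exceeds the supply, all genes are labeled with a warning.
#' @export
rank_delta_halflife <- function(fits_a, fits_b, n_top) {
  assert_columns(fits_a, c("gene", "halflife_h"))
  assert_columns(fits_b, c("gene", "halflife_h"))
  deltas <- inner_join(
    fits_a %>% select("gene", hl_a = "halflife_h"),
    fits_b %>% select("gene", hl_b = "halflife_h"),
    by = "gene"
  ) %>%
    mutate(delta_h = .data$hl_b - .data$hl_a) %>%
    arrange(.data$delta_h, .data$gene)

  n <- nrow(deltas)
  if (2 * n_top > n) {
    warn(sprintf("requested 2 x %d labels but only %d genes available; labeling all",
                 n_top, n))
    n_top <- ceiling(n / 2)
  }
  if (n > 2 * n_top &&
      (deltas$delta_h[n_top] == deltas$delta_h[n_top + 1] ||
       deltas$delta_h[n - n_top + 1] == deltas$delta_h[n - n_top])) {
    warn("delta half-life ties at the labeling boundary; labels there follow the gene-id tie-break")
  }
  decreased <- deltas %>% head(n_top) %>% mutate(label = "decreased")
  increased <- deltas %>% tail(n - n_top) %>% tail(min(n_top, n - n_top)) %>%
    mutate(label = "increased")
  bind_rows(decreased, increased) %>%
    select("gene", "delta_h", "label")
}
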