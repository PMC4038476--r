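# Cohort summaries, the relative cell-size statistic, endpoint proportions,
# and the hypothesis tests used on the recorded populations.

#' Relative linear cell size from input resistance
#'
#' `L_rel` is the square root of the reciprocal input resistance,
#' normalized to the mean of that quantity over the cell's own type, so the
#' type mean of `L_rel` is 1 by construction. It is a first-order proxy for
#' the linear size of the recorded cell (membrane area scales with
#' 1/R_in).
#'
#' @param data Data frame with one row per cell.
#' @param r_in Column of input resistances (MOhm); tidy-selected.
#' @param group Optional grouping column defining the normalization cohort
#'   (e.g. cell type); omit to normalize over all rows.
#' @return The input tibble with columns `lrel_raw` and `l_rel` appended.
#' @examples
#' l_rel(tibble::tibble(r_in = c(100, 25)))
#' @export
l_rel <- function(data, r_in = "r_in", group = NULL) {
  rin <- data[[r_in]]
  if (any(!is.finite(rin) | rin <= 0)) {
    abort("all input resistances must be positive")
  }
  out <- dplyr::mutate(as_tibble(data), lrel_raw = sqrt(1 / rin))
  if (!is.null(group)) {
    out <- out |>
      dplyr::group_by(dplyr::across(dplyr::all_of(group))) |>
      dplyr::mutate(l_rel = .data$lrel_raw / mean(.data$lrel_raw)) |>
      dplyr::ungroup()
  } else {
    out <- dplyr::mutate(out, l_rel = .data$lrel_raw /
                           mean(.data$lrel_raw))
  }
  out
}

#' Relative access resistance
#'
#' @param ra Access resistance (MOhm).
#' @param r_in Input resistance (MOhm).
#' @return `ra / r_in` (unitless).
#' @export
relative_ra <- function(ra, r_in) {
  stopifnot(all(r_in > 0))
  ra / r_in
}

#' Endpoint proportions from a count table
#'
#' Proportions of the touch-initiated endpoints per cell class, with the
#' denominator restricted to the touch-step methods (TZ + TZS + TS; WS
#' counts are carried through but excluded from the denominator). A zero
#' denominator gives `NA`, not 0.
#'
#' @param counts Data frame with columns `cell_class`, `endpoint`, `n`
#'   (non-negative integers).
#' @return Tibble with `cell_class`, `endpoint`, `n`, `denominator`,
#'   `proportion`.
#' @examples
#' counts <- tibble::tibble(
#'   cell_class = rep(c("neuron", "glia"), each = 4),
#'   endpoint = rep(c("WS", "TZ", "TZS", "TS"), 2),
#'   n = c(28, 59, 49, 14, 5, 28, 11, 7))
#' endpoint_proportions(counts)
#' @export
endpoint_proportions <- function(counts) {
  stopifnot(all(c("cell_class", "endpoint", "n") %in% names(counts)))
  if (any(counts$n < 0) || any(counts$n != round(counts$n))) {
    abort("counts must be non-negative integers")
  }
  touch <- c("TZ", "TZS", "TS")
  counts |>
    as_tibble() |>
    dplyr::group_by(.data$cell_class) |>
    dplyr::mutate(
      denominator = sum(.data$n[.data$endpoint %in% touch]),
      proportion = dplyr::if_else(
        .data$endpoint %in% touch & .data$denominator > 0,
        .data$n / .data$denominator, NA_real_)
    ) |>
    dplyr::ungroup()
}

#' Two-proportion z test
#'
#' Pooled-proportion z statistic for the difference of two independent
#' proportions, with a normal-approximation two-sided p value.
#'
#' @param x1,n1 Successes and trials of the first sample.
#' @param x2,n2 Successes and trials of the second sample.
#' @return One-row tibble: `z`, `p_two_sided`, `p1`, `p2`.
#' @examples
#' two_proportion_z(46, 168, 5, 33)
#' @export
two_proportion_z <- function(x1, n1, x2, n2) {
  stopifnot(n1 > 0, n2 > 0, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  p1 <- x1 / n1
  p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  if (pp <= 0 || pp >= 1) {
    abort("pooled proportion is 0 or 1: z undefined")
  }
  z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  tibble(z = z, p_two_sided = 2 * pnorm(-abs(z)), p1 = p1, p2 = p2)
}

#' Two-sample t test (Student or Welch)
#'
#' @param a,b Numeric samples (each of length at least 2).
#' @param mode `"student"` (pooled variance) or `"welch"`.
#' @return One-row tibble: `t`, `df`, `p_two_sided`. Identical groups up to
#'   a shift with zero variance give an infinite `t` (p of 0).
#' @export
two_sample_t <- function(a, b, mode = c("student", "welch")) {
  mode <- match.arg(mode)
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (var(a) == 0 && var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(tibble(t = 0, df = length(a) + length(b) - 2,
                    p_two_sided = 1))
    }
    return(tibble(t = sign(mean(a) - mean(b)) * Inf,
                  df = length(a) + length(b) - 2, p_two_sided = 0))
  }
  fit <- t.test(a, b, var.equal = (mode == "student"))
  tibble(t = unname(fit$statistic), df = unname(fit$parameter),
         p_two_sided = fit$p.value)
}

#' Pearson and Spearman correlation with a one-sided z test
#'
#' Reports the squared Pearson coefficient, the Spearman rank coefficient,
#' and a one-sided p value for the rank correlation from the Fisher
#' z transform (`z = atanh(rho) * sqrt(n - 3)`), testing the alternative in
#' the observed direction.
#'
#' @param x,y Numeric vectors (n >= 3, finite, non-constant).
#' @return One-row tibble: `pearson_r2`, `spearman_rho`, `p_one_sided_z`,
#'   `n`.
#' @export
correlations <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) abort("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) abort("constant input: correlation undefined")
  r <- cor(x, y)
  rho <- cor(x, y, method = "spearman")
  z <- atanh(max(min(rho, 1 - 1e-12), -1 + 1e-12)) * sqrt(n - 3)
  tibble(pearson_r2 = r^2, spearman_rho = rho,
         p_one_sided_z = pnorm(-abs(z)), n = n)
}

#' Cohort summary table (mean +/- SD with n)
#'
#' Groupwise summaries in the reporting convention of the cohort tables:
#' sample mean, sample standard deviation (n - 1 denominator), and the
#' contributing count, plus a formatted `mean +/- SD (n)` string.
#'
#' @param data Data frame of cell records.
#' @param vars Character vector of numeric columns to summarize.
#' @param by Character vector of grouping columns (e.g. `cell_class`,
#'   `endpoint`).
#' @return Long tibble: grouping columns, `parameter`, `mean`, `sd`, `n`,
#'   `label`.
#' @export
cohort_summary <- function(data, vars, by = c("cell_class", "endpoint")) {
  data |>
    as_tibble() |>
    tidyr::pivot_longer(dplyr::all_of(vars), names_to = "parameter",
                        values_to = "value") |>
    dplyr::filter(is.finite(.data$value)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "parameter")))) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(label = sprintf("%.3g±%.2g (%d)", .data$mean,
                                  .data$sd, .data$n))
}

#' Cross-check a count table against stated percentages
#'
#' Utility for validating published-style summaries: recomputes endpoint
#' percentages from counts and warns on each stated value that differs by
#' more than `tol` percentage points instead of silently reconciling.
#'
#' @param counts As in [endpoint_proportions()].
#' @param stated Data frame with columns `cell_class`, `endpoint` (may be a
#'   pooled label like `"TZ+TZS"`), `percent`.
#' @param tol Tolerance (percentage points).
#' @return Tibble of comparisons (`computed_percent`, `stated_percent`,
#'   `consistent`), invisibly warning on mismatches.
#' @export
validate_cohort_counts <- function(counts, stated, tol = 2) {
  prop <- endpoint_proportions(counts)
  rows <- purrr::pmap(stated, function(cell_class, endpoint, percent) {
    parts <- strsplit(endpoint, "+", fixed = TRUE)[[1]]
    sub <- prop[prop$cell_class == cell_class &
                  prop$endpoint %in% parts, ]
    comp <- 100 * sum(sub$n) / sub$denominator[1]
    tibble(cell_class = cell_class, endpoint = endpoint,
           computed_percent = comp, stated_percent = percent,
           consistent = abs(comp - percent) <= tol)
  })
  out <- dplyr::bind_rows(rows)
  bad <- out[!out$consistent, ]
  if (nrow(bad)) {
    warn(paste0("stated percentages inconsistent with counts: ",
                paste(sprintf("%s %s: stated %.0f%% vs computed %.1f%%",
                              bad$cell_class, bad$endpoint,
                              bad$stated_percent, bad$computed_percent),
                      collapse = "; ")))
  }
  out
}
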