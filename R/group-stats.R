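#' Summary statistics of a GRAVY group
#'
#' Five-number-style summary used throughout the hydropathy report.
#' Quartiles use the linear-interpolation convention between order
#' statistics (R's default quantile type 7); `frac_negative` counts values
#' strictly below zero, i.e. the hydrophilic fraction of the group.
#'
#' @param values Numeric vector, length >= 1.
#' @return One-row tibble: `n`, `mean`, `median`, `q1`, `q3`,
#'   `frac_negative`.
#' @export
gravy_summary <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) abort("cannot summarize an empty group")
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  tibble::tibble(
    n = length(values),
    mean = mean(values),
    median = q[2],
    q1 = q[1],
    q3 = q[3],
    frac_negative = mean(values < 0)
  )
}

#' Welch's two-sample t-test
#'
#' Two-sided unequal-variance t-test with Welch-Satterthwaite degrees of
#' freedom. When both groups are constant with equal means the difference
#' is exactly zero with no evidence either way, and `p = 1` is returned by
#' convention; constant groups with different means are an error.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @return One-row tibble: `t`, `df`, `p`.
#' @export
welch_t_test <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) {
    abort("Welch's t-test needs at least 2 observations per group")
  }
  vx <- stats::var(x)
  vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    if (mean(x) == mean(y)) {
      return(tibble::tibble(t = 0, df = length(x) + length(y) - 2, p = 1))
    }
    abort("both groups are constant with different means: t undefined")
  }
  fit <- t.test(x, y, var.equal = FALSE)
  tibble::tibble(
    t = unname(fit$statistic),
    df = unname(fit$parameter),
    p = fit$p.value
  )
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. The p-value is exact (full null enumeration of
#' the U distribution) when `min(n_x, n_y) <= 8` and the pooled sample is
#' tie-free; otherwise the normal approximation with tie correction and
#' continuity correction is used. `U` is the number of (x, y) pairs with
#' x ahead of y (the statistic for the first sample).
#'
#' @param x,y Numeric vectors, each of length >= 1.
#' @param exact_max Largest `min(n_x, n_y)` for which the exact null
#'   distribution is used (default 8).
#' @return One-row tibble: `U`, `p`.
#' @export
mann_whitney_u <- function(x, y, exact_max = 8L) {
  if (length(x) < 1L || length(y) < 1L) abort("both groups must be nonempty")
  has_ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- !has_ties && min(length(x), length(y)) <= exact_max
  fit <- suppressWarnings(
    wilcox.test(x, y, exact = use_exact, correct = TRUE)
  )
  tibble::tibble(U = unname(fit$statistic), p = fit$p.value)
}

#' Compare two GRAVY groups with both tests
#'
#' Runs Welch's t-test and the Mann-Whitney U test (both two-sided) and
#' summarises both groups. This is the comparison unit of the hydropathy
#' report.
#'
#' @param x,y Numeric vectors (e.g. GRAVY values of two protein groups).
#' @param label Comparison label.
#' @param name_x,name_y Group names used in the tidy output.
#' @return A `gravy_comparison` object; see [tidy()] for the flat form.
#' @export
compare_gravy_groups <- function(x, y, label = "x vs y",
                                 name_x = "x", name_y = "y") {
  if (length(x) < 2L) abort(paste0("group '", name_x, "' has fewer than 2 values"))
  if (length(y) < 2L) abort(paste0("group '", name_y, "' has fewer than 2 values"))
  welch <- welch_t_test(x, y)
  mwu <- mann_whitney_u(x, y)
  structure(
    list(
      label = label,
      name_x = name_x, name_y = name_y,
      summary_x = gravy_summary(x),
      summary_y = gravy_summary(y),
      welch_t = welch$t, welch_df = welch$df, welch_p = welch$p,
      mwu_u = mwu$U, mwu_p = mwu$p
    ),
    class = "gravy_comparison"
  )
}

#' @export
tidy.gravy_comparison <- function(x, ...) {
  tibble::tibble(
    label = x$label,
    n_x = x$summary_x$n, n_y = x$summary_y$n,
    median_x = x$summary_x$median, median_y = x$summary_y$median,
    q1_x = x$summary_x$q1, q3_x = x$summary_x$q3,
    q1_y = x$summary_y$q1, q3_y = x$summary_y$q3,
    frac_negative_x = x$summary_x$frac_negative,
    frac_negative_y = x$summary_y$frac_negative,
    welch_t = x$welch_t, welch_df = x$welch_df, welch_p = x$welch_p,
    mwu_u = x$mwu_u, mwu_p = x$mwu_p
  )
}

#' @export
print.gravy_comparison <- function(x, ...) {
  cat(sprintf(
    "<gravy_comparison> %s\n  %s: n=%d median=%.4f  |  %s: n=%d median=%.4f\n  Welch t=%.3f df=%.1f p=%.3g  |  Mann-Whitney U=%.0f p=%.3g\n",
    x$label,
    x$name_x, x$summary_x$n, x$summary_x$median,
    x$name_y, x$summary_y$n, x$summary_y$median,
    x$welch_t, x$welch_df, x$welch_p, x$mwu_u, x$mwu_p
  ))
  invisible(x)
}

#' Hydropathy profile of the surface subset
#'
#' The three comparisons of the proteome hydropathy analysis:
#' (a) surface subset vs the whole proteome, (b) surface subset vs the
#' non-surface background, and (c) for secreted proteins, mature-chain
#' GRAVY vs full-chain GRAVY. Comparison (c) summarises the two value sets
#' side by side; no paired test is claimed. Each comparison carries both a
#' Welch t and a Mann-Whitney U test.
#'
#' @param gravy_records Tibble with columns `gravy_full`, `category` and
#'   (for comparison c) `gravy_mature` — the output of [add_gravy()] on a
#'   classified proteome.
#' @return A `surface_profile` object (list of three `gravy_comparison`s:
#'   `surface_vs_proteome`, `surface_vs_background`, `mature_vs_full`);
#'   `tidy()` flattens it to a three-row tibble.
#' @export
surface_profile_report <- function(gravy_records) {
  stopifnot(all(c("gravy_full", "category") %in% names(gravy_records)))
  is_surface <- gravy_records$category %in% c("secreted", "lipoprotein", "lpxtg_anchored")
  surf <- gravy_records$gravy_full[is_surface]
  backg <- gravy_records$gravy_full[!is_surface]
  if (length(surf) < 2L) abort("fewer than 2 surface proteins: cannot compare groups")
  if (length(backg) < 2L) abort("fewer than 2 non-surface proteins: cannot compare groups")

  cmp <- list(
    surface_vs_proteome = compare_gravy_groups(
      surf, gravy_records$gravy_full,
      label = "surface subset vs whole proteome",
      name_x = "surface", name_y = "proteome"
    ),
    surface_vs_background = compare_gravy_groups(
      surf, backg,
      label = "surface subset vs non-surface background",
      name_x = "surface", name_y = "background"
    )
  )

  sec <- gravy_records$category == "secreted"
  if ("gravy_mature" %in% names(gravy_records)) {
    mature <- gravy_records$gravy_mature[sec & !is.na(gravy_records$gravy_mature)]
    full <- gravy_records$gravy_full[sec & !is.na(gravy_records$gravy_mature)]
    if (length(mature) >= 2L) {
      cmp$mature_vs_full <- compare_gravy_groups(
        mature, full,
        label = "secreted: mature GRAVY vs full GRAVY",
        name_x = "mature", name_y = "full"
      )
    }
  }
  structure(cmp, class = "surface_profile")
}

#' @export
tidy.surface_profile <- function(x, ...) {
  dplyr::bind_rows(lapply(unclass(x), tidy.gravy_comparison))
}

#' @export
print.surface_profile <- function(x, ...) {
  lapply(unclass(x), print)
  invisible(x)
}
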