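#' Retention fraction from log-CFU endpoints
#'
#' `10^(log_final - log_initial)`: the surviving fraction of viable cells
#' after a stress exposure, equal to `N_final / N_initial`. A drop of one
#' log unit gives 0.1; equal endpoints give 1.
#'
#' @param log_initial,log_final log10 CFU/mL at the start and end of the
#'   exposure. Vectorised.
#' @return Surviving fraction (> 0 for finite inputs).
#' @export
retention_fraction <- function(log_initial, log_final) {
  if (any(!is.finite(log_initial)) || any(!is.finite(log_final))) {
    abort("log-CFU endpoints must be finite")
  }
  10^(log_final - log_initial)
}

STRESSORS <- c("acid", "bile", "lysozyme")
FEATURE_COLS <- c("antagonism", "acid_retention", "bile_retention", "lysozyme_retention")

#' Build the isolate-by-variable feature matrix
#'
#' Converts a long stress panel (one row per isolate and stressor, with
#' log-CFU endpoints, plus the isolate's mean antagonism halo) into the
#' 4-column matrix analysed by [stress_pca()]: antagonism halo (mm) and
#' the acid, bile, and lysozyme retention fractions.
#'
#' @param panels Tibble with columns `isolate_id`, `stressor` (one of
#'   acid/bile/lysozyme), `log_cfu_initial`, `log_cfu_final`,
#'   `antagonism_mm` (constant within an isolate).
#' @return Tibble with one row per isolate: `isolate_id`, `antagonism`,
#'   `acid_retention`, `bile_retention`, `lysozyme_retention`.
#' @export
build_feature_matrix <- function(panels) {
  need <- c("isolate_id", "stressor", "log_cfu_initial", "log_cfu_final", "antagonism_mm")
  stopifnot(all(need %in% names(panels)))
  if (length(unique(panels$isolate_id)) < 2L) abort("need >= 2 isolates")
  bad <- setdiff(unique(panels$stressor), STRESSORS)
  if (length(bad) > 0L) abort(paste0("unknown stressor(s): ", paste(bad, collapse = ", ")))
  for (iso in unique(panels$isolate_id)) {
    have <- panels$stressor[panels$isolate_id == iso]
    missing <- setdiff(STRESSORS, have)
    if (length(missing) > 0L) {
      abort(paste0("isolate ", iso, ": ", paste(missing, collapse = ", ")))
    }
    if (anyDuplicated(have)) {
      abort(paste0("isolate ", iso, ": duplicated stressor rows"))
    }
  }
  if (any(panels$antagonism_mm < 0)) abort("antagonism halo diameters must be >= 0")
  wide <- panels |>
    dplyr::mutate(retention = retention_fraction(.data$log_cfu_initial, .data$log_cfu_final)) |>
    dplyr::select("isolate_id", "stressor", "retention", "antagonism_mm") |>
    tidyr::pivot_wider(
      names_from = "stressor", values_from = "retention",
      names_glue = "{stressor}_retention"
    ) |>
    dplyr::rename(antagonism = "antagonism_mm")
  wide[, c("isolate_id", FEATURE_COLS)]
}

#' Z-score standardize feature columns
#'
#' Centers each numeric column to mean 0 and scales it to unit standard
#' deviation. The population SD convention (divisor `n`) is the default,
#' matching common PCA-preprocessing practice; the sample convention
#' (divisor `n - 1`) is available via `sd_type`.
#'
#' @param m Feature tibble from [build_feature_matrix()] (any non-numeric
#'   id columns are passed through untouched).
#' @param sd_type `"population"` or `"sample"`.
#' @return The tibble with each numeric column standardized.
#' @export
zscore_columns <- function(m, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  num <- vapply(m, is.numeric, logical(1))
  out <- m
  for (col in names(m)[num]) {
    v <- m[[col]]
    n <- length(v)
    s <- if (sd_type == "population") sqrt(sum((v - mean(v))^2) / n) else sd(v)
    if (!is.finite(s) || s == 0) {
      abort(paste0("column '", col, "' is constant: standardization undefined"))
    }
    out[[col]] <- (v - mean(v)) / s
  }
  out
}

#' PCA of a standardized stress-tolerance profile
#'
#' Principal components from the singular-value decomposition of the
#' column-centered matrix. Explained-variance ratios are the eigenvalue
#' shares lambda_k / sum(lambda); ratios below `zero_tol` are reported as
#' exactly 0 (with `n` isolates at most `min(n - 1, n_variables)`
#' components are nonzero). Because a biplot's axes are sign-ambiguous,
#' each component is oriented so its largest-magnitude loading is
#' positive, which makes results deterministic and row-order invariant.
#'
#' @param m Standardized feature tibble (see [zscore_columns()]); a
#'   non-numeric `isolate_id` column labels the scores.
#' @param zero_tol Ratios below this are zeroed (default 1e-12).
#' @return A `stress_pca` object with elements `scores` (tibble
#'   isolate x PC), `loadings` (tibble variable x PC),
#'   `explained_variance_ratio`, `sdev`. Methods: [tidy()], [glance()],
#'   [autoplot()].
#' @export
stress_pca <- function(m, zero_tol = 1e-12) {
  num <- vapply(m, is.numeric, logical(1))
  x <- as.matrix(m[, num, drop = FALSE])
  if (nrow(x) < 2L) abort("PCA needs >= 2 isolates")
  ids <- if ("isolate_id" %in% names(m)) m$isolate_id else paste0("row", seq_len(nrow(x)))
  fit <- prcomp(x, center = TRUE, scale. = FALSE)
  if (all(fit$sdev < sqrt(zero_tol))) abort("matrix has rank 0: PCA undefined")

  rot <- fit$rotation
  scores <- fit$x
  # deterministic orientation: largest-|loading| entry of each PC positive
  for (k in seq_len(ncol(rot))) {
    j <- which.max(abs(rot[, k]))
    if (rot[j, k] < 0) {
      rot[, k] <- -rot[, k]
      scores[, k] <- -scores[, k]
    }
  }
  lambda <- fit$sdev^2
  ratio <- lambda / sum(lambda)
  ratio[ratio < zero_tol] <- 0

  structure(
    list(
      scores = dplyr::bind_cols(
        tibble::tibble(isolate_id = ids),
        tibble::as_tibble(scores)
      ),
      loadings = dplyr::bind_cols(
        tibble::tibble(variable = rownames(rot)),
        tibble::as_tibble(rot)
      ),
      explained_variance_ratio = ratio,
      sdev = fit$sdev,
      center = fit$center
    ),
    class = "stress_pca"
  )
}

#' @export
tidy.stress_pca <- function(x, matrix = c("scores", "loadings", "eigenvalues"), ...) {
  matrix <- match.arg(matrix)
  switch(matrix,
    scores = tidyr::pivot_longer(x$scores, -"isolate_id", names_to = "PC", values_to = "score"),
    loadings = tidyr::pivot_longer(x$loadings, -"variable", names_to = "PC", values_to = "loading"),
    eigenvalues = tibble::tibble(
      PC = paste0("PC", seq_along(x$explained_variance_ratio)),
      variance = x$sdev^2,
      explained_variance_ratio = x$explained_variance_ratio
    )
  )
}

#' @export
glance.stress_pca <- function(x, ...) {
  tibble::tibble(
    n_isolates = nrow(x$scores),
    n_variables = nrow(x$loadings),
    n_nonzero_components = sum(x$explained_variance_ratio > 0),
    pc1_ratio = x$explained_variance_ratio[1],
    pc2_ratio = if (length(x$explained_variance_ratio) >= 2) x$explained_variance_ratio[2] else NA_real_
  )
}

#' @export
print.stress_pca <- function(x, ...) {
  cat(sprintf(
    "<stress_pca> %d isolates x %d variables; explained variance: %s\n",
    nrow(x$scores), nrow(x$loadings),
    paste(sprintf("PC%d %.1f%%", seq_along(x$explained_variance_ratio),
                  100 * x$explained_variance_ratio), collapse = ", ")
  ))
  invisible(x)
}

#' Biplot of a stress-tolerance PCA
#'
#' Isolate scores as points and variable loadings as arrows (scaled to the
#' score range) on the first two principal components.
#'
#' @param object A `stress_pca` fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stress_pca <- function(object, ...) {
  sc <- object$scores
  ld <- object$loadings
  if (!all(c("PC1", "PC2") %in% names(sc))) abort("biplot needs at least 2 components")
  arrow_scale <- 0.8 * max(abs(c(sc$PC1, sc$PC2))) / max(abs(as.matrix(ld[, c("PC1", "PC2")])))
  ratio <- object$explained_variance_ratio
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted", colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted", colour = "grey60") +
    ggplot2::geom_segment(
      data = ld,
      ggplot2::aes(
        x = 0, y = 0,
        xend = .data$PC1 * arrow_scale, yend = .data$PC2 * arrow_scale
      ),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.2, "cm")),
      colour = "steelblue"
    ) +
    ggplot2::geom_text(
      data = ld,
      ggplot2::aes(
        x = .data$PC1 * arrow_scale, y = .data$PC2 * arrow_scale,
        label = .data$variable
      ),
      colour = "steelblue", vjust = -0.6, size = 3
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$isolate_id), vjust = -0.8) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * ratio[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * ratio[2]),
      title = "Stress-tolerance profile biplot"
    ) +
    ggplot2::theme_minimal()
}
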