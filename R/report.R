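provenance <- function(extra = list()) {
  c(list(package = "probioprofile",
         version = as.character(packageVersion("probioprofile"))), extra)
}

#' End-to-end hydropathy profile of a proteome
#'
#' The full in-silico pipeline: classify every protein's surface
#' localization, compute full-chain GRAVY (and mature-chain GRAVY for
#' secreted proteins), and compare the GRAVY distributions of the surface
#' subset against the whole proteome and the non-surface background.
#'
#' @param proteome Proteome tibble (see [read_fasta()]), or a path to a
#'   protein FASTA file.
#' @param params [classifier_params()].
#' @param scale Hydropathy scale.
#' @param out_dir Optional directory; when given, writes
#'   `surface_calls.tsv` (per-protein calls + GRAVY) and `profile.json`
#'   (summary counts, the three group comparisons, parameters, and package
#'   version for provenance).
#' @return A list of class `proteome_profile`: `records` (per-protein
#'   tibble), `summary` (category counts), `comparisons`
#'   (a `surface_profile`), `params`.
#' @export
run_profile <- function(proteome, params = classifier_params(),
                        scale = kd_scale(), out_dir = NULL) {
  if (is.character(proteome) && length(proteome) == 1L) {
    proteome <- read_fasta(proteome)
  }
  calls <- classify_proteome(proteome, params, scale)
  records <- dplyr::left_join(
    proteome, tibble::as_tibble(calls),
    by = c(id = "protein_id")
  )
  records <- add_gravy(records, scale)
  records <- dplyr::select(records, -"sequence")
  comparisons <- surface_profile_report(records)
  res <- structure(
    list(
      records = records,
      summary = surface_summary(calls),
      comparisons = comparisons,
      params = params,
      source_label = attr(proteome, "source_label") %||% "proteome"
    ),
    class = "proteome_profile"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_table(
      records, file.path(out_dir, "surface_calls.tsv"),
      format = "tsv",
      col_order = c(
        "id", "description", "category", "gravy_full", "gravy_mature",
        "n_scored", "h_start", "h_end", "cleavage_pos", "sp_mean_kd",
        "lipobox_pos", "lpxtg_pos"
      )
    )
    jsonlite::write_json(
      list(
        provenance = provenance(list(
          source = res$source_label,
          scale = attr(scale, "name") %||% "custom",
          params = unclass(params)
        )),
        summary = res$summary,
        comparisons = tidy(comparisons)
      ),
      file.path(out_dir, "profile.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE
    )
  }
  res
}

#' @export
print.proteome_profile <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<proteome_profile> %s\n  %d proteins: %d surface (%d secreted, %d lipoprotein, %d LPXTG-anchored)\n",
    x$source_label, s$n_total, s$n_surface, s$n_secreted, s$n_lipoprotein, s$n_lpxtg
  ))
  print(x$comparisons)
  invisible(x)
}

#' Compute assay metrics from a plate file
#'
#' @param plate Plate tibble (`well`, `group`, `od`) or a CSV path
#'   (see [read_plate()]).
#' @param out_dir Optional directory for `assays.tsv` and `assays.json`.
#' @return Tibble of assay results (see [assay_report()]).
#' @export
run_assays <- function(plate, out_dir = NULL) {
  if (is.character(plate) && length(plate) == 1L) plate <- read_plate(plate)
  res <- assay_report(plate)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_table(res, file.path(out_dir, "assays.tsv"),
                col_order = c("assay", "value", "unit", "detail"))
    jsonlite::write_json(
      list(provenance = provenance(), results = res),
      file.path(out_dir, "assays.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE
    )
  }
  res
}

#' Stress-panel PCA from a long panel table
#'
#' Retention fractions from the log-CFU endpoints, Z-score
#' standardization, and PCA with deterministic orientation — the pipeline
#' that ranks isolates by their joint stress-tolerance and antagonism
#' profile.
#'
#' @param panel Long panel tibble (see [generate_stress_panel()]) or a TSV
#'   path with columns `isolate_id`, `stressor`, `log_cfu_initial`,
#'   `log_cfu_final`, `antagonism_mm`.
#' @param sd_type Z-score convention, see [zscore_columns()].
#' @param out_dir Optional directory for `pca.json` (scores, loadings,
#'   explained-variance ratios).
#' @return A `stress_pca` fit.
#' @export
run_pca <- function(panel, sd_type = "population", out_dir = NULL) {
  if (is.character(panel) && length(panel) == 1L) {
    panel <- readr::read_tsv(panel, show_col_types = FALSE)
  }
  fm <- build_feature_matrix(panel)
  fit <- stress_pca(zscore_columns(fm, sd_type = sd_type))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(
        provenance = provenance(list(sd_type = sd_type)),
        scores = fit$scores,
        loadings = fit$loadings,
        explained_variance_ratio = fit$explained_variance_ratio
      ),
      file.path(out_dir, "pca.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  fit
}

#' Whole-proteome hydropathy benchmark statistics
#'
#' The four headline statistics of a proteome hydropathy profile: median
#' GRAVY of the whole proteome, median GRAVY of the surface subset, the
#' fraction of surface proteins with GRAVY < 0, and the median
#' mature-chain GRAVY of secreted proteins. Intended for benchmarking a
#' real annotated proteome FASTA against published values; the classifier
#' thresholds that the surface subset depends on are tunable via `params`
#' (a starting config ships at
#' `system.file("extdata", "benchmark-params.conf", package = "probioprofile")`).
#'
#' @param proteome Proteome tibble or FASTA path.
#' @param params [classifier_params()].
#' @param scale Hydropathy scale.
#' @return One-row tibble: `n_total`, `n_surface`, `n_secreted`,
#'   `median_gravy_proteome`, `median_gravy_surface`,
#'   `pct_surface_negative`, `median_gravy_mature_secreted`.
#' @export
gravy_benchmark <- function(proteome, params = classifier_params(), scale = kd_scale()) {
  prof <- run_profile(proteome, params, scale)
  rec <- prof$records
  is_surface <- rec$category %in% c("secreted", "lipoprotein", "lpxtg_anchored")
  mature <- rec$gravy_mature[rec$category == "secreted" & !is.na(rec$gravy_mature)]
  tibble::tibble(
    n_total = nrow(rec),
    n_surface = sum(is_surface),
    n_secreted = sum(rec$category == "secreted"),
    median_gravy_proteome = median(rec$gravy_full),
    median_gravy_surface = median(rec$gravy_full[is_surface]),
    pct_surface_negative = 100 * mean(rec$gravy_full[is_surface] < 0),
    median_gravy_mature_secreted = if (length(mature)) median(mature) else NA_real_
  )
}

#' Histogram of GRAVY distributions, proteome vs surface subset
#'
#' @param records Per-protein tibble from [run_profile()] (needs
#'   `gravy_full` and `category`).
#' @param bins Histogram bins.
#' @return A ggplot object.
#' @export
plot_gravy_distributions <- function(records, bins = 60) {
  stopifnot(all(c("gravy_full", "category") %in% names(records)))
  df <- dplyr::mutate(
    records,
    subset = ifelse(
      .data$category %in% c("secreted", "lipoprotein", "lpxtg_anchored"),
      "surface subset", "whole proteome"
    )
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gravy_full, fill = .data$subset)) +
    ggplot2::geom_histogram(
      bins = bins, alpha = 0.6, position = "identity",
      ggplot2::aes(y = ggplot2::after_stat(density))
    ) +
    ggplot2::labs(
      x = "GRAVY (Kyte-Doolittle)", y = "density",
      fill = NULL, title = "Hydropathy of the proteome and its surface subset"
    ) +
    ggplot2::theme_minimal()
}
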