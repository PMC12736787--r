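#' Classify crystal-violet biofilm formation
#'
#' Replicate ODs are averaged and the test mean (ODt) is compared with the
#' negative-control mean (ODc) on the standard four-level scale with
#' inclusive upper bounds:
#' Negative `ODt <= ODc`; Weak `ODc < ODt <= 2 ODc`;
#' Moderate `2 ODc < ODt <= 4 ODc`; Strong `ODt > 4 ODc`.
#' Replicate standard deviations are carried for reporting but play no
#' role in the class; the class is invariant to rescaling all ODs by a
#' common positive factor.
#'
#' @param od_test Numeric vector of test-well OD readings (>= 1 replicate).
#' @param od_control Numeric vector of negative-control OD readings.
#' @return One-row tibble: `odc_mean`, `odc_sd`, `odt_mean`, `odt_sd`,
#'   `fold_ratio` (ODt/ODc), `biofilm_class`.
#' @export
#' @examples
#' biofilm_classify(0.21975, 0.08025)  # fold 2.74, Moderate
biofilm_classify <- function(od_test, od_control) {
  if (length(od_test) < 1L) abort("no test wells")
  if (length(od_control) < 1L) abort("no control wells")
  if (any(od_test < 0) || any(od_control < 0)) abort("OD readings must be >= 0")
  odc <- mean(od_control)
  odt <- mean(od_test)
  if (odc == 0) abort("control mean OD is 0: fold ratio undefined")
  cls <- if (odt <= odc) "Negative"
    else if (odt <= 2 * odc) "Weak"
    else if (odt <= 4 * odc) "Moderate"
    else "Strong"
  tibble::tibble(
    odc_mean = odc, odc_sd = sd_or_zero(od_control),
    odt_mean = odt, odt_sd = sd_or_zero(od_test),
    fold_ratio = odt / odc,
    biofilm_class = cls
  )
}

sd_or_zero <- function(v) if (length(v) < 2L) 0 else sd(v)

#' Autoaggregation percentage
#'
#' `(initial - final) / initial * 100` from the OD600 of a standing
#' suspension before and after incubation. Negative values (final OD above
#' initial) are reported as-is, not clamped.
#'
#' @param od_initial,od_final OD600 readings; `od_initial` must be > 0.
#' @return Percentage in `(-Inf, 100]`. Vectorised.
#' @export
#' @examples
#' autoaggregation_pct(0.3, 0.2766)  # ~7.8
autoaggregation_pct <- function(od_initial, od_final) {
  if (any(od_initial <= 0)) abort("`od_initial` must be > 0")
  (od_initial - od_final) / od_initial * 100
}

#' Coaggregation percentage with a pathogen
#'
#' `100 * ((Ax + Ay)/2 - Amix) / ((Ax + Ay)/2)` where `ax` and `ay` are the
#' OD600 of the isolate and the pathogen alone and `amix` of their 1:1
#' mixture after standing incubation. Symmetric in `ax` and `ay`.
#'
#' @param ax,ay,amix OD600 readings; `ax + ay` must be > 0.
#' @return Percentage (`<= 100` whenever `amix >= 0`). Vectorised.
#' @export
coaggregation_pct <- function(ax, ay, amix) {
  if (any(ax + ay <= 0)) abort("`ax + ay` must be > 0")
  expected <- (ax + ay) / 2
  100 * (expected - amix) / expected
}

#' Bacterial adhesion to solvents (BATS) percentage
#'
#' `(1 - A/A0) * 100` from the aqueous-phase OD600 before (`a0`) and after
#' (`a`) partitioning against a solvent. Adhesion to toluene measures cell
#' surface hydrophobicity; chloroform and ethyl acetate probe electron
#' donor/acceptor character. Negative values (OD gain in the aqueous
#' phase) are meaningful and reported as-is.
#'
#' @param a0,a OD600 before solvent addition and after phase separation;
#'   `a0` must be > 0.
#' @return Percentage in `(-Inf, 100]`. Vectorised.
#' @export
#' @examples
#' bats_adhesion_pct(1.0, 1.0475)  # -4.75: a hydrophilic surface
bats_adhesion_pct <- function(a0, a) {
  if (any(a0 <= 0)) abort("`a0` must be > 0")
  (1 - a / a0) * 100
}

#' Read a plate CSV of OD readings
#'
#' Expected columns: `well`, `group`, `od`. Recognised group labels:
#' `test`/`control` (biofilm), `ax`/`ay`/`amix` (coaggregation),
#' `od_initial`/`od_final` (autoaggregation), `a0`/`a` (BATS).
#'
#' @param path CSV path.
#' @return Tibble with those columns.
#' @export
read_plate <- function(path) {
  plate <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("well", "group", "od")
  if (!all(need %in% names(plate))) {
    abort(paste0("plate CSV must have columns: ", paste(need, collapse = ", ")))
  }
  known <- c("test", "control", "ax", "ay", "amix", "od_initial", "od_final", "a0", "a")
  unknown <- setdiff(unique(plate$group), known)
  if (length(unknown) > 0L) {
    abort(paste0("unknown plate group label(s): ", paste(unknown, collapse = ", ")))
  }
  plate[need]
}

#' Compute every assay present on a plate table
#'
#' Applies the biofilm, autoaggregation, coaggregation, and BATS
#' calculators to whichever group labels the plate carries (replicates are
#' averaged per group). Assays whose groups are absent are skipped; a
#' biofilm `test` group without `control` wells is an error.
#'
#' @param plate Tibble from [read_plate()].
#' @return Tibble with one row per assay: `assay`, `value`, `unit`,
#'   `detail`.
#' @export
assay_report <- function(plate) {
  stopifnot(all(c("group", "od") %in% names(plate)))
  gm <- function(g) {
    v <- plate$od[plate$group == g]
    if (length(v) == 0L) NULL else mean(v)
  }
  rows <- list()
  if (any(plate$group %in% c("test", "control"))) {
    if (is.null(gm("test"))) abort("biofilm assay: no test wells")
    if (is.null(gm("control"))) abort("biofilm assay: no control wells")
    bf <- biofilm_classify(plate$od[plate$group == "test"], plate$od[plate$group == "control"])
    rows$biofilm <- tibble::tibble(
      assay = "biofilm", value = bf$fold_ratio, unit = "fold over control",
      detail = bf$biofilm_class
    )
  }
  if (!is.null(gm("od_initial")) && !is.null(gm("od_final"))) {
    rows$auto <- tibble::tibble(
      assay = "autoaggregation",
      value = autoaggregation_pct(gm("od_initial"), gm("od_final")),
      unit = "%", detail = NA_character_
    )
  }
  if (!is.null(gm("ax")) && !is.null(gm("ay")) && !is.null(gm("amix"))) {
    rows$co <- tibble::tibble(
      assay = "coaggregation",
      value = coaggregation_pct(gm("ax"), gm("ay"), gm("amix")),
      unit = "%", detail = NA_character_
    )
  }
  if (!is.null(gm("a0")) && !is.null(gm("a"))) {
    rows$bats <- tibble::tibble(
      assay = "bats_adhesion",
      value = bats_adhesion_pct(gm("a0"), gm("a")),
      unit = "%", detail = NA_character_
    )
  }
  if (length(rows) == 0L) abort("plate contains no recognised assay groups")
  dplyr::bind_rows(rows)
}
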