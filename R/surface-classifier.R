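#' Parameters of the surface-localization heuristics
#'
#' The three detectors (signal peptide, lipobox, LPXTG sortase anchor) are
#' positional heuristics over Kyte-Doolittle hydropathy and short motifs.
#' All spans and thresholds are exposed here; the defaults are sized for
#' canonical Gram-positive signal peptides (~20-35 aa with a hydrophobic
#' h-region of >= 8 residues) and sortase anchors sitting ~30-40 residues
#' from the C-terminus.
#'
#' @param sp_scan_len Residues scanned from the N-terminus for a
#'   hydrophobic window (default 45).
#' @param h_window Width of the hydrophobic window (default 8).
#' @param h_thresh Mean Kyte-Doolittle value a window must reach to count
#'   as hydrophobic (default 1.5); also used for the transmembrane window.
#' @param sp_cleave_min,sp_cleave_max Allowed 1-based positions of the
#'   signal-peptide cleavage site, the second A of the A-X-A motif
#'   (defaults 15 and 45).
#' @param lipobox_c_min,lipobox_c_max Allowed positions of the conserved
#'   lipobox cysteine (defaults 15 and 40).
#' @param lpxtg_c_window C-terminal span, in residues, in which the LPXTG
#'   motif must start (default 50).
#' @param tm_window Width of the transmembrane window required after the
#'   LPXTG motif (default 15).
#' @param tail_len,tail_min_kr Length of the C-terminal tail inspected for
#'   positive charge and the minimum count of K/R it must contain
#'   (defaults 10 and 2).
#' @return A `classifier_params` list.
#' @export
classifier_params <- function(sp_scan_len = 45L, h_window = 8L, h_thresh = 1.5,
                              sp_cleave_min = 15L, sp_cleave_max = 45L,
                              lipobox_c_min = 15L, lipobox_c_max = 40L,
                              lpxtg_c_window = 50L, tm_window = 15L,
                              tail_len = 10L, tail_min_kr = 2L) {
  p <- list(
    sp_scan_len = as.integer(sp_scan_len), h_window = as.integer(h_window),
    h_thresh = as.numeric(h_thresh),
    sp_cleave_min = as.integer(sp_cleave_min), sp_cleave_max = as.integer(sp_cleave_max),
    lipobox_c_min = as.integer(lipobox_c_min), lipobox_c_max = as.integer(lipobox_c_max),
    lpxtg_c_window = as.integer(lpxtg_c_window), tm_window = as.integer(tm_window),
    tail_len = as.integer(tail_len), tail_min_kr = as.integer(tail_min_kr)
  )
  ints <- p[setdiff(names(p), "h_thresh")]
  if (any(vapply(ints, function(v) is.na(v) || v <= 0L, logical(1)))) {
    abort("all classifier spans and counts must be positive integers")
  }
  if (!is.finite(p$h_thresh)) abort("`h_thresh` must be finite")
  if (p$sp_cleave_min > p$sp_cleave_max) abort("`sp_cleave_min` must be <= `sp_cleave_max`")
  if (p$lipobox_c_min > p$lipobox_c_max) abort("`lipobox_c_min` must be <= `lipobox_c_max`")
  structure(p, class = "classifier_params")
}

#' Read classifier parameters from a flat key:value config file
#'
#' Lines of the form `key: value` (or `key = value`); `#` starts a comment;
#' unknown keys are an error. Missing keys keep their defaults.
#'
#' @param path Config file path.
#' @return A `classifier_params` list.
#' @export
read_classifier_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*[:=]\\s*")
  bad <- which(lengths(kv) != 2L)
  if (length(bad) > 0L) abort(paste0("cannot parse config line: '", lines[bad[1]], "'"))
  keys <- vapply(kv, `[[`, character(1), 1)
  vals <- as.numeric(vapply(kv, `[[`, character(1), 2))
  known <- names(formals(classifier_params))
  unknown <- setdiff(keys, known)
  if (length(unknown) > 0L) {
    abort(paste0("unknown classifier parameter(s): ", paste(unknown, collapse = ", ")))
  }
  do.call(classifier_params, as.list(setNames(vals, keys)))
}

# first window of width w (window start <= max_start) whose mean hydropathy
# reaches thresh; returns c(start, end) or NULL
first_hydrophobic_window <- function(sequence, params, scale, max_end = NULL) {
  len <- nchar(sequence)
  w <- params$h_window
  seg_len <- min(len, params$sp_scan_len + w - 1L)
  if (!is.null(max_end)) seg_len <- min(seg_len, max_end)
  if (seg_len < w) return(NULL)
  vals <- residue_hydropathy(substr(sequence, 1L, seg_len), scale)
  means <- rolling_mean_na(vals, w)
  starts <- seq_along(means)
  ok <- starts <= params$sp_scan_len & !is.nan(means) & means >= params$h_thresh
  if (!any(ok)) return(NULL)
  s <- starts[which(ok)[1]]
  c(start = s, end = s + w - 1L)
}

#' Detect a signal peptide by the hydrophobic-region + A-X-A heuristic
#'
#' A protein is called secreted when (i) some window of `h_window` residues
#' starting within the first `sp_scan_len` positions has mean hydropathy
#' >= `h_thresh`, and (ii) an A-X-A triplet ends (second A) between
#' `max(sp_cleave_min, h_end + 1)` and `sp_cleave_max`. The cleavage site is
#' the second A of the first qualifying triplet after the first qualifying
#' hydrophobic window; the mature chain starts at the next residue.
#'
#' @param sequence Single amino-acid sequence.
#' @param params [classifier_params()].
#' @param scale Hydropathy scale.
#' @return A list with `h_start`, `h_end`, `cleavage_pos`, `sp_mean_kd`,
#'   or `NULL` when no signal peptide is called.
#' @export
detect_signal_peptide <- function(sequence, params = classifier_params(), scale = kd_scale()) {
  sequence <- toupper(sequence)
  len <- nchar(sequence)
  if (len < params$sp_cleave_min) return(NULL)
  hw <- first_hydrophobic_window(sequence, params, scale)
  if (is.null(hw)) return(NULL)
  lo <- max(params$sp_cleave_min, hw[["end"]] + 1L)
  hi <- min(params$sp_cleave_max, len)
  if (lo > hi) return(NULL)
  # A-X-A with the second A at position j+2 in [lo, hi]
  seg <- substr(sequence, max(1L, lo - 2L), hi)
  m <- gregexpr("A(?=.A)", seg, perl = TRUE)[[1]]
  if (m[1] == -1L) return(NULL)
  j <- m + max(1L, lo - 2L) - 1L          # positions of the first A
  cle <- j + 2L
  cle <- cle[cle >= lo & cle <= hi]
  if (length(cle) == 0L) return(NULL)
  cleavage_pos <- cle[1]
  list(
    h_start = unname(hw[["start"]]), h_end = unname(hw[["end"]]),
    cleavage_pos = as.integer(cleavage_pos),
    sp_mean_kd = window_hydropathy(sequence, 1L, cleavage_pos, scale)
  )
}

#' Detect a lipoprotein lipobox
#'
#' Finds the first match of L-\[A/S\]-\[A/G\]-C whose cysteine falls in
#' `[lipobox_c_min, lipobox_c_max]`, provided an N-terminal hydrophobic
#' window (same criterion as the signal-peptide detector) ends before the
#' cysteine. Only the hydrophobic region is required, not a full
#' signal-peptide call.
#'
#' @inheritParams detect_signal_peptide
#' @return 1-based position of the lipobox leucine, or `NULL`.
#' @export
detect_lipobox <- function(sequence, params = classifier_params(), scale = kd_scale()) {
  sequence <- toupper(sequence)
  len <- nchar(sequence)
  seg_end <- min(len, params$lipobox_c_max)
  if (seg_end < 4L) return(NULL)
  m <- gregexpr("L[AS][AG]C", substr(sequence, 1L, seg_end))[[1]]
  if (m[1] == -1L) return(NULL)
  for (pos in as.integer(m)) {
    cys <- pos + 3L
    if (cys < params$lipobox_c_min || cys > params$lipobox_c_max) next
    hw <- first_hydrophobic_window(sequence, params, scale, max_end = cys - 1L)
    if (!is.null(hw) && hw[["end"]] < cys) return(pos)
  }
  NULL
}

#' Detect an LPXTG sortase anchor
#'
#' Finds the last L-P-x-T-G motif starting within the final
#' `lpxtg_c_window` residues, and requires a transmembrane window
#' (`tm_window` residues with mean hydropathy >= `h_thresh`) strictly after
#' the motif plus a positively charged tail (>= `tail_min_kr` K/R in the
#' final `tail_len` residues) — the classic Gram-positive cell-wall
#' anchoring architecture.
#'
#' @inheritParams detect_signal_peptide
#' @return 1-based position of the motif leucine, or `NULL`.
#' @export
detect_lpxtg_anchor <- function(sequence, params = classifier_params(), scale = kd_scale()) {
  sequence <- toupper(sequence)
  len <- nchar(sequence)
  if (len < params$lpxtg_c_window) return(NULL)
  s0 <- len - params$lpxtg_c_window + 1L
  # overlapping matches; motif must start at or after s0
  m <- gregexpr("LP(?=.TG)", substr(sequence, s0, len), perl = TRUE)[[1]]
  if (m[1] == -1L) return(NULL)
  pos <- as.integer(m) + s0 - 1L
  pos <- pos[pos + 4L <= len]
  if (length(pos) == 0L) return(NULL)
  motif_pos <- max(pos)                  # closest to the C-terminus
  # transmembrane window strictly after the motif
  tm_from <- motif_pos + 5L
  if (len - tm_from + 1L < params$tm_window) return(NULL)
  vals <- residue_hydropathy(substr(sequence, tm_from, len), scale)
  means <- rolling_mean_na(vals, params$tm_window)
  if (!any(!is.nan(means) & means >= params$h_thresh)) return(NULL)
  # positively charged tail
  tail_seq <- substr(sequence, len - params$tail_len + 1L, len)
  n_kr <- stringr::str_count(tail_seq, "[KR]")
  if (n_kr < params$tail_min_kr) return(NULL)
  motif_pos
}

#' Classify one protein's surface localization
#'
#' Runs all three detectors and assigns a single category with precedence
#' `lpxtg_anchored > lipoprotein > secreted > none` (anchored forms are the
#' most specific evidence; the categories are mutually exclusive). All
#' detector evidence is retained in the returned row.
#'
#' @param id Protein identifier.
#' @inheritParams detect_signal_peptide
#' @return One-row tibble: `protein_id`, `category`, `h_start`, `h_end`,
#'   `cleavage_pos`, `sp_mean_kd`, `lipobox_pos`, `lpxtg_pos`.
#' @export
classify_protein <- function(id, sequence, params = classifier_params(), scale = kd_scale()) {
  calls_to_tibble(list(classify_one(id, sequence, params, scale)))
}

classify_one <- function(id, sequence, params, scale) {
  sp <- detect_signal_peptide(sequence, params, scale)
  lb <- detect_lipobox(sequence, params, scale)
  lp <- detect_lpxtg_anchor(sequence, params, scale)
  category <- if (!is.null(lp)) "lpxtg_anchored"
    else if (!is.null(lb)) "lipoprotein"
    else if (!is.null(sp)) "secreted"
    else "none"
  list(
    protein_id = id,
    category = category,
    h_start = if (is.null(sp)) NA_integer_ else as.integer(sp$h_start),
    h_end = if (is.null(sp)) NA_integer_ else as.integer(sp$h_end),
    cleavage_pos = if (is.null(sp)) NA_integer_ else sp$cleavage_pos,
    sp_mean_kd = if (is.null(sp)) NA_real_ else sp$sp_mean_kd,
    lipobox_pos = if (is.null(lb)) NA_integer_ else as.integer(lb),
    lpxtg_pos = if (is.null(lp)) NA_integer_ else as.integer(lp)
  )
}

calls_to_tibble <- function(calls) {
  tibble::tibble(
    protein_id = vapply(calls, `[[`, character(1), "protein_id"),
    category = vapply(calls, `[[`, character(1), "category"),
    h_start = vapply(calls, `[[`, integer(1), "h_start"),
    h_end = vapply(calls, `[[`, integer(1), "h_end"),
    cleavage_pos = vapply(calls, `[[`, integer(1), "cleavage_pos"),
    sp_mean_kd = vapply(calls, `[[`, numeric(1), "sp_mean_kd"),
    lipobox_pos = vapply(calls, `[[`, integer(1), "lipobox_pos"),
    lpxtg_pos = vapply(calls, `[[`, integer(1), "lpxtg_pos")
  )
}

#' Classify every protein of a proteome
#'
#' @param proteome Proteome tibble (see [read_fasta()]).
#' @param params [classifier_params()].
#' @param scale Hydropathy scale.
#' @return Tibble of per-protein calls (one row per record, input order)
#'   of class `surface_calls`; [surface_summary()] / [glance()] give the
#'   category counts.
#' @export
classify_proteome <- function(proteome, params = classifier_params(), scale = kd_scale()) {
  stopifnot(is.data.frame(proteome), nrow(proteome) >= 1L)
  calls <- purrr::map2(
    proteome$id, proteome$sequence,
    classify_one,
    params = params, scale = scale
  )
  out <- calls_to_tibble(calls)
  class(out) <- c("surface_calls", class(out))
  attr(out, "params") <- params
  out
}

#' Category counts of a surface classification
#'
#' @param calls Result of [classify_proteome()].
#' @return One-row tibble: `n_total`, `n_surface`, `n_secreted`,
#'   `n_lipoprotein`, `n_lpxtg`.
#' @export
surface_summary <- function(calls) {
  tab <- table(factor(calls$category,
    levels = c("secreted", "lipoprotein", "lpxtg_anchored", "none")
  ))
  tibble::tibble(
    n_total = nrow(calls),
    n_surface = sum(tab[c("secreted", "lipoprotein", "lpxtg_anchored")]),
    n_secreted = unname(tab[["secreted"]]),
    n_lipoprotein = unname(tab[["lipoprotein"]]),
    n_lpxtg = unname(tab[["lpxtg_anchored"]])
  )
}

#' @export
glance.surface_calls <- function(x, ...) surface_summary(x)
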