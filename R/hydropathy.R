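#' Kyte-Doolittle hydropathy scale
#'
#' Returns a hydropathy scale: a named numeric vector over the 20 canonical
#' amino acids, plus a `name` attribute used to label downstream outputs.
#' The default is the Kyte & Doolittle (1982) reference scale, on which
#' isoleucine is the most hydrophobic residue (4.5) and arginine the most
#' hydrophilic (-4.5). Ambiguity codes (X/B/Z) and selenocysteine (U) carry
#' no value and are excluded from all averages.
#'
#' @param name Scale name; only `"kyte-doolittle"` is built in. A custom
#'   scale may be supplied to the `scale` argument of the hydropathy
#'   functions as a named numeric vector covering exactly the 20 canonical
#'   residues.
#' @return Named numeric vector of length 20 with attribute `"name"`.
#' @export
#' @examples
#' kd_scale()[c("I", "R", "A")]
kd_scale <- function(name = "kyte-doolittle") {
  if (!identical(name, "kyte-doolittle")) {
    abort(paste0("unknown hydropathy scale: '", name, "'"))
  }
  values <- c(
    A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
    L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
  )
  attr(values, "name") <- name
  values
}

CANONICAL_AA <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)

# letters tolerated on input but never scored
TOLERATED_AA <- c("X", "B", "Z", "U")

check_scale <- function(scale) {
  if (!is.numeric(scale) || is.null(names(scale)) ||
      !setequal(names(scale), CANONICAL_AA) || anyDuplicated(names(scale))) {
    abort("`scale` must be a named numeric vector covering exactly the 20 canonical residues")
  }
  scale
}

# per-residue hydropathy of one sequence; NA for non-canonical letters
residue_hydropathy <- function(sequence, scale = kd_scale()) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  unname(scale[chars])
}

#' Grand average of hydropathy (GRAVY)
#'
#' Arithmetic mean of per-residue Kyte-Doolittle values over the canonical
#' residues of a sequence. Ambiguous letters (X/B/Z) and selenocysteine (U)
#' are excluded from both numerator and denominator rather than scored as 0,
#' so X-rich draft annotations do not get dragged toward hydrophilicity.
#' Negative GRAVY indicates a hydrophilic protein.
#'
#' @param sequence Character vector of amino-acid sequences (case
#'   insensitive). Vectorised.
#' @param scale Hydropathy scale, see [kd_scale()].
#' @return Numeric vector of GRAVY values in `[-4.5, 4.5]`.
#' @seealso [gravy_mature()], [window_hydropathy()]
#' @export
#' @examples
#' gravy("DIK")      # (-3.5 + 4.5 - 3.9) / 3
#' gravy("AXA")      # X excluded -> 1.8
gravy <- function(sequence, scale = kd_scale()) {
  check_scale(scale)
  # residue counting keeps this linear in total sequence length, so whole
  # proteomes can be scored in one call
  seqs <- toupper(sequence)
  counts <- vapply(
    CANONICAL_AA,
    function(res) stringr::str_count(seqs, stringr::fixed(res)),
    numeric(length(seqs))
  )
  if (length(seqs) == 1L) counts <- matrix(counts, nrow = 1L, dimnames = list(NULL, CANONICAL_AA))
  n_canonical <- rowSums(counts)
  if (any(n_canonical == 0L)) {
    abort("GRAVY undefined: sequence contains no canonical residue")
  }
  unname(drop(counts %*% scale[CANONICAL_AA]) / n_canonical)
}

#' Count of residues that contribute to GRAVY
#'
#' @param sequence Character vector of amino-acid sequences.
#' @return Integer vector: canonical residues per sequence.
#' @export
n_scored_residues <- function(sequence) {
  seqs <- toupper(sequence)
  counts <- vapply(
    CANONICAL_AA,
    function(res) stringr::str_count(seqs, stringr::fixed(res)),
    numeric(length(seqs))
  )
  if (length(seqs) == 1L) counts <- matrix(counts, nrow = 1L)
  as.integer(rowSums(counts))
}

#' Mean hydropathy of a sequence window
#'
#' Mean scale value over residues `start .. start + width - 1` (1-based),
#' with the same exclusion rule for non-canonical letters as [gravy()].
#' Used by the surface classifier to find N-terminal hydrophobic regions
#' and C-terminal transmembrane stretches.
#'
#' @param sequence Single amino-acid sequence.
#' @param start 1-based window start.
#' @param width Window width (>= 1).
#' @param scale Hydropathy scale.
#' @return Mean hydropathy of the window (NaN if the window holds no
#'   canonical residue).
#' @export
#' @examples
#' window_hydropathy("LLLLDDDD", 1, 4)  # 3.8
window_hydropathy <- function(sequence, start, width, scale = kd_scale()) {
  check_scale(scale)
  stopifnot(length(sequence) == 1L)
  len <- nchar(sequence)
  if (width < 1L) abort("`width` must be >= 1")
  if (start < 1L || start + width - 1L > len) {
    abort(sprintf(
      "window [%d, %d] out of range for sequence of length %d",
      start, start + width - 1L, len
    ))
  }
  vals <- residue_hydropathy(substr(sequence, start, start + width - 1L), scale)
  mean(vals[!is.na(vals)])
}

#' GRAVY of the mature chain after signal-peptide cleavage
#'
#' GRAVY of residues `cleavage_pos + 1 .. length`, i.e. of the exported
#' moiety once the signal peptide (residues 1..cleavage_pos) is removed.
#'
#' @param sequence Single amino-acid sequence.
#' @param cleavage_pos 1-based index of the last signal-peptide residue;
#'   must leave a nonempty mature chain.
#' @param scale Hydropathy scale.
#' @return GRAVY of the mature chain.
#' @export
#' @examples
#' gravy_mature("LLLLLLDDD", 6)  # GRAVY of "DDD" = -3.5
gravy_mature <- function(sequence, cleavage_pos, scale = kd_scale()) {
  stopifnot(length(sequence) == 1L, length(cleavage_pos) == 1L)
  len <- nchar(sequence)
  if (cleavage_pos < 1L || cleavage_pos >= len) {
    abort(sprintf(
      "cleavage at position %d leaves no mature chain (length %d)",
      cleavage_pos, len
    ))
  }
  gravy(substr(sequence, cleavage_pos + 1L, len), scale)
}

# rolling means of width w over a numeric vector with NA holes
# (non-canonical residues); mean over non-NA entries in each window
rolling_mean_na <- function(vals, w) {
  n <- length(vals)
  if (n < w) return(numeric(0))
  x <- ifelse(is.na(vals), 0, vals)
  k <- as.numeric(!is.na(vals))
  cx <- c(0, cumsum(x))
  ck <- c(0, cumsum(k))
  sums <- cx[(w + 1):(n + 1)] - cx[1:(n - w + 1)]
  cnts <- ck[(w + 1):(n + 1)] - ck[1:(n - w + 1)]
  out <- sums / cnts
  out[cnts == 0] <- NaN
  out
}

#' Add GRAVY columns to a proteome table
#'
#' Computes `gravy_full` and `n_scored` for every record of a proteome
#' tibble (as returned by [read_fasta()]). When the table carries a
#' `cleavage_pos` column (from [classify_proteome()]), `gravy_mature` is
#' filled for rows with a signal-peptide call and left `NA` otherwise.
#'
#' @param proteome Tibble with at least `id` and `sequence` columns.
#' @param scale Hydropathy scale.
#' @return The input tibble with `gravy_full`, `n_scored` (and possibly
#'   `gravy_mature`) columns added.
#' @export
add_gravy <- function(proteome, scale = kd_scale()) {
  stopifnot(is.data.frame(proteome), all(c("id", "sequence") %in% names(proteome)))
  out <- dplyr::mutate(
    tibble::as_tibble(proteome),
    gravy_full = gravy(.data$sequence, scale),
    n_scored = n_scored_residues(.data$sequence)
  )
  if ("cleavage_pos" %in% names(out)) {
    out$gravy_mature <- purrr::map2_dbl(
      out$sequence, out$cleavage_pos,
      function(s, cp) if (is.na(cp)) NA_real_ else gravy_mature(s, cp, scale)
    )
  }
  out
}
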