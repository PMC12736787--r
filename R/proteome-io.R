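#' Read a protein FASTA file into a proteome tibble
#'
#' Parses a multi-record amino-acid FASTA and validates it for downstream
#' hydropathy analysis. Sequences are upper-cased and a single trailing stop
#' (`*`) is stripped; an internal `*` is rejected so truncated ORFs are not
#' silently accepted (GRAVY is undefined for stops). Record ids are the
#' header token before the first whitespace and must be unique. The 20
#' canonical residues plus X/B/Z/U are accepted; anything else is a
#' validation error reporting the offending position.
#'
#' @param path Path to a FASTA file.
#' @param source_label Label recorded on the result (defaults to the file
#'   name); carried into reports for provenance.
#' @return Tibble with columns `id`, `description`, `sequence`, in file
#'   order, with attribute `source_label`.
#' @export
read_fasta <- function(path, source_label = basename(path)) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (!any(startsWith(readLines(path, warn = FALSE), ">"))) {
    abort(paste0("empty proteome: no FASTA records in ", path))
  }
  recs <- tryCatch(
    seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE, forceDNAtolower = FALSE),
    error = function(e) abort(paste0("not a readable FASTA file: ", path, " (", conditionMessage(e), ")"))
  )
  if (length(recs) == 0L) abort(paste0("empty proteome: no FASTA records in ", path))
  ids <- vapply(recs, function(r) attr(r, "name"), character(1))
  annots <- vapply(recs, function(r) attr(r, "Annot") %||% "", character(1))
  desc <- sub("^>\\S*\\s*", "", annots)
  seqs <- toupper(vapply(recs, as.character, character(1)))

  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    abort(paste0("duplicate sequence id(s): ", paste(unique(dup), collapse = ", ")))
  }
  if (any(!nzchar(ids))) abort("empty sequence id in FASTA header")

  # one trailing stop codon is tolerated and stripped
  seqs <- sub("\\*$", "", seqs)
  validate_sequences(ids, seqs)

  out <- tibble::tibble(id = unname(ids), description = unname(desc), sequence = unname(seqs))
  attr(out, "source_label") <- source_label
  out
}

validate_sequences <- function(ids, seqs) {
  legal <- paste0(c(CANONICAL_AA, TOLERATED_AA), collapse = "")
  bad_pos <- regexpr(paste0("[^", legal, "]"), seqs)
  if (any(bad_pos > 0L)) {
    i <- which(bad_pos > 0L)[1]
    abort(sprintf(
      "invalid residue '%s' at position %d of sequence '%s'",
      substr(seqs[i], bad_pos[i], bad_pos[i]), bad_pos[i], ids[i]
    ))
  }
  if (any(nchar(seqs) == 0L)) {
    abort(paste0("empty sequence for id '", ids[which(nchar(seqs) == 0L)[1]], "'"))
  }
  invisible(TRUE)
}

#' Write a proteome tibble to FASTA
#'
#' @param proteome Tibble with `id`, `sequence` and optionally `description`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteome, path) {
  stopifnot(all(c("id", "sequence") %in% names(proteome)))
  desc <- proteome$description %||% rep("", nrow(proteome))
  names <- ifelse(nzchar(desc), paste(proteome$id, desc), proteome$id)
  seqinr::write.fasta(
    sequences = as.list(proteome$sequence),
    names = names,
    file.out = path,
    as.string = TRUE,
    nbchar = 70
  )
  invisible(path)
}

#' Write a result table to TSV or JSON
#'
#' Serialises a collection of homogeneous rows with a deterministic column
#' order (sorted names unless `col_order` is given), so repeated runs
#' produce byte-identical files. Values round-trip without loss (TSV at
#' full precision; JSON with unrounded digits).
#'
#' @param rows Data frame, or list of named lists sharing one key set.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @param col_order Optional character vector fixing the column order.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path, format = c("tsv", "json"), col_order = NULL) {
  format <- match.arg(format)
  if (!is.data.frame(rows)) {
    if (length(rows) > 0L) {
      keys <- lapply(rows, function(r) sort(names(r)))
      ref <- keys[[1]]
      bad <- which(!vapply(keys, identical, logical(1), ref))
      if (length(bad) > 0L) {
        abort(sprintf(
          "row %d has keys {%s}; expected {%s}",
          bad[1], paste(keys[[bad[1]]], collapse = ","), paste(ref, collapse = ",")
        ))
      }
    }
    rows <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  }
  cols <- col_order %||% sort(names(rows))
  if (!setequal(cols, names(rows))) abort("`col_order` must name exactly the table's columns")
  rows <- rows[, cols, drop = FALSE]
  if (format == "tsv") {
    readr::write_tsv(rows, path)
  } else {
    jsonlite::write_json(rows, path, dataframe = "rows", digits = NA, na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Read a table written by [write_table()]
#'
#' @param path File path.
#' @param format `"tsv"` or `"json"` (guessed from the extension by default).
#' @return Tibble.
#' @export
read_table <- function(path, format = NULL) {
  format <- format %||% if (grepl("\\.json$", path)) "json" else "tsv"
  if (format == "tsv") {
    readr::read_tsv(path, show_col_types = FALSE)
  } else {
    tibble::as_tibble(jsonlite::fromJSON(path))
  }
}
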