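# Peptide sequences, validation, and dataset input/output.

#' Standard amino-acid alphabet
#'
#' The 20 standard one-letter residue codes in alphabetical order
#' (Ala first). All encoders, property scales and feature names use this
#' fixed order.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Validate peptide sequences
#'
#' Normalizes sequences to uppercase and checks that every character is one
#' of the 20 standard residue codes. Ambiguity and non-natural codes
#' (B, J, O, U, X, Z) are rejected, not imputed: the models cover peptides
#' composed of natural amino acids only.
#'
#' @param sequences Character vector of peptide sequences.
#' @param ids Optional identifiers used in error messages; defaults to
#'   `seq_along(sequences)`.
#' @return The validated, uppercased character vector (invisibly the same
#'   length and order as the input).
#' @examples
#' validate_peptides(c("gildh", "ACDEF"))
#' @export
validate_peptides <- function(sequences, ids = NULL) {
  if (length(sequences) == 0L) stop("no sequences", call. = FALSE)
  if (is.null(ids)) ids <- as.character(seq_along(sequences))
  sequences <- toupper(sequences)
  for (i in seq_along(sequences)) {
    s <- sequences[i]
    if (!nzchar(s)) stop(sprintf("record '%s': empty sequence", ids[i]), call. = FALSE)
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    bad <- which(!chars %in% AA_ALPHABET)
    if (length(bad) > 0L) {
      stop(sprintf(
        "record '%s': illegal character '%s' at position %d (allowed: %s)",
        ids[i], chars[bad[1L]], bad[1L], paste(AA_ALPHABET, collapse = "")),
        call. = FALSE)
    }
  }
  sequences
}

#' Read peptide or protein sequences
#'
#' Reads multi-record FASTA (wrapped or unwrapped lines) or plain text with
#' one sequence per line. The format is auto-detected from the first
#' non-empty line (`>` starts FASTA) unless `format` is given. Sequences
#' are uppercased and validated against the 20-letter alphabet; records
#' with illegal characters are rejected with the offending symbol and
#' position. Input order is preserved.
#'
#' @param path Path to the input file, or a character vector of lines.
#' @param format One of `"auto"`, `"fasta"`, `"text"`.
#' @return Named character vector of sequences (names are FASTA ids or
#'   `seq1`, `seq2`, ... for plain text).
#' @export
read_peptides <- function(path, format = c("auto", "fasta", "text")) {
  format <- match.arg(format)
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path, warn = FALSE) else path
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("no sequences", call. = FALSE)
  if (format == "auto") {
    format <- if (startsWith(lines[1L], ">")) "fasta" else "text"
  }
  if (format == "fasta") {
    if (!startsWith(lines[1L], ">"))
      stop("not FASTA: first record lacks a '>' header", call. = FALSE)
    header_idx <- which(startsWith(lines, ">"))
    ids <- sub("^>\\s*", "", lines[header_idx])
    ids <- vapply(strsplit(ids, "\\s+"), `[`, character(1L), 1L)
    bounds <- c(header_idx, length(lines) + 1L)
    seqs <- vapply(seq_along(header_idx), function(i) {
      body <- lines[seq.int(bounds[i] + 1L, bounds[i + 1L] - 1L)]
      if (bounds[i] + 1L > bounds[i + 1L] - 1L) "" else paste(body, collapse = "")
    }, character(1L))
  } else {
    ids <- paste0("seq", seq_along(lines))
    seqs <- lines
  }
  seqs <- validate_peptides(seqs, ids)
  names(seqs) <- ids
  seqs
}

#' Construct a half-life dataset
#'
#' A half-life dataset is a data frame with columns `sequence` (validated
#' peptide) and `half_life_s` (strictly positive seconds), the unit of
#' training and evaluation throughout the package.
#'
#' @param sequence Character vector of peptide sequences.
#' @param half_life_s Numeric vector of half-lives in seconds, all > 0.
#' @return A `data.frame` of class `c("hl_dataset", "data.frame")`.
#' @export
hl_dataset <- function(sequence, half_life_s) {
  sequence <- validate_peptides(sequence)
  half_life_s <- as.numeric(half_life_s)
  if (length(half_life_s) != length(sequence))
    stop("sequence and half_life_s lengths differ", call. = FALSE)
  if (anyNA(half_life_s) || any(half_life_s <= 0))
    stop("half_life_s must be positive decimal seconds", call. = FALSE)
  out <- data.frame(sequence = sequence, half_life_s = half_life_s,
                    stringsAsFactors = FALSE)
  class(out) <- c("hl_dataset", "data.frame")
  out
}

#' Read a half-life dataset from TSV/CSV
#'
#' Expects a header with columns `sequence` and `half_life_s` (UTF-8);
#' the separator is taken from the file extension (`.csv` is comma,
#' anything else tab).
#'
#' @param path File path.
#' @return An [hl_dataset()].
#' @export
read_hl_dataset <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("sequence", "half_life_s")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L)
    stop("dataset is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  hl_dataset(df$sequence, df$half_life_s)
}

#' Write a half-life dataset as TSV
#'
#' @param ds An [hl_dataset()] (or compatible data frame).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_hl_dataset <- function(ds, path) {
  utils::write.table(as.data.frame(ds)[, c("sequence", "half_life_s")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
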