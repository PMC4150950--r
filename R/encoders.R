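# Feature encoders: k-mer compositions and positional binary profiles.
#
# Conventions fixed across the package:
#  * residue order is alphabetical one-letter (Ala first), see AA_ALPHABET;
#  * k-mer composition uses overlapping windows with denominator L - k + 1,
#    so every composition row sums to 1;
#  * compositions are fractions, not percentages.

kmer_names <- function(k) {
  stopifnot(k %in% 1:3)
  out <- AA_ALPHABET
  for (i in seq_len(k - 1L)) {
    out <- as.vector(t(outer(out, AA_ALPHABET, paste0)))
  }
  out
}

seq_to_idx <- function(sequence) {
  match(strsplit(sequence, "", fixed = TRUE)[[1L]], AA_ALPHABET)
}

#' Extract a terminal region of a peptide
#'
#' Returns the first (`end = "N"`) or last (`end = "C"`) `k` residues,
#' keeping the native N-to-C orientation in both cases.
#'
#' @param sequence A validated peptide sequence.
#' @param end `"N"` or `"C"`.
#' @param k Window size; must not exceed the peptide length.
#' @return The terminal subsequence as a character scalar.
#' @examples
#' terminal_region("ACDEFGHIKL", "N", 5)  # "ACDEF"
#' terminal_region("ACDEFGHIKL", "C", 5)  # "GHIKL"
#' @export
terminal_region <- function(sequence, end = c("N", "C"), k) {
  end <- match.arg(end)
  n <- nchar(sequence)
  if (k > n) stop("terminal window exceeds peptide length", call. = FALSE)
  if (end == "N") substr(sequence, 1L, k) else substr(sequence, n - k + 1L, n)
}

#' k-mer composition of a peptide
#'
#' Fraction of each of the 20^k possible k-mers among the L - k + 1
#' overlapping windows of the (region-restricted) sequence, in fixed
#' lexicographic order. Dimensions are 20, 400 and 8000 for k = 1, 2, 3.
#'
#' @param sequence A validated peptide sequence.
#' @param k k-mer size, 1, 2 or 3.
#' @param region `"full"`, `"nterm"` or `"cterm"`.
#' @param region_length Terminal window size when `region != "full"`
#'   (the published models use 5 and 10).
#' @return Named numeric vector of length 20^k summing to 1.
#' @examples
#' kmer_composition("ACACA", 2)[c("AC", "CA")]  # 0.5 0.5
#' @export
kmer_composition <- function(sequence, k, region = "full", region_length = NULL) {
  sequence <- apply_region(sequence, region, region_length)
  L <- nchar(sequence)
  if (L < k) stop("sequence too short for k-mer", call. = FALSE)
  idx <- seq_to_idx(sequence)
  nw <- L - k + 1L
  codes <- idx[seq_len(nw)]
  if (k >= 2L) codes <- (codes - 1L) * 20L + idx[seq_len(nw) + 1L]
  if (k >= 3L) codes <- (codes - 1L) * 20L + idx[seq_len(nw) + 2L]
  v <- tabulate(codes, nbins = 20L^k) / nw
  names(v) <- kmer_names(k)
  v
}

apply_region <- function(sequence, region, region_length) {
  if (identical(region, "full")) return(sequence)
  if (is.null(region_length))
    stop("region_length is required for terminal regions", call. = FALSE)
  terminal_region(sequence, if (region == "nterm") "N" else "C", region_length)
}

#' Positional binary profile of a peptide
#'
#' One-hot encoding: each position contributes a 20-cell indicator block in
#' alphabetical residue order (Ala is `1,0,...,0`), concatenated
#' N-terminus first; total length 20 times the region length.
#'
#' @inheritParams kmer_composition
#' @return Named 0/1 vector of length `20 * L`; every 20-cell block sums
#'   to exactly 1.
#' @export
binary_profile <- function(sequence, region = "full", region_length = NULL) {
  sequence <- apply_region(sequence, region, region_length)
  idx <- seq_to_idx(sequence)
  L <- length(idx)
  v <- numeric(20L * L)
  v[(seq_len(L) - 1L) * 20L + idx] <- 1
  names(v) <- as.vector(vapply(seq_len(L), function(p)
    sprintf("p%d.%s", p, AA_ALPHABET), character(20L)))
  v
}

#' Decode a binary profile back to a sequence
#'
#' Inverse of [binary_profile()] for full-region profiles.
#'
#' @param profile A 0/1 vector whose length is a multiple of 20 and whose
#'   20-cell blocks each sum to 1.
#' @return The peptide sequence.
#' @export
decode_binary_profile <- function(profile) {
  stopifnot(length(profile) %% 20L == 0L)
  m <- matrix(profile, nrow = 20L)
  if (!all(colSums(m) == 1) || !all(profile %in% c(0, 1)))
    stop("not a one-hot profile", call. = FALSE)
  paste(AA_ALPHABET[apply(m, 2L, which.max)], collapse = "")
}

#' Encoder specification
#'
#' Bundles an encoding kind with an optional terminal-region restriction.
#' The resulting feature space is fully determined: 20 / 400 / 8000
#' features for amino acid, dipeptide and tripeptide composition over the
#' chosen region, and 20 per position for the binary profile.
#'
#' @param kind `"aac"`, `"dpc"`, `"tpc"` (k = 1, 2, 3 composition) or
#'   `"binary"`.
#' @param region `"full"`, `"nterm"` or `"cterm"`.
#' @param region_length Terminal window size; required when
#'   `region != "full"`.
#' @return An object of class `"hlp_encoder"`.
#' @export
encoder <- function(kind = c("aac", "dpc", "tpc", "binary"),
                    region = c("full", "nterm", "cterm"),
                    region_length = NULL) {
  kind <- match.arg(kind)
  region <- match.arg(region)
  if (region != "full") {
    if (is.null(region_length) || region_length < 1L)
      stop("region_length must be a positive integer for terminal regions",
           call. = FALSE)
    region_length <- as.integer(region_length)
  }
  structure(list(kind = kind,
                 k = match(kind, c("aac", "dpc", "tpc"), nomatch = NA_integer_),
                 region = region, region_length = region_length),
            class = "hlp_encoder")
}

#' @export
print.hlp_encoder <- function(x, ...) {
  dim_str <- if (x$kind == "binary") "20 x region length" else
    format(20L^x$k, big.mark = ",")
  cat(sprintf("<hlp_encoder> kind=%s region=%s%s (dimension %s)\n",
              x$kind, x$region,
              if (is.null(x$region_length)) "" else paste0(":", x$region_length),
              dim_str))
  invisible(x)
}

encoder_dimension <- function(enc, peptide_length = NULL) {
  if (enc$kind != "binary") return(20L^enc$k)
  L <- if (enc$region == "full") peptide_length else enc$region_length
  if (is.null(L)) stop("binary full-region dimension needs the peptide length",
                       call. = FALSE)
  20L * L
}

#' Encode peptides into a feature matrix
#'
#' Applies an encoder to each sequence; rows align with the input order and
#' carry identical feature names. Binary encoding over the full region
#' requires uniform peptide length.
#'
#' @param sequences Character vector of validated peptides, or an
#'   [hl_dataset()].
#' @param enc An [encoder()].
#' @return Numeric matrix, one row per peptide, with feature-name column
#'   names.
#' @export
encode_peptides <- function(sequences, enc) {
  if (inherits(sequences, "hl_dataset") || is.data.frame(sequences))
    sequences <- sequences$sequence
  if (length(sequences) == 0L) stop("no sequences", call. = FALSE)
  if (enc$kind == "binary") {
    lens <- nchar(sequences)
    if (enc$region == "full" && length(unique(lens)) > 1L)
      stop("binary encoding requires uniform length", call. = FALSE)
  }
  rows <- lapply(seq_along(sequences), function(i) {
    tryCatch({
      if (enc$kind == "binary")
        binary_profile(sequences[i], enc$region, enc$region_length)
      else
        kmer_composition(sequences[i], enc$k, enc$region, enc$region_length)
    }, error = function(e) {
      stop(sprintf("record %d ('%s'): %s", i, sequences[i], conditionMessage(e)),
           call. = FALSE)
    })
  })
  X <- do.call(rbind, rows)
  rownames(X) <- if (!is.null(names(sequences))) names(sequences) else NULL
  X
}

#' Write a feature matrix as CSV
#'
#' @param X Matrix from [encode_peptides()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(X, path) {
  utils::write.csv(as.data.frame(X), path, row.names = FALSE)
  invisible(path)
}
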