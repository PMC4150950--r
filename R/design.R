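# In-silico design workflows: single-point mutant design, whole-protein
# scanning, and batch filtering. All coordinates in reports are 1-based
# and inclusive.

#' Enumerate all single-point mutants of a peptide
#'
#' Generates every single-residue substitution — 19 per position, so
#' exactly `19 * N` mutants for a length-`N` parent — in deterministic
#' order (position-major, substituted residue alphabetical). The parent
#' itself is excluded.
#'
#' @param sequence A validated peptide.
#' @return Data frame with columns `position` (1-based), `original`,
#'   `substituted`, `mutant`.
#' @export
generate_mutants <- function(sequence) {
  sequence <- validate_peptides(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  rows <- lapply(seq_len(n), function(pos) {
    subs <- setdiff(AA_ALPHABET, chars[pos])
    muts <- vapply(subs, function(r) {
      m <- chars
      m[pos] <- r
      paste(m, collapse = "")
    }, character(1L))
    data.frame(position = pos, original = chars[pos], substituted = subs,
               mutant = unname(muts), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Score and rank single-point mutants
#'
#' Scores the parent and all `19 * N` mutants with a fitted model, sorts
#' by predicted half-life (descending; ties by position then substituted
#' residue), flags mutants predicted to outlive the parent, and reports
#' physicochemical deltas relative to the parent for the full property
#' panel.
#'
#' @param sequence Parent peptide.
#' @param model An `"hlp_model"` whose encoder accepts the parent length.
#' @param top Return only the `top` highest-ranked mutants (`Inf` for
#'   all).
#' @return An object of class `"hlp_mutants"`: `parent`,
#'   `parent_half_life`, and `mutants`, a data frame with prediction,
#'   `improves_parent`, and `delta_*` columns for each physicochemical
#'   property.
#' @export
rank_mutants <- function(sequence, model, top = Inf) {
  sequence <- validate_peptides(sequence)
  mut <- generate_mutants(sequence)
  parent_pred <- predict(model, sequence)
  mut$predicted_half_life_s <- predict(model, mut$mutant)
  ord <- order(-mut$predicted_half_life_s, mut$position,
               match(mut$substituted, AA_ALPHABET))
  mut <- mut[ord, , drop = FALSE]
  mut$improves_parent <- mut$predicted_half_life_s > parent_pred
  if (is.finite(top)) mut <- utils::head(mut, top)
  parent_props <- peptide_properties(sequence)
  mut_props <- peptide_properties(mut$mutant)
  prop_cols <- setdiff(names(parent_props), c("sequence", "length"))
  for (p in prop_cols) {
    mut[[paste0("delta_", p)]] <- mut_props[[p]] - parent_props[[p]]
  }
  rownames(mut) <- NULL
  structure(list(parent = sequence, parent_half_life = parent_pred,
                 mutants = mut), class = "hlp_mutants")
}

#' @export
print.hlp_mutants <- function(x, ...) {
  cat(sprintf("<hlp_mutants> parent %s, predicted half-life %.4g s\n",
              x$parent, x$parent_half_life))
  better <- sum(x$mutants$improves_parent)
  cat(sprintf("  %d mutant(s) scored, %d predicted above the parent\n",
              nrow(x$mutants), better))
  print(utils::head(x$mutants[, c("position", "original", "substituted",
                                  "mutant", "predicted_half_life_s")], 5L))
  invisible(x)
}

#' Scan a protein for high half-life peptide windows
#'
#' Slides a window of length `window` along the protein with step 1
#' (`L - window + 1` windows), scores each window with the model, and
#' reports the windows with 1-based inclusive coordinates plus the
#' arg-max window.
#'
#' @param protein A validated protein sequence.
#' @param window Window length; must not exceed the protein length and
#'   must be compatible with the model encoder.
#' @param model An `"hlp_model"`.
#' @return An object of class `"hlp_scan"`: `windows` (data frame
#'   `start`, `end`, `subsequence`, `predicted_half_life_s`) and `best`
#'   (the highest-scoring row).
#' @export
scan_protein <- function(protein, window, model) {
  protein <- validate_peptides(protein)
  window <- as.integer(window)
  L <- nchar(protein)
  if (window > L)
    stop(sprintf("window (%d) exceeds protein length (%d)", window, L),
         call. = FALSE)
  starts <- seq_len(L - window + 1L)
  subs <- substring(protein, starts, starts + window - 1L)
  preds <- predict(model, subs)
  windows <- data.frame(start = starts, end = starts + window - 1L,
                        subsequence = subs,
                        predicted_half_life_s = preds,
                        stringsAsFactors = FALSE)
  best <- windows[which.max(windows$predicted_half_life_s), , drop = FALSE]
  structure(list(protein = protein, window = window, windows = windows,
                 best = best), class = "hlp_scan")
}

#' @export
print.hlp_scan <- function(x, ...) {
  cat(sprintf("<hlp_scan> %d windows of length %d over a %d-residue protein\n",
              nrow(x$windows), x$window, nchar(x$protein)))
  cat(sprintf("  best: %s at %d-%d, predicted %.4g s\n",
              x$best$subsequence, x$best$start, x$best$end,
              x$best$predicted_half_life_s))
  invisible(x)
}

#' Filter a batch of peptides by predicted half-life and properties
#'
#' Scores every peptide, keeps those with predicted half-life at least
#' `min_half_life` whose physicochemical panel satisfies all supplied
#' bounds, and returns them sorted by prediction (descending).
#'
#' @param peptides Character vector of peptides (or an [hl_dataset()]).
#' @param model An `"hlp_model"`.
#' @param min_half_life Minimum predicted half-life in seconds.
#' @param property_constraints Optional named list of `c(lower, upper)`
#'   bounds (use `-Inf`/`Inf` for one-sided) on columns of
#'   [peptide_properties()], e.g.
#'   `list(net_charge_ph7 = c(-Inf, 0))`.
#' @return An object of class `"hlp_batch"`: `kept` (scored data frame,
#'   sorted), `n_in`, `n_kept`.
#' @export
batch_filter <- function(peptides, model, min_half_life = 0,
                         property_constraints = NULL) {
  if (inherits(peptides, "hl_dataset") || is.data.frame(peptides))
    peptides <- peptides$sequence
  peptides <- validate_peptides(peptides)
  props <- peptide_properties(peptides)
  if (!is.null(property_constraints)) {
    for (nm in names(property_constraints)) {
      b <- property_constraints[[nm]]
      if (!nm %in% names(props))
        stop("unknown property '", nm, "'", call. = FALSE)
      if (length(b) != 2L || b[1L] > b[2L])
        stop("invalid bounds for '", nm, "': lower must not exceed upper",
             call. = FALSE)
    }
  }
  pred <- predict(model, peptides)
  keep <- pred >= min_half_life
  if (!is.null(property_constraints)) {
    for (nm in names(property_constraints)) {
      b <- property_constraints[[nm]]
      keep <- keep & props[[nm]] >= b[1L] & props[[nm]] <= b[2L]
    }
  }
  out <- data.frame(sequence = peptides,
                    predicted_half_life_s = pred,
                    stringsAsFactors = FALSE)
  out <- cbind(out, props[, setdiff(names(props), "sequence"), drop = FALSE])
  out <- out[keep, , drop = FALSE]
  out <- out[order(-out$predicted_half_life_s, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  structure(list(kept = out, n_in = length(peptides), n_kept = nrow(out),
                 min_half_life = min_half_life,
                 property_constraints = property_constraints),
            class = "hlp_batch")
}

#' @export
print.hlp_batch <- function(x, ...) {
  cat(sprintf("<hlp_batch> %d of %d peptide(s) retained (min half-life %g s)\n",
              x$n_kept, x$n_in, x$min_half_life))
  invisible(x)
}
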