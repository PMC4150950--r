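# Correlation-based feature-subset selection (CFS) with forward
# best-first search.
#
# Merit of a subset S with k = |S|:
#
#     merit(S) = k * rcf / sqrt(k + k * (k - 1) * rff)
#
# where rcf is the mean absolute Pearson correlation between the features
# in S and the half-life target, and rff the mean absolute pairwise
# correlation within S. The search is forward best-first from the empty
# set, terminating after `stale_limit` consecutive expansions that do not
# improve the best merit found (the classic -N 5 stopping rule); ties are
# broken by feature order, which is lexicographic for every encoder, so
# the search is fully deterministic.
#
# Selection is run on the full training set by default, mirroring the
# original modelling protocol. Note this leaks target information into any
# subsequent cross-validation of a model restricted to the selected
# features; use cross_validate(..., nested_selection = TRUE) for an
# unbiased estimate.

abs_cor_with_target <- function(X, y) {
  sds <- apply(X, 2L, stats::sd)
  r <- rep(0, ncol(X))
  ok <- sds > 0 & stats::sd(y) > 0
  if (any(ok))
    r[ok] <- abs(suppressWarnings(stats::cor(X[, ok, drop = FALSE], y)))
  r[is.na(r)] <- 0
  stats::setNames(r, colnames(X))
}

abs_cor_matrix <- function(X) {
  C <- suppressWarnings(stats::cor(X))
  C[is.na(C)] <- 0
  abs(C)
}

#' Absolute feature-target correlations
#'
#' Per-feature absolute Pearson correlation with the half-life target.
#' Constant features get 0 (not `NA`), so degenerate columns never
#' contribute relevance.
#'
#' @param X Feature matrix from [encode_peptides()].
#' @param y Half-lives (seconds), aligned with the rows of `X`.
#' @return Named numeric vector in `[0, 1]`.
#' @export
feature_target_correlation <- function(X, y) {
  stopifnot(nrow(X) == length(y), nrow(X) >= 3L)
  abs_cor_with_target(X, y)
}

#' CFS merit of a feature subset
#'
#' @param subset Character vector of feature names (columns of `X`); the
#'   empty subset has merit 0 by convention.
#' @inheritParams feature_target_correlation
#' @return Merit score in `[0, 1]`.
#' @export
cfs_merit <- function(subset, X, y) {
  unknown <- setdiff(subset, colnames(X))
  if (length(unknown) > 0L)
    stop("unknown feature name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (length(subset) == 0L) return(0)
  rcf <- abs_cor_with_target(X[, subset, drop = FALSE], y)
  rff <- abs_cor_matrix(X[, subset, drop = FALSE])
  merit_from_cors(match(subset, subset), rcf, rff)
}

merit_from_cors <- function(idx, rcf, rff) {
  k <- length(idx)
  if (k == 0L) return(0)
  mean_rcf <- mean(rcf[idx])
  if (k == 1L) return(mean_rcf)
  sub_ff <- rff[idx, idx]
  mean_rff <- mean(sub_ff[upper.tri(sub_ff)])
  k * mean_rcf / sqrt(k + k * (k - 1) * mean_rff)
}

#' Best-first CFS feature selection
#'
#' Forward best-first search over feature subsets scored by [cfs_merit()].
#' Maintains a queue of evaluated subsets, repeatedly expands the
#' best-merit unexpanded subset by single-feature additions, and stops
#' after `stale_limit` consecutive expansions without improving the best
#' merit found.
#'
#' After the search, the locally predictive post-step (the default
#' behaviour of the reference CFS implementation) scans the remaining
#' features in decreasing target correlation and admits any feature more
#' correlated with the target than with every already-selected feature;
#' this recovers relevant features that the merit's redundancy penalty
#' would otherwise leave out of small subsets. Disable with
#' `locally_predictive = FALSE` for the bare merit-maximising subset.
#'
#' @inheritParams feature_target_correlation
#' @param stale_limit Consecutive non-improving expansions tolerated
#'   before stopping (default 5).
#' @param locally_predictive Apply the locally predictive post-step
#'   (default `TRUE`).
#' @param max_trace Maximum number of evaluated subsets kept in the
#'   returned trace.
#' @return An object of class `"hlp_selection"`: `selected` (feature names
#'   in discovery order), `merit` (of the best-first subset, before the
#'   post-step), and `trace` (a data frame of evaluated subsets and their
#'   merits).
#' @export
best_first_select <- function(X, y, stale_limit = 5L,
                              locally_predictive = TRUE,
                              max_trace = 10000L) {
  stopifnot(ncol(X) >= 1L)
  rcf <- abs_cor_with_target(X, y)
  rff <- abs_cor_matrix(X)
  p <- ncol(X)

  node_key <- function(idx) paste0("s", paste(sort(idx), collapse = ","))
  seen <- new.env(hash = TRUE, parent = emptyenv())
  open_sets <- list(integer(0))
  open_merit <- 0
  open_expanded <- FALSE
  assign(node_key(integer(0)), TRUE, envir = seen)

  best_idx <- integer(0)
  best_merit <- 0
  stale <- 0L
  trace_keys <- character(0)
  trace_merits <- numeric(0)

  while (stale < stale_limit) {
    cand <- which(!open_expanded)
    if (length(cand) == 0L) break
    pick <- cand[which.max(open_merit[cand])]
    open_expanded[pick] <- TRUE
    base <- open_sets[[pick]]
    improved <- FALSE
    for (j in setdiff(seq_len(p), base)) {
      child <- c(base, j)
      key <- node_key(child)
      if (!is.null(seen[[key]])) next
      assign(key, TRUE, envir = seen)
      m <- merit_from_cors(child, rcf, rff)
      open_sets[[length(open_sets) + 1L]] <- child
      open_merit <- c(open_merit, m)
      open_expanded <- c(open_expanded, FALSE)
      if (length(trace_keys) < max_trace) {
        trace_keys <- c(trace_keys, paste(colnames(X)[child], collapse = ","))
        trace_merits <- c(trace_merits, m)
      }
      if (m > best_merit + 1e-9) {
        best_merit <- m
        best_idx <- child
        improved <- TRUE
      }
    }
    stale <- if (improved) 0L else stale + 1L
  }

  if (locally_predictive && length(best_idx) > 0L) {
    remaining <- setdiff(order(-rcf), best_idx)
    for (j in remaining) {
      if (rcf[j] <= 0) break
      if (rcf[j] > max(rff[j, best_idx])) best_idx <- c(best_idx, j)
    }
  }

  structure(list(
    selected = colnames(X)[best_idx],
    merit = best_merit,
    trace = data.frame(subset = trace_keys, merit = trace_merits,
                       stringsAsFactors = FALSE)),
    class = "hlp_selection")
}

#' @export
print.hlp_selection <- function(x, ...) {
  cat(sprintf("<hlp_selection> %d feature(s), merit %.4f\n",
              length(x$selected), x$merit))
  if (length(x$selected) > 0L)
    cat("  ", paste(x$selected, collapse = ", "), "\n", sep = "")
  invisible(x)
}

## --- Published feature-set configurations ----------------------------

BUILTIN_FEATURE_SETS <- list(
  hl10_aac4 = list(
    features = c("D", "G", "P", "R"),
    encoder = "aac", learner = "knn", weighting = "inverse",
    note = "4 residues selected on the 10mer set; instance-based model"),
  hl10_dpc8 = list(
    features = c("EK", "EL", "GD", "GF", "IE", "KP", "PG", "YL"),
    encoder = "dpc", learner = "knn", weighting = "uniform",
    note = "8 dipeptides selected on the 10mer set; instance-based model"),
  hl10_tpc38 = list(
    features = c("AAH", "AGR", "AMP", "ARE", "ASV", "DSI", "EEK", "ELY",
                 "ESK", "FCI", "FGD", "FSL", "FSS", "FYC", "GDS", "GFG",
                 "GLF", "GSI", "GTS", "ILP", "INF", "INK", "IRN", "ITK",
                 "KIL", "KIS", "KLP", "LVL", "MVL", "PGF", "PVQ", "SGL",
                 "SIE", "SLR", "SVL", "VFK", "VLF", "VYL"),
    encoder = "tpc", learner = "knn", weighting = "uniform",
    note = "38 tripeptides selected on the 10mer set; instance-based model"),
  hl16_aac4 = list(
    features = c("C", "D", "G", "R"),
    encoder = "aac", learner = "dtable", weighting = "uniform",
    note = "4 residues selected on the 16mer set; decision-table model"),
  hl16_dpc3 = list(
    features = c("CG", "GD", "GF"),
    encoder = "dpc", learner = "dtable", weighting = "uniform",
    note = "3 dipeptides selected on the 16mer set; decision-table model"),
  hl16_tpc5 = list(
    features = c("AQC", "EAQ", "FGD", "GFG", "QCG"),
    encoder = "tpc", learner = "dtable", weighting = "uniform",
    note = "5 tripeptides selected on the 16mer set; decision-table model")
)

#' Published feature-set configurations
#'
#' The feature subsets reported for the original 10mer and 16mer half-life
#' models ship as named configurations so the published model forms can be
#' reconstructed on user (or simulated) data without re-running selection.
#' The original training data are not redistributable, so these are
#' configurations — encoder, learner and feature subset — to be trained on
#' data you supply, not fitted models.
#'
#' Available names: `hl10_aac4` (D, G, P, R), `hl10_dpc8` (EK, EL, GD, GF,
#' IE, KP, PG, YL), `hl10_tpc38` (38 tripeptides), `hl16_aac4`
#' (C, D, G, R), `hl16_dpc3` (CG, GD, GF), `hl16_tpc5` (5 tripeptides).
#'
#' @param name Configuration name; omit to list all names.
#' @return A list with elements `name`, `features`, `encoder`, `learner`,
#'   `weighting`, `note`; or the vector of available names.
#' @export
builtin_features <- function(name = NULL) {
  if (is.null(name)) return(names(BUILTIN_FEATURE_SETS))
  if (!name %in% names(BUILTIN_FEATURE_SETS))
    stop("unknown built-in feature set '", name, "'; available: ",
         paste(names(BUILTIN_FEATURE_SETS), collapse = ", "), call. = FALSE)
  c(list(name = name), BUILTIN_FEATURE_SETS[[name]])
}
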