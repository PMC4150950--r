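# Cross-validated evaluation and the stable-vs-unstable group analysis.

with_preserved_rng <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

fold_assignment <- function(n, n_folds = 5L, seed = 1L, y = NULL) {
  sizes <- rep(n %/% n_folds, n_folds)
  if (n %% n_folds > 0L) sizes[seq_len(n %% n_folds)] <- sizes[seq_len(n %% n_folds)] + 1L
  labels <- rep(seq_len(n_folds), times = sizes)
  if (is.null(y)) {
    perm <- with_preserved_rng(seed, sample.int(n))
    folds <- integer(n)
    folds[perm] <- labels
  } else {
    # stratified: spread the sorted targets cyclically over folds,
    # randomizing the fold order within each block of n_folds
    ord <- order(y)
    folds <- integer(n)
    lab <- with_preserved_rng(seed, {
      unlist(lapply(seq_len(ceiling(n / n_folds)), function(b)
        sample.int(n_folds)))[seq_len(n)]
    })
    folds[ord] <- lab
  }
  folds
}

#' Regression performance metrics
#'
#' The three statistics used throughout: `R`, the Pearson correlation of
#' predicted versus actual half-life; `R2`, the coefficient of
#' determination `1 - sum((pred - actual)^2) / SD` where `SD` is the sum
#' of squared deviations of the actual values from the *training* mean
#' (this definition permits negative `R2` whenever predictions do worse
#' than the training-mean baseline); and `MAE`, the mean absolute error in
#' seconds.
#'
#' @param predicted,actual Numeric vectors of equal, non-zero length.
#' @param train_mean Mean half-life of the training peptides (a scalar, or
#'   one value per record when folds had different training means).
#' @return List with elements `R`, `R2`, `MAE`.
#' @examples
#' hl_metrics(c(3, 2, 1), c(1, 2, 3), 2)  # R = -1, R2 = -3, MAE = 4/3
#' @export
hl_metrics <- function(predicted, actual, train_mean) {
  if (length(predicted) != length(actual) || length(actual) == 0L)
    stop("predicted and actual must have equal non-zero length", call. = FALSE)
  if (stats::sd(actual) == 0)
    stop("R undefined: actual values have zero variance", call. = FALSE)
  SD <- sum((actual - train_mean)^2)
  if (SD == 0)
    stop("R2 undefined: zero squared deviation from the training mean",
         call. = FALSE)
  list(R = suppressWarnings(stats::cor(predicted, actual)),
       R2 = 1 - sum((predicted - actual)^2) / SD,
       MAE = mean(abs(predicted - actual)))
}

#' Five-fold cross-validation of a half-life model
#'
#' Records are shuffled with `seed` and split into `n_folds` near-equal
#' folds; each fold is predicted by a model trained on the remaining
#' folds. Metrics are computed on the pooled out-of-fold predictions, with
#' each record's squared deviation taken from its own fold's training mean
#' (the `SD` term of [hl_metrics()]). Deterministic for a fixed seed.
#'
#' Feature selection, when requested through `features`, is applied as
#' given on every fold; `nested_selection = TRUE` instead re-runs
#' [best_first_select()] inside each training fold, avoiding the leak
#' inherent in selecting on the full dataset.
#'
#' @inheritParams hlp_fit
#' @param n_folds Number of folds (default 5).
#' @param stratified Spread sorted half-lives across folds instead of a
#'   uniform shuffle.
#' @param nested_selection Re-select features within each training fold.
#' @param ... Passed to [hlp_fit()] (learner hyperparameters).
#' @return An object of class `"hlp_cv"`: fold assignment, pooled
#'   `predicted` and `actual`, `R`, `R2`, `MAE`, `seed`.
#' @export
cross_validate <- function(data, enc = encoder("dpc"),
                           learner = c("svr", "knn", "dtable"),
                           features = NULL, n_folds = 5L, seed = 1L,
                           stratified = FALSE, nested_selection = FALSE, ...) {
  learner <- match.arg(learner)
  if (!inherits(data, "hl_dataset")) data <- hl_dataset(data$sequence, data$half_life_s)
  n <- nrow(data)
  if (n < 2L * n_folds)
    stop(sprintf("too few records for %d-fold CV", n_folds), call. = FALSE)
  folds <- fold_assignment(n, n_folds, seed,
                           y = if (stratified) data$half_life_s else NULL)
  predicted <- numeric(n)
  train_means <- numeric(n)
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    train <- data[tr, , drop = FALSE]
    class(train) <- class(data)
    feats <- if (nested_selection) {
      Xtr <- encode_peptides(train$sequence, enc)
      best_first_select(Xtr, train$half_life_s)$selected
    } else features
    m <- hlp_fit(train, enc, learner = learner, features = feats,
                 seed = seed, ...)
    predicted[!tr] <- predict(m, data$sequence[!tr])
    train_means[!tr] <- mean(train$half_life_s)
  }
  met <- hl_metrics(predicted, data$half_life_s, train_means)
  structure(list(folds = folds, predicted = predicted,
                 actual = data$half_life_s, train_means = train_means,
                 R = met$R, R2 = met$R2, MAE = met$MAE,
                 n_folds = n_folds, seed = as.integer(seed),
                 learner = learner, encoder = enc),
            class = "hlp_cv")
}

#' @export
print.hlp_cv <- function(x, ...) {
  cat(sprintf("<hlp_cv> %d-fold CV, %s on %s (n = %d, seed %d)\n",
              x$n_folds, x$learner, x$encoder$kind, length(x$actual), x$seed))
  cat(sprintf("  R = %.3f, R2 = %.3f, MAE = %.4g s (pooled out-of-fold)\n",
              x$R, x$R2, x$MAE))
  invisible(x)
}

#' @export
plot.hlp_cv <- function(x, ...) {
  graphics::plot(x$actual, x$predicted,
                 xlab = "actual half-life (s)",
                 ylab = "predicted half-life (s)",
                 main = sprintf("%d-fold CV: R = %.2f", x$n_folds, x$R), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

welch_p <- function(a, b) {
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  }
  tryCatch(stats::t.test(a, b)$p.value, error = function(e) NA_real_)
}

#' Compare the most and least stable peptides
#'
#' Sorts the dataset by half-life and contrasts the top `n_top` peptides
#' (stable group) with the bottom `n_top` (unstable group): per-residue
#' mean amino acid composition in each group with a two-sided Welch t-test
#' p-value per residue, and group means of the physicochemical property
#' panel. Ties in half-life are broken by sequence so group membership is
#' independent of record order. With fewer than `2 * n_top` records the
#' groups shrink to `floor(n / 2)` with a warning.
#'
#' @param data An [hl_dataset()].
#' @param n_top Group size (default 20).
#' @return An object of class `"hlp_groups"`: `composition` (data frame
#'   residue, mean_stable, mean_unstable, p_value), `properties` (data
#'   frame of panel means per group), `stable`/`unstable` (row indices),
#'   `group_size`.
#' @export
compare_extremes <- function(data, n_top = 20L) {
  if (!inherits(data, "hl_dataset")) data <- hl_dataset(data$sequence, data$half_life_s)
  n <- nrow(data)
  g <- min(n_top, n %/% 2L)
  if (g < n_top)
    warning(sprintf("only %d records: group size reduced to %d", n, g))
  ord <- order(data$half_life_s, data$sequence)
  unstable <- sort(ord[seq_len(g)])
  stable <- sort(ord[seq.int(n - g + 1L, n)])
  aac <- encode_peptides(data$sequence, encoder("aac"))
  comp <- data.frame(
    residue = AA_ALPHABET,
    mean_stable = colMeans(aac[stable, , drop = FALSE]),
    mean_unstable = colMeans(aac[unstable, , drop = FALSE]),
    p_value = vapply(AA_ALPHABET, function(r)
      welch_p(aac[stable, r], aac[unstable, r]), numeric(1L)),
    row.names = NULL, stringsAsFactors = FALSE)
  panel <- peptide_properties(data$sequence)
  prop_cols <- setdiff(names(panel), c("sequence", "length"))
  props <- data.frame(
    property = prop_cols,
    mean_stable = vapply(prop_cols, function(p)
      mean(panel[stable, p]), numeric(1L)),
    mean_unstable = vapply(prop_cols, function(p)
      mean(panel[unstable, p]), numeric(1L)),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(composition = comp, properties = props,
                 stable = stable, unstable = unstable, group_size = g),
            class = "hlp_groups")
}

#' @export
print.hlp_groups <- function(x, ...) {
  cat(sprintf("<hlp_groups> top/bottom %d peptides by half-life\n",
              x$group_size))
  sig <- x$composition[!is.na(x$composition$p_value) &
                         x$composition$p_value < 0.05, ]
  if (nrow(sig) > 0L) {
    cat("  residues with p < 0.05:",
        paste(sig$residue, collapse = ", "), "\n")
  } else cat("  no residue differs at p < 0.05\n")
  invisible(x)
}

#' @export
plot.hlp_groups <- function(x, ...) {
  m <- t(as.matrix(x$composition[, c("mean_stable", "mean_unstable")]))
  colnames(m) <- x$composition$residue
  graphics::barplot(m, beside = TRUE, legend.text = c("stable", "unstable"),
                    xlab = "residue", ylab = "mean composition", ...)
  invisible(x)
}
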