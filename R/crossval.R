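# Ten-fold cross-validation with per-fold validity recomputation.
#
# Each fold is predicted from a model fitted on its complement; a test
# compound is predictable only when every one of its groups is present in
# the complement and supported there by at least three molecules.  This
# gate is what thins the predictable set relative to the training fit.

# run code with a private, seeded RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

#' Assign compounds to K cross-validation folds
#'
#' Near-equal random folds from a seeded permutation; deterministic for a
#' given seed.
#'
#' @param ids compound identifiers.
#' @param k number of folds.
#' @param seed RNG seed for the permutation.
#' @return named integer vector of fold labels (1..k) per id.
#' @export
kfold_split <- function(ids, k = 10, seed = 20171221) {
  n <- length(ids)
  if (k < 2) stop("k must be at least 2")
  if (k > n) stop("k = ", k, " exceeds the number of compounds (", n, ")")
  perm <- with_seed(seed, sample.int(n))
  fold <- integer(n)
  fold[perm] <- rep_len(seq_len(k), n)
  stats::setNames(fold, ids)
}

#' K-fold cross-validation of a group-contribution fit
#'
#' For each fold the model is refitted on the complement (with group
#' validity recomputed on that complement) and the held-out compounds are
#' predicted.  Compounds whose groups are missing or invalid in the
#' complement are recorded as not predictable, with the reason, and do not
#' enter the statistics.  `q2` is the squared Pearson correlation between
#' experimental values and out-of-fold predictions over the predictable
#' compounds.
#'
#' @param training a `training_set`.
#' @param k number of folds.
#' @param seed fold-assignment seed.
#' @param uses_constant,uses_special model structure.
#' @param tol,max_iter solver settings.
#' @return object of class `ga_cv`: list with `k`, `seed`, `folds`,
#'   `predictions` (data frame id/fold/observed/predicted/predictable/
#'   reason), `n_predictable`, `q2`, `avg_dev`, `sd_dev`.
#' @export
cross_validate <- function(training, k = 10, seed = 20171221,
                           uses_constant = TRUE, uses_special = FALSE,
                           tol = 1e-12, max_iter = 1e5) {
  n <- length(training)
  folds <- kfold_split(training$ids, k = k, seed = seed)
  pred <- data.frame(id = training$ids, fold = unname(folds),
                     observed = training$values,
                     predicted = NA_real_, predictable = FALSE,
                     reason = "")
  for (f in sort(unique(folds))) {
    test_idx <- which(folds == f)
    train_idx <- which(folds != f)
    complement <- subset_training(training, train_idx)
    fit <- tryCatch(
      fit_groups(complement, uses_constant = uses_constant,
                 uses_special = uses_special, tol = tol, max_iter = max_iter),
      error = function(e) stop("fold ", f, " cannot be fitted: ",
                               conditionMessage(e)))
    for (t in test_idx) {
      p <- predict_property(training$counts[[t]], fit$table)
      if (p$eligible) {
        pred$predicted[t] <- p$value
        pred$predictable[t] <- TRUE
      } else {
        pred$reason[t] <- paste0(
          if (length(p$missing)) paste0("missing: ", paste(p$missing, collapse = ", ")),
          if (length(p$missing) && length(p$invalid)) "; ",
          if (length(p$invalid)) paste0("invalid: ", paste(p$invalid, collapse = ", ")))
      }
    }
  }
  ok <- pred$predictable
  st <- if (sum(ok) >= 2) fit_statistics(pred$observed[ok], pred$predicted[ok])
        else list(r2 = NA_real_, avg_dev = NA_real_, sd_dev = NA_real_, n = sum(ok))
  structure(list(k = k, seed = seed, folds = folds, predictions = pred,
                 n_predictable = sum(ok), q2 = st$r2,
                 avg_dev = st$avg_dev, sd_dev = st$sd_dev),
            class = "ga_cv")
}

#' @export
print.ga_cv <- function(x, ...) {
  cat(sprintf("<cv> K = %d: %d/%d predictable, Q2 = %.4f, avg dev = %.3f, std dev = %.3f\n",
              x$k, x$n_predictable, nrow(x$predictions), x$q2,
              x$avg_dev, x$sd_dev))
  invisible(x)
}
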