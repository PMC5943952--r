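# Re-derivation of group contributions from training data: sparse design
# matrix, Gauss-Seidel least squares on the normal equations, residual
# statistics, and the outlier-exclusion loop driven by the cross-validated
# standard error.

#' Assemble a training set
#'
#' @param counts_list list of `group_counts` objects (one per compound,
#'   with unique ids).
#' @param values numeric experimental descriptor values, one per compound,
#'   in the same order.
#' @return object of class `training_set`.
#' @export
training_set <- function(counts_list, values) {
  stopifnot(length(counts_list) == length(values))
  ids <- vapply(counts_list, function(gc) gc$id, "")
  if (anyDuplicated(ids)) stop("duplicate compound id(s): ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (!all(is.finite(values))) stop("experimental values must be finite")
  structure(list(counts = counts_list, values = as.numeric(values), ids = ids),
            class = "training_set")
}

#' @export
length.training_set <- function(x) length(x$counts)

subset_training <- function(training, idx) {
  training_set(training$counts[idx], training$values[idx])
}

CONST_KEY <- "(Const)"

#' Build the design matrix of a training set
#'
#' One row per compound, one column per fitted parameter: every signature
#' occurring in the training set (groups supported by fewer than three
#' molecules are retained -- they are fitted, merely flagged invalid for
#' prediction), the special-group columns when `uses_special`, and an
#' all-ones column when `uses_constant`.
#'
#' @param training a `training_set`.
#' @param uses_constant fit an additive constant C.
#' @param uses_special include special-group columns with nonzero counts.
#' @return list with sparse matrix `X` (dgCMatrix, dimnames = ids x keys),
#'   response `y`, and `keys`.
#' @export
build_design <- function(training, uses_constant = TRUE, uses_special = FALSE) {
  n <- length(training)
  if (n == 0) stop("empty training set")
  triplets <- lapply(seq_len(n), function(r) {
    gc <- training$counts[[r]]
    v <- gc$counts
    if (uses_special) v <- c(v, gc$special[gc$special > 0])
    if (!length(v)) return(NULL)
    data.frame(r = r, key = names(v), x = unname(v))
  })
  tr <- do.call(rbind, triplets)
  keys <- sort(unique(tr$key))
  if (uses_constant) {
    tr <- rbind(tr, data.frame(r = seq_len(n), key = CONST_KEY, x = 1))
    keys <- c(keys, CONST_KEY)
  }
  X <- Matrix::sparseMatrix(i = tr$r, j = match(tr$key, keys), x = tr$x,
                            dims = c(n, length(keys)),
                            dimnames = list(training$ids, keys))
  list(X = X, y = training$values, keys = keys)
}

#' Solve a least-squares problem by Gauss-Seidel iteration
#'
#' Iterates the Gauss-Seidel update on the normal equations
#' \eqn{X^T X a = X^T y} from a zero start until the largest relative
#' coordinate change drops below `tol`.  On well-conditioned problems the
#' result agrees with a direct dense solve to high accuracy.
#'
#' @param X design matrix (dense or sparse).
#' @param y response vector.
#' @param tol relative coordinate-change tolerance.  The default 1e-12 is
#'   tight enough that the final iterate tracks the direct least-squares
#'   solution to well below 1e-8 on well-conditioned problems.
#' @param max_iter maximum number of sweeps.
#' @return list with `coef` (named when X has column names), `iterations`
#'   and `converged`.  Non-convergence is an error carrying the last
#'   iterate and residual norm in its `data` field.
#' @export
gauss_seidel_solve <- function(X, y, tol = 1e-12, max_iter = 1e5) {
  A <- as.matrix(Matrix::crossprod(X))
  b <- as.numeric(Matrix::crossprod(X, y))
  p <- ncol(A)
  if (any(diag(A) == 0))
    stop("zero diagonal in normal equations: column(s) ",
         paste(colnames(A)[diag(A) == 0], collapse = ", "),
         " never occur in the data")
  # one sweep solves L x_new = b - U x_old with L the lower triangle
  U <- A; U[lower.tri(U, diag = TRUE)] <- 0
  x <- numeric(p)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    x_new <- forwardsolve(A, b - U %*% x, upper.tri = FALSE)
    delta <- max(abs(x_new - x) / pmax(1, abs(x_new)))
    x <- as.numeric(x_new)
    if (delta < tol) break
    if (iter >= max_iter) {
      e <- simpleError(sprintf(
        "Gauss-Seidel did not converge in %d sweeps (last delta %.3g)",
        iter, delta))
      e$data <- list(coef = stats::setNames(x, colnames(A)),
                     residual_norm = sqrt(sum((b - A %*% x)^2)))
      stop(e)
    }
  }
  list(coef = stats::setNames(x, colnames(A)), iterations = iter, converged = TRUE)
}

#' Residual statistics of a fit
#'
#' `r2` is the squared Pearson correlation of experimental versus fitted
#' values; the average deviation is the mean absolute residual and the
#' standard deviation the root-mean-square residual.  When the predictions
#' are constant the correlation is undefined and `r2` is reported as 0.
#'
#' @param y experimental values.
#' @param predictions fitted/predicted values.
#' @return list with `r2`, `avg_dev`, `sd_dev`, `n`.
#' @export
fit_statistics <- function(y, predictions) {
  stopifnot(length(y) == length(predictions), length(y) >= 2)
  if (stats::sd(y) == 0) stop("zero variance in experimental values; R2 undefined")
  r2 <- if (stats::sd(predictions) == 0) 0
        else stats::cor(y, predictions)^2
  res <- y - predictions
  list(r2 = r2, avg_dev = mean(abs(res)), sd_dev = sqrt(mean(res^2)),
       n = length(y))
}

#' Fit group contributions to a training set
#'
#' Builds the design, solves the least-squares problem by Gauss-Seidel,
#' and assembles the result as a `parameter_table` with occurrence and
#' molecule counts from the data and validity flags from the >= 3-molecule
#' rule.
#'
#' @param training a `training_set`.
#' @param descriptor descriptor id recorded in the fitted table.
#' @param uses_constant,uses_special model structure (see [build_design()]).
#' @param tol,max_iter passed to [gauss_seidel_solve()].
#' @return object of class `ga_fit`: list with `table`, `n_used`, `r2`,
#'   `avg_dev`, `sd_dev`, `residuals` (data frame id/observed/fitted/
#'   residual) and `solver` info.
#' @export
fit_groups <- function(training, descriptor = "custom",
                       uses_constant = TRUE, uses_special = FALSE,
                       tol = 1e-12, max_iter = 1e5) {
  d <- build_design(training, uses_constant, uses_special)
  sol <- gauss_seidel_solve(d$X, d$y, tol = tol, max_iter = max_iter)
  fitted <- as.numeric(d$X %*% sol$coef)
  st <- fit_statistics(d$y, fitted)

  keys <- setdiff(d$keys, CONST_KEY)
  nmol <- molecule_support(training$counts)
  nocc <- occurrence_counts(training$counts)
  parts <- strsplit(keys, "|", fixed = TRUE)
  is_special <- keys %in% SPECIAL_KEYS
  entries <- data.frame(
    entry = seq_along(keys),
    atom_type = ifelse(is_special,
                       c(alkane_C = "Alkane", unsatHC_C = "Unsaturated HC",
                         h_acceptor = "H")[keys],
                       vapply(parts, `[`, "", 1)),
    neighbors = ifelse(is_special,
                       c(alkane_C = "No of C atoms",
                         unsatHC_C = "No of C atoms",
                         h_acceptor = "H Acceptor")[keys],
                       vapply(parts, function(p) if (length(p) > 1) p[2] else "", "")),
    contribution = unname(sol$coef[keys]),
    occurrences = as.integer(nocc[keys]),
    molecules = as.integer(ifelse(keys %in% names(nmol), nmol[keys], 0L)))
  constant <- if (uses_constant) unname(sol$coef[CONST_KEY]) else 0
  if (uses_constant)
    entries <- rbind(data.frame(entry = 0L, atom_type = "Const", neighbors = "",
                                contribution = constant,
                                occurrences = length(training),
                                molecules = length(training)),
                     entries)
  entries$entry <- seq_len(nrow(entries))
  table <- new_parameter_table(descriptor, entries, constant = constant,
                               uses_constant = uses_constant,
                               uses_special = uses_special)
  structure(list(table = table, n_used = length(training),
                 r2 = st$r2, avg_dev = st$avg_dev, sd_dev = st$sd_dev,
                 residuals = data.frame(id = training$ids, observed = d$y,
                                        fitted = fitted,
                                        residual = d$y - fitted),
                 solver = sol[c("iterations", "converged")]),
            class = "ga_fit")
}

#' @export
print.ga_fit <- function(x, ...) {
  cat(sprintf("<fit> N = %d, R2 = %.4f, avg dev = %.3f, std dev = %.3f\n",
              x$n_used, x$r2, x$avg_dev, x$sd_dev))
  invisible(x)
}

#' Fit with iterative outlier exclusion
#'
#' Alternates fitting and ten-fold cross-validation: after each fit the
#' cross-validated standard error sigma_cv is measured and every compound
#' whose experimental value deviates from its fitted value by more than
#' `threshold` times sigma_cv is excluded; the loop repeats until no new
#' exclusion occurs or `max_rounds` is reached.
#'
#' @param training a `training_set`.
#' @param descriptor descriptor id for the fitted table.
#' @param uses_constant,uses_special model structure.
#' @param k,seed cross-validation settings (see [cross_validate()]).
#' @param threshold exclusion multiple of the cross-validated standard
#'   error (3 by default).
#' @param min_deviation absolute floor below which a deviation is never an
#'   outlier; prevents the rule from flagging floating-point noise when a
#'   model fits (near-)exactly.
#' @param max_rounds iteration cap; reaching it flags the result as not
#'   converged.
#' @return a `ga_fit` with extra fields `outliers` (data frame id/observed/
#'   fitted/deviation/round), `sigma_cv`, `rounds` and `outlier_converged`.
#' @export
fit_with_outlier_removal <- function(training, descriptor = "custom",
                                     uses_constant = TRUE, uses_special = FALSE,
                                     k = 10, seed = 20171221,
                                     threshold = 3, min_deviation = 1e-8,
                                     max_rounds = 10) {
  current <- training
  outliers <- data.frame(id = character(), observed = numeric(),
                         fitted = numeric(), deviation = numeric(),
                         round = integer())
  converged <- FALSE
  fit <- NULL
  sigma_cv <- NA_real_
  for (round in seq_len(max_rounds)) {
    if (length(current) == 0) stop("outlier exclusion emptied the training set")
    fit <- fit_groups(current, descriptor, uses_constant, uses_special)
    cv <- cross_validate(current, k = k, seed = seed,
                         uses_constant = uses_constant,
                         uses_special = uses_special)
    sigma_cv <- cv$sd_dev
    dev <- abs(fit$residuals$residual)
    out <- which(dev > threshold * sigma_cv & dev > min_deviation)
    if (!length(out)) { converged <- TRUE; break }
    outliers <- rbind(outliers, data.frame(
      id = fit$residuals$id[out], observed = fit$residuals$observed[out],
      fitted = fit$residuals$fitted[out], deviation = dev[out],
      round = round))
    current <- subset_training(current, -out)
  }
  fit$outliers <- outliers
  fit$sigma_cv <- sigma_cv
  fit$rounds <- round
  fit$outlier_converged <- converged
  fit
}
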