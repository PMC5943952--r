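# Design matrices, Gauss-Seidel least squares, statistics, outlier loop.

test_that("design matrices have one column per parameter plus the constant", {
  tr <- training_set(list(gc_make("a", c(G1 = 1)), gc_make("b", c(G1 = 1, G2 = 1)),
                          gc_make("c", c(G2 = 2))), c(1, 2, 1))
  d0 <- build_design(tr, uses_constant = FALSE)
  expect_equal(dim(d0$X), c(3, 2))
  expect_equal(unname(as.matrix(d0$X)[3, "G2"]), 2)
  d1 <- build_design(tr, uses_constant = TRUE)
  expect_equal(dim(d1$X), c(3, 3))
  expect_true(all(as.matrix(d1$X)[, "(Const)"] == 1))

  # an ethanol row against a viscosity-style design
  eth <- perceive(read_smiles("CCO", id = "ethanol"))
  dd <- build_design(training_set(list(eth), 0.33), uses_constant = TRUE)
  expect_equal(sort(dd$keys),
               sort(c("C sp3|H3C", "C sp3|H2CO", "O|HC", "(Const)")))
  expect_true(all(as.matrix(dd$X)[1, ] == 1))

  expect_error(build_design(training_set(list(), numeric(0))), "empty")
  expect_error(training_set(list(gc_make("a", c(G1 = 1)),
                                 gc_make("a", c(G1 = 1))), c(1, 2)),
               "duplicate compound id")
})

test_that("Gauss-Seidel solves least-squares problems to solver accuracy", {
  expect_equal(gauss_seidel_solve(diag(3), c(1, 2, 3))$coef,
               c(1, 2, 3), ignore_attr = TRUE)
  # hand-solved 2x2 normal equations: X = [[1,0],[1,1],[0,1]], y = (1,2,1)
  X <- matrix(c(1, 1, 0, 0, 1, 1), 3, 2)
  expect_equal(gauss_seidel_solve(X, c(1, 2, 1))$coef, c(1, 1),
               ignore_attr = TRUE, tolerance = 1e-9)
  # noise-free synthetic: exact recovery
  set.seed(99)
  Xs <- matrix(rpois(60 * 8, 1), 60, 8)
  a <- runif(8, -1, 1)
  sol <- gauss_seidel_solve(Xs, as.numeric(Xs %*% a))
  expect_equal(unname(sol$coef), a, tolerance = 1e-8)
  expect_true(sol$converged)
})

test_that("Gauss-Seidel matches the direct solver on random systems", {
  set.seed(7)
  for (rep in 1:25) {
    n <- sample(20:120, 1); p <- sample(2:30, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    expect_equal(unname(gauss_seidel_solve(X, y)$coef),
                 unname(qr.solve(X, y)), tolerance = 1e-8)
  }
})

test_that("solver failure modes are explicit", {
  X <- matrix(c(1, 1, 0, 0), 2, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(gauss_seidel_solve(X, c(1, 2)), "zero diagonal.*b")
  # an unconverged run carries its last iterate
  Xc <- matrix(rnorm(200), 20, 10)
  err <- tryCatch(gauss_seidel_solve(Xc, rnorm(20), max_iter = 2),
                  error = function(e) e)
  expect_match(conditionMessage(err), "did not converge")
  expect_length(err$data$coef, 10)
  expect_true(is.finite(err$data$residual_norm))
})

test_that("fit statistics implement R2, mean-absolute and RMS deviations", {
  y <- c(1.0, 2.5, 0.3, 4.2)
  p <- c(1.2, 2.2, 0.1, 4.4)
  st <- fit_statistics(y, p)
  res <- y - p
  expect_equal(st$r2, (sum((y - mean(y)) * (p - mean(p))) /
                         sqrt(sum((y - mean(y))^2) * sum((p - mean(p))^2)))^2)
  expect_equal(st$avg_dev, mean(abs(res)))
  expect_equal(st$sd_dev, sqrt(mean(res^2)))

  perfect <- fit_statistics(y, y)
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$avg_dev, 0)
  expect_equal(perfect$sd_dev, 0)

  expect_equal(fit_statistics(y, rep(mean(y), 4))$r2, 0)
  expect_error(fit_statistics(rep(1, 4), p), "zero variance")
})

test_that("fitting a synthetic design recovers the true contributions", {
  d <- make_design(synth_spec(n_compounds = 300, n_groups = 25,
                              sigma = 0.1, seed = 21))
  fit <- fit_groups(synthetic_training(d), uses_constant = FALSE)
  ahat <- fit$table$entries$contribution[match(colnames(d$X), fit$table$entries$key)]
  expect_lt(sqrt(mean((ahat - d$a_true)^2)), 0.04)
  expect_gt(fit$r2, 0.99)
  # groups are flagged by molecule support even while all are fitted
  expect_equal(fit$table$entries$valid, fit$table$entries$molecules >= 3)
  # noise-free refit is exact
  d0 <- make_design(synth_spec(n_compounds = 100, n_groups = 10,
                               sigma = 0, seed = 5))
  expect_equal(fit_groups(synthetic_training(d0), uses_constant = FALSE)$r2, 1)
})

test_that("a fitted constant is recovered when the model uses one", {
  d <- make_design(synth_spec(n_compounds = 400, n_groups = 10, sigma = 0.05,
                              constant = -0.7, seed = 13))
  fit <- fit_groups(synthetic_training(d), uses_constant = TRUE)
  expect_equal(fit$table$constant, -0.7, tolerance = 0.05)
  expect_equal(fit$table$entries$atom_type[1], "Const")
})

test_that("the outlier loop excludes exactly the shifted compound", {
  d <- make_design(synth_spec(n_compounds = 120, n_groups = 15,
                              sigma = 0.1, seed = 31))
  y <- d$y
  y[40] <- y[40] + 10 * d$spec$sigma
  tr <- training_set(synthetic_training(d)$counts, y)
  fit <- fit_with_outlier_removal(tr, uses_constant = FALSE, k = 10, seed = 3)
  expect_equal(fit$outliers$id, "S0040")
  expect_true(fit$outlier_converged)
  expect_equal(fit$n_used, 119)

  # a clean set passes in a single round with no exclusions
  clean <- fit_with_outlier_removal(synthetic_training(d),
                                    uses_constant = FALSE, k = 10, seed = 3)
  expect_equal(nrow(clean$outliers), 0)
  expect_equal(clean$rounds, 1)

  # a tiny cap leaves the loop unconverged
  capped <- fit_with_outlier_removal(tr, uses_constant = FALSE, k = 10,
                                     seed = 3, max_rounds = 1)
  expect_false(capped$outlier_converged)
})
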