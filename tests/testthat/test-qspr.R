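# constructed regression fixture: independent columns, known sparse signal
make_fixture <- function(n = 60, p = 50,
                         support = c(1, ceiling(p / 3), p - 2),
                         w = c(2, -3, 0.5), noise = 0, seed = 101) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("d%02d", 1:p)))
  y <- drop(X[, support, drop = FALSE] %*% w) + 1.5 +
    if (noise > 0) rnorm(n, 0, noise) else 0
  list(X = X, y = y, support = colnames(X)[support], w = w)
}

test_that("SCR recovers an exact sparse linear signal", {
  fx <- make_fixture()
  pm <- fit_scr(fx$X, fx$y)
  expect_true(all(fx$support %in% pm$selected))
  expect_equal(pm$stats$R2, 1, tolerance = 1e-12)
  expect_lt(pm$stats$SD, 1e-10)
  # coefficients on the true support match the generative weights
  expect_equal(unname(pm$coef[fx$support]), fx$w, tolerance = 1e-6)
  expect_equal(pm$intercept, 1.5, tolerance = 1e-6)
})

test_that("SCR rejects degenerate inputs and bounds model size", {
  fx <- make_fixture()
  expect_error(fit_scr(fx$X, rep(2, nrow(fx$X))), "zero variance")
  expect_error(fit_scr(matrix(1, 10, 2, dimnames = list(NULL, c("a", "b"))),
                       rnorm(10)), "non-constant")

  # wide noisy problem stays within max_vars
  set.seed(33)
  Xw <- matrix(rpois(103 * 200, 1), 103, 200,
               dimnames = list(NULL, paste0("c", 1:200)))
  yw <- drop(Xw[, 1:5] %*% runif(5, 0.5, 1.5)) + rnorm(103, 0, 0.4)
  pm <- fit_scr(Xw, yw)
  expect_lte(pm$stats$n_vars, 30L)
  expect_gte(pm$stats$R2, 0)
})

test_that("RBF refinement interpolates residual structure", {
  fx <- make_fixture(n = 20, p = 10, support = c(1, 2), w = c(1, 1))
  # add a nonlinearity the linear part cannot capture
  y <- fx$y + 0.5 * sin(fx$X[, 1] * 2)
  base <- fit_scr(fx$X, y)
  rbf <- fit_rbf_scr(fx$X, y, base)
  rss_base <- sum((y - predict(base, fx$X))^2)
  rss_rbf <- sum((y - predict(rbf, fx$X))^2)
  expect_lte(rss_rbf, rss_base + 1e-12)

  # zero residuals produce a ~zero RBF correction
  pm0 <- fit_scr(fx$X, fx$y)
  rbf0 <- fit_rbf_scr(fx$X, fx$y, pm0)
  expect_lt(max(abs(rbf0$rbf$alpha)), 1e-6)

  # auto width is the median pairwise distance in the selected subspace
  Xs <- fx$X[, rbf$selected, drop = FALSE]
  d <- dist(Xs)
  expect_equal(rbf$rbf$width, median(d[d > 0]))
})

test_that("consensus prediction is the mean over accepted partials", {
  fx <- make_fixture(n = 50, p = 20, noise = 0.3)
  m <- fit_consensus(list(X = fx$X, y = fx$y), n_partials = 8,
                     seed = 5, compute_q2 = FALSE)
  pr <- predict(m, fx$X)
  # explicit-loop cross-check of the averaging contract
  for (r in c(1, 17, 42)) {
    preds <- vapply(m$partials, function(p)
      predict(p, fx$X[r, , drop = FALSE]), 0)
    acc <- vapply(m$partials, function(p) {
      xs <- fx$X[r, p$selected, drop = FALSE]
      drop(xs %*% p$ad$XtX_inv %*% t(xs)) <= p$ad$h_threshold
    }, TRUE)
    use <- if (any(acc)) which(acc) else seq_along(preds)
    expect_equal(pr$logk7_pred[r], mean(preds[use]))
  }
  # prediction invariant under row reordering
  idx <- rev(seq_len(nrow(fx$X)))
  pr2 <- predict(m, fx$X[idx, ])
  expect_equal(pr2$logk7_pred, pr$logk7_pred[idx])
})

test_that("without resampling all partials coincide with the single model", {
  fx <- make_fixture(n = 40, p = 15, noise = 0.2)
  m <- fit_consensus(list(X = fx$X, y = fx$y), n_partials = 3,
                     leave_fraction = 0, seed = 9, compute_q2 = FALSE)
  single <- fit_scr(fx$X, fx$y)
  pr <- predict(m, fx$X)
  expect_equal(pr$logk7_pred, predict(single, fx$X), tolerance = 1e-10)
  expect_equal(pr$sd_partials, rep(0, nrow(fx$X)), tolerance = 1e-10)
})

test_that("identical seeds give byte-identical serialized models", {
  fx <- make_fixture(n = 40, p = 15, noise = 0.2)
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  m1 <- fit_consensus(list(X = fx$X, y = fx$y), n_partials = 4, seed = 77,
                      compute_q2 = FALSE)
  m2 <- fit_consensus(list(X = fx$X, y = fx$y), n_partials = 4, seed = 77,
                      compute_q2 = FALSE)
  write_consensus_json(m1, f1)
  write_consensus_json(m2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # round trip restores a working model
  m3 <- read_consensus_json(f1)
  expect_equal(predict(m3, fx$X)$logk7_pred, predict(m1, fx$X)$logk7_pred)
})

test_that("LMO cross-validation separates signal from noise", {
  fx <- make_fixture(n = 60, p = 20)
  expect_gt(cross_validate_lmo(fx$X, fx$y, seed = 3), 0.99)
  set.seed(14)
  ynoise <- rnorm(60)
  expect_lt(cross_validate_lmo(fx$X, ynoise, seed = 3), 0.1)
})

test_that("applicability domain accepts training-like and rejects alien compounds", {
  ds <- generate_qspr_dataset(n_compounds = 60, noise_sd = 0.2, seed = 21)
  m <- fit_consensus(ds$records, preset = "mna", n_partials = 10,
                     seed = 4, compute_q2 = FALSE)
  pr_train <- predict(m, ds$records[1:10, ])
  expect_true(all(pr_train$in_ad))
  alien <- suppressWarnings(parse_structures("ClC(Cl)(Cl)Cl tetrachloromethane",
                                             "smiles"))
  pr_alien <- predict(m, alien)
  expect_false(pr_alien$in_ad)
  expect_gt(pr_alien$unseen_fraction, 0.2)
})

test_that("the combined preset cycles partials through descriptor-family variants", {
  ds <- generate_qspr_dataset(n_compounds = 40, noise_sd = 0.2, seed = 12)
  m <- fit_consensus(ds$records, preset = "both", n_partials = 8,
                     seed = 3, compute_q2 = FALSE)
  expect_equal(nrow(m$variants), 16L)
  expect_equal(vapply(m$partials, `[[`, 0L, "variant"), 1:8)
  expect_setequal(unique(m$variants$family), c("mna", "ana"))
  pr <- predict(m, ds$records[1:5, ])
  expect_true(all(is.finite(pr$logk7_pred)))
})

test_that("prediction error on in-distribution structures tracks the noise level", {
  sigma <- 0.3
  ds <- generate_qspr_dataset(n_compounds = 110, noise_sd = sigma, seed = 30)
  sp <- rational_split(ds$records, 6, 2)
  m <- fit_consensus(sp$train, preset = "mna", n_partials = 10,
                     seed = 15, compute_q2 = FALSE)
  pr <- predict(m, sp$test)
  rmse <- sqrt(mean((sp$test$logk7 - pr$logk7_pred)^2))
  expect_lt(rmse, 2 * sigma)
})
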