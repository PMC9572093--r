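#' Self-consistent regression (SCR)
#'
#' Iterative least-squares variable selection: starting from all usable
#' columns, a ridge-regularized fit is computed and every column whose
#' coefficient fails the t-significance threshold is dropped; when all
#' survivors are significant but still more numerous than `max_vars`, the
#' single least significant column is dropped; the procedure repeats until a
#' compact, fully significant equation remains, which is then refit by
#' ordinary least squares (the ridge acts only as a selection stabilizer, so
#' noise-free data are recovered exactly). Zero-variance columns are
#' pre-dropped; with very wide matrices (`p > 3n`) an initial univariate
#' correlation screen keeps the `3n` most correlated columns.
#'
#' @param X numeric matrix (rows = compounds) with column names.
#' @param y numeric response, `length(y) == nrow(X)`, non-constant.
#' @param lambda ridge penalty; default `1e-3 * trace(X'X) / p` on the
#'   centered matrix.
#' @param t_threshold minimum |t| for a column to survive (default 2).
#' @param max_vars maximum variables in the final equation (default 30).
#' @return Object of class `partial_model`: `selected` (column names),
#'   `coef` (named, final OLS), `intercept`, and `stats`
#'   (`R2`, `F_stat`, `SD`, `n_vars`).
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(300), 30, dimnames = list(NULL, paste0("d", 1:10)))
#' fit_scr(X, 2 * X[, 1] - X[, 4] + 5)
#' @export
fit_scr <- function(X, y, lambda = NULL, t_threshold = 2, max_vars = 30) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  if (stats::var(y) == 0) stop("response has zero variance")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  n <- nrow(X)

  keep <- apply(X, 2L, stats::var) > 0
  cols <- colnames(X)[keep]
  if (!length(cols)) stop("no non-constant columns in X")
  if (length(cols) > 3L * n) {
    sc <- abs(suppressWarnings(stats::cor(X[, cols], y)))
    sc[is.na(sc)] <- 0
    cols <- cols[order(-sc)][seq_len(3L * n)]
  }

  repeat {
    Xc <- scale(X[, cols, drop = FALSE], scale = FALSE)
    yc <- y - mean(y)
    p <- length(cols)
    XtX <- crossprod(Xc)
    lam <- if (is.null(lambda)) 1e-3 * sum(diag(XtX)) / p else lambda
    A <- XtX + diag(lam, p)
    Ainv <- solve(A)
    b <- drop(Ainv %*% crossprod(Xc, yc))
    rss <- sum((yc - Xc %*% b)^2)
    # effective model degrees of freedom of the ridge fit, so the residual
    # variance stays meaningful when p approaches or exceeds n
    df_eff <- sum(diag(Ainv %*% XtX))
    sigma2 <- rss / max(n - df_eff - 1, 1)
    se <- sqrt(pmax(diag(Ainv %*% XtX %*% Ainv), .Machine$double.eps) * sigma2)
    tval <- abs(b) / se

    insig <- which(tval < t_threshold)
    if (length(insig) == p) {       # nothing significant: keep the best, stop
      cols <- cols[which.max(tval)]
      break
    } else if (length(insig) > 0L) {
      # drop gradually (worst quarter of the current columns at most) so that
      # masked-but-relevant columns can regain significance as rivals leave
      k_drop <- min(length(insig), max(1L, ceiling(p / 4)))
      cols <- cols[-insig[order(tval[insig])][seq_len(k_drop)]]
    } else if (p > max_vars) {
      cols <- cols[-which.min(tval)]
    } else break
    if (length(cols) <= 1L) break
  }

  # final unpenalized refit; rank-deficient columns are discarded
  Xs <- X[, cols, drop = FALSE]
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, Xs), y)
  cf <- fit$coefficients
  bad <- names(cf)[is.na(cf)]
  if (length(bad)) {
    cols <- setdiff(cols, bad)
    Xs <- X[, cols, drop = FALSE]
    fit <- stats::lm.fit(cbind(`(Intercept)` = 1, Xs), y)
    cf <- fit$coefficients
  }
  rss <- sum(fit$residuals^2)
  sst <- sum((y - mean(y))^2)
  p <- length(cols)
  dfres <- max(n - p - 1L, 1L)
  structure(list(
    selected = cols,
    coef = cf[-1L],
    intercept = unname(cf[1L]),
    stats = list(R2 = 1 - rss / sst,
                 F_stat = if (p > 0) ((sst - rss) / p) / (rss / dfres) else NA_real_,
                 SD = sqrt(rss / dfres),
                 n_vars = p),
    t_threshold = t_threshold, max_vars = max_vars
  ), class = "partial_model")
}

#' @export
print.partial_model <- function(x, ...) {
  s <- x$stats
  cat(sprintf("partial_model: %d variables, R2 = %.4f, F = %.3g, SD = %.4g%s\n",
              s$n_vars, s$R2, s$F_stat, s$SD,
              if (!is.null(x$rbf)) " (+RBF refinement)" else ""))
  invisible(x)
}

#' Predict from a partial model
#'
#' @param object a `partial_model` (optionally RBF-refined).
#' @param X numeric matrix containing at least the model's selected columns.
#' @param ... unused.
#' @export
predict.partial_model <- function(object, X, ...) {
  Xs <- X[, object$selected, drop = FALSE]
  out <- drop(Xs %*% object$coef) + object$intercept
  if (!is.null(object$rbf)) {
    r <- object$rbf
    K <- exp(-as.matrix(pdist2(Xs, r$centers)) / (2 * r$width^2))
    out <- out + drop(K %*% r$alpha)
  }
  unname(out)
}

# squared Euclidean cross-distances
pdist2 <- function(A, B) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  pmax(d, 0)
}

#' Radial-basis refinement of an SCR model
#'
#' Fits a Gaussian radial-basis interpolator over the base model's
#' selected-column subspace to the base model's training residuals; the
#' refined prediction is linear part + RBF part. The kernel width defaults
#' to the median pairwise Euclidean distance of the training rows ("auto");
#' the kernel system is ridge-stabilized, so duplicate rows with conflicting
#' responses are tolerated (with a warning).
#'
#' @param X,y the training matrix and response used to fit `base`.
#' @param base a [fit_scr()] model.
#' @param kernel_width `"auto"` or a positive number.
#' @param ridge stabilizing diagonal (default 1e-8 of the mean kernel trace).
#' @return The base model with an `rbf` component; class `partial_model`.
#' @export
fit_rbf_scr <- function(X, y, base, kernel_width = "auto", ridge = NULL) {
  stopifnot(inherits(base, "partial_model"))
  Xs <- X[, base$selected, drop = FALSE]
  res <- y - predict(base, X)
  D2 <- pdist2(Xs, Xs)
  if (identical(kernel_width, "auto")) {
    d <- sqrt(D2[upper.tri(D2)])
    kernel_width <- stats::median(d[d > 0])
    if (!is.finite(kernel_width) || kernel_width <= 0) kernel_width <- 1
  }
  stopifnot(kernel_width > 0)
  if (any(D2[upper.tri(D2)] == 0) && stats::var(res) > 0)
    warning("duplicate rows in the selected-column subspace; ridge-stabilized solve")
  K <- exp(-D2 / (2 * kernel_width^2))
  lam <- if (is.null(ridge)) 1e-8 * mean(diag(K)) else ridge
  alpha <- solve(K + diag(lam, nrow(K)), res)
  out <- base
  out$rbf <- list(centers = Xs, alpha = alpha, width = kernel_width)
  rbf_pred <- predict(out, X)
  rss <- sum((y - rbf_pred)^2)
  sst <- sum((y - mean(y))^2)
  out$stats$R2 <- 1 - rss / sst
  out$stats$SD <- sqrt(rss / max(nrow(X) - out$stats$n_vars - 1L, 1L))
  out
}

# descriptor-variant grid backing consensus diversity
variant_grid <- function(preset, max_level) {
  switch(preset,
    mna = data.frame(family = "mna", level = max_level, include_h = TRUE),
    qna_like = data.frame(family = "ana", level = max_level, include_h = TRUE),
    both = expand.grid(family = c("mna", "ana"), level = 0:3,
                       include_h = c(TRUE, FALSE), stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE))
}

#' Fit a consensus QSPR model
#'
#' Builds an ensemble of [fit_scr()] partial models (optionally RBF-refined),
#' each trained on a resampled variant of the training data that leaves out a
#' uniformly random 20% of the rows; for the `"both"` preset the partials
#' additionally cycle through 16 descriptor-family/level variants (MNA and
#' the numeric aggregate family at levels 0-3, with and without hydrogens),
#' so the 320-partial preset is 16 variants x 20 resamples. The consensus
#' prediction is the arithmetic mean over the in-applicability-domain
#' partials.
#'
#' @param data either an [activity_table()] with a `structure` list column of
#'   [molecular_graph()] objects, or a list `list(X = matrix, y = numeric)`
#'   with a prebuilt descriptor matrix.
#' @param preset `"mna"`, `"qna_like"`, or `"both"` (descriptor families);
#'   ignored for matrix input.
#' @param n_partials ensemble size (default 20; 320 for `"both"`).
#' @param max_level MNA neighborhood level (default 2).
#' @param use_rbf refine each partial with [fit_rbf_scr()]?
#' @param leave_fraction fraction of rows left out per partial (default 0.2).
#' @param seed random seed governing all resampling (default 20191).
#' @param compute_q2 also run [cross_validate_lmo()] on the primary
#'   descriptor matrix and store `Q2_LMO`?
#' @param ... further arguments to [fit_scr()] (`lambda`, `t_threshold`,
#'   `max_vars`).
#' @return Object of class `consensus_model`.
#' @export
fit_consensus <- function(data, preset = c("mna", "qna_like", "both"),
                          n_partials = NULL, max_level = 2L, use_rbf = FALSE,
                          leave_fraction = 0.2, seed = 20191,
                          compute_q2 = TRUE, ...) {
  preset <- match.arg(preset)
  matrix_input <- is.list(data) && !is.data.frame(data) && !is.null(data$X)

  if (matrix_input) {
    y <- data$y
    variants <- data.frame(family = "matrix", level = NA, include_h = NA)
    mats <- list(data$X)
    vocabs <- list(colnames(data$X))
    ids <- rownames(data$X)
  } else {
    stopifnot(is.data.frame(data), !is.null(data$structure), !is.null(data$logk7))
    if (nrow(data) < 30L)
      warning("fewer than 30 training records; consensus models need more data to be meaningful")
    y <- data$logk7
    ids <- data$id
    variants <- variant_grid(preset, max_level)
    mats <- vector("list", nrow(variants))
    vocabs <- vector("list", nrow(variants))
    for (v in seq_len(nrow(variants))) {
      M <- descriptor_matrix(data$structure, max_level = variants$level[v],
                             include_h = variants$include_h[v],
                             family = variants$family[v])
      mats[[v]] <- M
      vocabs[[v]] <- attr(M, "vocabulary")
    }
  }
  if (stats::var(y) == 0) stop("response has zero variance")
  if (is.null(n_partials)) n_partials <- if (preset == "both") 320L else 20L
  if (n_partials < 2L) stop("n_partials must be >= 2")

  n <- length(y)
  n_out <- floor(leave_fraction * n)
  set.seed(seed)
  partials <- vector("list", n_partials)
  for (i in seq_len(n_partials)) {
    v <- (i - 1L) %% length(mats) + 1L
    rows <- if (n_out > 0) sort(sample.int(n, n - n_out)) else seq_len(n)
    Xi <- mats[[v]][rows, , drop = FALSE]
    pm <- fit_scr(Xi, y[rows], ...)
    if (use_rbf) pm <- fit_rbf_scr(Xi, y[rows], pm)
    # leverage geometry of the selected-column training subspace
    Xs <- Xi[, pm$selected, drop = FALSE]
    XtX <- crossprod(Xs)
    XtX_inv <- tryCatch(solve(XtX), error = function(e)
      solve(XtX + diag(1e-8 * mean(diag(XtX)) + 1e-12, ncol(XtX))))
    pm$variant <- v
    pm$rows <- rows
    pm$ad <- list(XtX_inv = XtX_inv,
                  h_threshold = 3 * length(pm$selected) / length(rows))
    partials[[i]] <- pm
  }

  model <- structure(list(
    partials = partials, n_partials = n_partials, preset = preset,
    variants = variants, vocabularies = vocabs,
    max_level = max_level, use_rbf = use_rbf,
    seed = seed, leave_fraction = leave_fraction,
    ad_unseen_threshold = 0.2,
    training = list(n = n, mean = mean(y), range = diff(range(y)), ids = ids),
    matrix_input = matrix_input,
    Q2_LMO = NA_real_
  ), class = "consensus_model")

  if (compute_q2) {
    model$Q2_LMO <- cross_validate_lmo(mats[[1L]], y, seed = seed + 1L, ...)
  }
  model
}

#' @export
print.consensus_model <- function(x, ...) {
  r2 <- mean(vapply(x$partials, function(p) p$stats$R2, 0))
  v <- mean(vapply(x$partials, function(p) p$stats$n_vars, 0))
  cat(sprintf(
    "consensus_model: %d partials (preset '%s'), mean R2 = %.3f, mean vars = %.1f, Q2_LMO = %.3f\n",
    x$n_partials, x$preset, r2, v, x$Q2_LMO))
  invisible(x)
}

#' Leave-many-out cross-validation
#'
#' Repeatedly holds out a random `leave_fraction` of the rows, fits
#' [fit_scr()] on the remainder, and scores the held-out predictions;
#' returns the mean over rounds of `1 - PRESS / SS_tot`, where `SS_tot` sums
#' squared deviations of the held-out observations from the training-fold
#' mean. Defaults follow the 20 x 20% scheme.
#'
#' @param X descriptor matrix.
#' @param y response.
#' @param n_rounds number of rounds (default 20).
#' @param leave_fraction held-out fraction in (0, 0.5) (default 0.2).
#' @param seed random seed.
#' @param ... passed to [fit_scr()].
#' @return Q2_LMO (can be negative for uninformative models).
#' @export
cross_validate_lmo <- function(X, y, n_rounds = 20L, leave_fraction = 0.2,
                               seed = 20191, ...) {
  stopifnot(n_rounds >= 1L, leave_fraction > 0, leave_fraction < 0.5)
  n <- nrow(X)
  n_out <- max(1L, floor(leave_fraction * n))
  set.seed(seed)
  q2 <- numeric(n_rounds)
  for (r in seq_len(n_rounds)) {
    out <- sample.int(n, n_out)
    pm <- fit_scr(X[-out, , drop = FALSE], y[-out], ...)
    pred <- predict(pm, X[out, , drop = FALSE])
    press <- sum((y[out] - pred)^2)
    sst <- sum((y[out] - mean(y[-out]))^2)
    q2[r] <- 1 - press / sst
  }
  mean(q2)
}

#' Predict activities with a consensus model
#'
#' For each compound the descriptor vectors are rebuilt with the model's
#' stored configuration and vocabularies (unseen descriptors are dropped and
#' counted), each partial model predicts, and the consensus value is the
#' arithmetic mean over the partials for which the compound lies inside the
#' applicability domain (leverage in the partial's selected-column subspace
#' below its `3p/n` threshold). A compound is `in_ad` when its unseen
#' descriptor fraction is at most 0.2 and at least half of the partials
#' accept it; when every partial rejects a compound the mean over all
#' partials is still reported with `in_ad = FALSE`.
#'
#' @param object a [fit_consensus()] model.
#' @param newdata list of [molecular_graph()] objects, an [activity_table()]
#'   with structures, or (for matrix-trained models) a numeric matrix with
#'   the training columns.
#' @param ... unused.
#' @return data.frame: `id`, `logk7_pred`, `sd_partials`, `in_ad`,
#'   `unseen_fraction`, `n_partials_used`.
#' @export
predict.consensus_model <- function(object, newdata, ...) {
  if (object$matrix_input) {
    stopifnot(is.matrix(newdata))
    mats <- list(newdata[, object$vocabularies[[1L]], drop = FALSE])
    unseen <- rep(0, nrow(newdata))
    ids <- rownames(newdata)
    if (is.null(ids)) ids <- paste0("row", seq_len(nrow(newdata)))
  } else {
    graphs <- if (is.data.frame(newdata)) newdata$structure else newdata
    ids <- if (is.data.frame(newdata)) newdata$id else
      vapply(graphs, `[[`, "", "id")
    variants <- object$variants
    mats <- vector("list", nrow(variants))
    unseen <- rep(0, length(graphs))
    for (v in seq_len(nrow(variants))) {
      M <- suppressMessages(descriptor_matrix(
        graphs, max_level = variants$level[v],
        include_h = variants$include_h[v], family = variants$family[v],
        vocabulary = object$vocabularies[[v]]))
      mats[[v]] <- M
      if (v == 1L) unseen <- attr(M, "unseen_fraction")
    }
  }

  n_new <- nrow(mats[[1L]])
  preds <- matrix(NA_real_, n_new, object$n_partials)
  accept <- matrix(FALSE, n_new, object$n_partials)
  for (i in seq_along(object$partials)) {
    pm <- object$partials[[i]]
    M <- mats[[pm$variant]]
    preds[, i] <- predict(pm, M)
    Xs <- M[, pm$selected, drop = FALSE]
    h <- rowSums((Xs %*% pm$ad$XtX_inv) * Xs)
    accept[, i] <- h <= pm$ad$h_threshold
  }

  out <- data.frame(id = ids, logk7_pred = NA_real_, sd_partials = NA_real_,
                    in_ad = FALSE, unseen_fraction = unname(unseen),
                    n_partials_used = 0L, stringsAsFactors = FALSE)
  for (r in seq_len(n_new)) {
    use <- which(accept[r, ])
    if (!length(use)) use <- seq_len(ncol(preds))
    out$logk7_pred[r] <- mean(preds[r, use])
    out$sd_partials[r] <- if (length(use) > 1L) stats::sd(preds[r, use]) else 0
    out$n_partials_used[r] <- length(use)
    out$in_ad[r] <- unseen[r] <= object$ad_unseen_threshold &&
      mean(accept[r, ]) >= 0.5
  }
  out
}

#' Serialize / restore a consensus model as JSON
#'
#' The JSON document carries the full configuration, vocabularies and partial
#' models; identical fits (same data, same seed) produce byte-identical
#' files.
#'
#' @param model a [fit_consensus()] model.
#' @param path output / input file path.
#' @return `read_consensus_json` returns the restored `consensus_model`.
#' @export
write_consensus_json <- function(model, path) {
  stopifnot(inherits(model, "consensus_model"))
  ser <- model
  ser$partials <- lapply(model$partials, function(p) {
    p$ad$XtX_inv <- as.vector(p$ad$XtX_inv)
    if (!is.null(p$rbf)) p$rbf$centers <- list(dim = dim(p$rbf$centers),
                                               data = as.vector(p$rbf$centers))
    p
  })
  json <- jsonlite::serializeJSON(ser, digits = NA)
  writeLines(json, path)
  invisible(path)
}

#' @rdname write_consensus_json
#' @export
read_consensus_json <- function(path) {
  ser <- jsonlite::unserializeJSON(paste(readLines(path, warn = FALSE),
                                         collapse = "\n"))
  ser$partials <- lapply(ser$partials, function(p) {
    k <- length(p$selected)
    p$ad$XtX_inv <- matrix(p$ad$XtX_inv, k, k)
    if (!is.null(p$rbf)) {
      d <- p$rbf$centers$dim
      p$rbf$centers <- matrix(p$rbf$centers$data, d[1L], d[2L],
                              dimnames = list(NULL, p$selected))
    }
    p
  })
  class(ser) <- "consensus_model"
  ser
}
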