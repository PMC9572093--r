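#' Kinetic constants of the model oxidation system
#'
#' Bundles the physical constants of the initiated liquid-phase oxidation
#' used throughout the kinetic analysis. Defaults describe AIBN-initiated
#' oxidation of 1,4-dioxane at 348 K: quadratic peroxyl-radical termination
#' constant `2k6 = 6.67e7` L mol^-1 s^-1, chain propagation
#' `k2 = 7.9` L mol^-1 s^-1, substrate concentration `[RH] = 11.75` mol/L,
#' and initiation rate `Vi = 1e-7` mol L^-1 s^-1. `k2` and `RH_conc` do not
#' enter the F-parameter analysis; they are carried for the simulator.
#'
#' @param two_k6,k2,RH_conc,Vi,T_K positive numerics (units above; `T_K` in
#'   kelvin).
#' @return List of class `kinetic_constants`.
#' @export
kinetic_constants <- function(two_k6 = 6.67e7, k2 = 7.9, RH_conc = 11.75,
                              Vi = 1e-7, T_K = 348) {
  vals <- c(two_k6 = two_k6, k2 = k2, RH_conc = RH_conc, Vi = Vi, T_K = T_K)
  if (any(vals <= 0)) stop("all kinetic constants must be positive")
  structure(as.list(vals), class = "kinetic_constants")
}

#' Initiation rate from the initiator decay law
#'
#' `Vi = 2 e kp [AIBN]`, with the decay constant from
#' `log10(kp) = 17.70 - 35 / (4.575e-3 * T)` (activation energy of 35
#' kcal/mol over 4.575e-3 kcal mol^-1 K^-1, i.e. 2.303*R*T in those units);
#' `e` is the probability of radical escape into the bulk (default 0.5).
#'
#' @param T_K temperature in kelvin.
#' @param AIBN_conc initiator concentration, mol/L.
#' @param e cage-escape probability in (0, 1].
#' @return List with `kp` (s^-1) and `Vi` (mol L^-1 s^-1).
#' @examples
#' initiation_rate(348, 1.9e-3)
#' @export
initiation_rate <- function(T_K, AIBN_conc, e = 0.5) {
  stopifnot(T_K > 0, AIBN_conc >= 0, e > 0, e <= 1)
  kp <- 10^(17.70 - 35 / (4.575e-3 * T_K))
  list(kp = kp, Vi = 2 * e * kp * AIBN_conc)
}

#' Rate table of inhibited initial oxidation rates
#'
#' Holds (inhibitor concentration, initial oxygen-uptake rate) observations
#' for one inhibitor. Exactly one `conc = 0` row designates the uninhibited
#' rate `V0`.
#'
#' @param conc concentrations, mol/L (one zero entry).
#' @param rate initial rates, mol L^-1 s^-1 (all positive).
#' @param id inhibitor id.
#' @return data.frame of class `rate_table` with attribute `V0`.
#' @export
rate_table <- function(conc, rate, id = "") {
  stopifnot(length(conc) == length(rate))
  if (any(conc < 0)) stop("concentrations must be >= 0")
  if (any(rate <= 0)) stop("rates must be > 0")
  if (sum(conc == 0) != 1L) stop("exactly one conc = 0 row must designate V0")
  df <- data.frame(conc = conc, rate = rate)
  df <- df[order(df$conc), , drop = FALSE]
  rownames(df) <- NULL
  if (any(diff(df$rate) > 0))
    warning("initial rate is not monotonically decreasing with concentration")
  attr(df, "V0") <- df$rate[df$conc == 0]
  attr(df, "id") <- id
  class(df) <- c("rate_table", "data.frame")
  df
}

#' Read a rate table from CSV
#'
#' Expects columns `conc_M` and `rate_M_per_s`, with optional scale-factor
#' header comment lines (`# scale_conc: 1e-6`) applied multiplicatively.
#'
#' @param path CSV file path.
#' @param id inhibitor id (defaults to file name).
#' @export
read_rate_table <- function(path, id = sub("[.]csv$", "", basename(path))) {
  hdr <- readLines(path, n = 10L, warn = FALSE)
  scl_c <- scl_r <- 1
  m <- grep("^#\\s*scale_conc:", hdr, value = TRUE)
  if (length(m)) scl_c <- as.numeric(sub(".*:", "", m[1]))
  m <- grep("^#\\s*scale_rate:", hdr, value = TRUE)
  if (length(m)) scl_r <- as.numeric(sub(".*:", "", m[1]))
  df <- utils::read.csv(path, comment.char = "#")
  rate_table(df$conc_M * scl_c, df$rate_M_per_s * scl_r, id = id)
}

#' Initial rate from a kinetic curve
#'
#' Least-squares slope of oxygen uptake versus time over the initial window,
#' with standard error and the window-fit R^2 as a linearity diagnostic.
#'
#' @param time,uptake numeric vectors (seconds; mol/L absorbed), time
#'   strictly increasing.
#' @param window either a number of leading points (`n_points`) or a time
#'   span in seconds (`t_max`); default: first 10% of points, minimum 3.
#' @return List with `rate`, `se`, `r_squared`, `n_points`.
#' @export
initial_rate <- function(time, uptake, window = NULL) {
  stopifnot(length(time) == length(uptake), !is.unsorted(time, strictly = TRUE))
  n <- length(time)
  idx <- if (is.null(window)) seq_len(max(3L, ceiling(0.1 * n)))
  else if (window >= 1 && window == round(window)) seq_len(as.integer(window))
  else seq_len(sum(time <= window))
  if (n < 3L || length(idx) < 3L)
    stop("initial window must contain at least 3 points")
  if (max(idx) > n) stop("window exceeds the available data")
  fit <- stats::lm(uptake[idx] ~ time[idx])
  sm <- summary(fit)
  list(rate = unname(stats::coef(fit)[2L]),
       se = unname(sm$coefficients[2L, 2L]),
       r_squared = sm$r.squared, n_points = length(idx))
}

#' Inhibition parameter F
#'
#' `F = V0/V - V/V0`, the dimensionless measure of rate suppression; linear
#' in inhibitor concentration under quasi-steady-state chain oxidation.
#'
#' @param V0 uninhibited initial rate (> 0).
#' @param V inhibited initial rate (> 0); warns if `V > V0`.
#' @return F (vectorized over `V`).
#' @examples
#' f_parameter(2.30e-6, 1.13e-6)
#' @export
f_parameter <- function(V0, V) {
  if (any(V0 <= 0) || any(V <= 0)) stop("rates must be positive")
  if (any(V > V0)) warning("inhibited rate exceeds uninhibited rate")
  V0 / V - V / V0
}

#' Effective inhibition constant f*k7 from a rate table
#'
#' Computes F per non-zero-concentration row, fits the through-origin
#' least-squares line of F versus concentration, and scales the slope by
#' `sqrt(2k6 * Vi)`:
#' `F = f*k7 [InH] / sqrt(2k6 Vi)`  =>  `f*k7 = slope * sqrt(2k6 Vi)`.
#' The through-origin fit is the package's documented convention for this
#' analysis (the F-intercept is zero by construction at `[InH] = 0`).
#'
#' @param table a [rate_table()].
#' @param constants a [kinetic_constants()].
#' @return List with `fk7`, `se` (propagated from the slope SE), `slope`,
#'   `slope_se`, and `points` (conc, F) used.
#' @export
fit_fk7 <- function(table, constants = kinetic_constants()) {
  stopifnot(inherits(table, "rate_table"))
  V0 <- attr(table, "V0")
  nz <- table[table$conc > 0, , drop = FALSE]
  if (nrow(nz) < 1L) stop("need at least one non-zero concentration")
  F_vals <- f_parameter(V0, nz$rate)
  scale <- sqrt(constants$two_k6 * constants$Vi)
  if (all(F_vals == 0)) {
    warning("all F values are zero; fk7 = 0")
    return(list(fk7 = 0, se = 0, slope = 0, slope_se = 0,
                points = data.frame(conc = nz$conc, F = F_vals)))
  }
  if (nrow(nz) == 1L) {
    slope <- F_vals / nz$conc; slope_se <- 0
  } else {
    fit <- stats::lm(F_vals ~ 0 + nz$conc)
    slope <- unname(stats::coef(fit))
    slope_se <- unname(summary(fit)$coefficients[1L, 2L])
  }
  if (slope < 0) warning("negative slope: compound does not inhibit")
  list(fk7 = slope * scale, se = slope_se * scale,
       slope = slope, slope_se = slope_se,
       points = data.frame(conc = nz$conc, F = F_vals))
}

#' Induction period of an oxygen-uptake curve
#'
#' Two-tangent construction: the curve is split at the interior breakpoint
#' minimizing the total residual sum of squares of two straight-line fits
#' (initial inhibited segment, final uninhibited segment); tau is the
#' abscissa of the intersection of the two lines. A curve whose two slopes
#' agree within `tol` (relative) has no induction period: tau = 0 with
#' `flagged = TRUE`.
#'
#' @param time,uptake the curve (seconds; mol/L), time strictly increasing,
#'   at least 6 points.
#' @param tol relative slope-difference tolerance (default 0.05).
#' @return List with `tau`, `slope_initial`, `slope_final`, `flagged`.
#' @export
induction_period <- function(time, uptake, tol = 0.05) {
  stopifnot(length(time) == length(uptake), length(time) >= 6L,
            !is.unsorted(time, strictly = TRUE))
  n <- length(time)
  best <- NULL; best_sse <- Inf
  for (k in 3:(n - 3L)) {
    i1 <- seq_len(k); i2 <- (k + 1L):n  # disjoint segments
    f1 <- stats::lm.fit(cbind(1, time[i1]), uptake[i1])
    f2 <- stats::lm.fit(cbind(1, time[i2]), uptake[i2])
    sse <- sum(f1$residuals^2) + sum(f2$residuals^2)
    if (sse < best_sse) {
      best_sse <- sse
      best <- list(a1 = f1$coefficients[1L], b1 = f1$coefficients[2L],
                   a2 = f2$coefficients[1L], b2 = f2$coefficients[2L])
    }
  }
  b1 <- unname(best$b1); b2 <- unname(best$b2)
  denom <- max(abs(b1), abs(b2))
  if (denom == 0 || abs(b2 - b1) / denom < tol)
    return(list(tau = 0, slope_initial = b1, slope_final = b2, flagged = TRUE))
  tau <- unname((best$a2 - best$a1) / (b1 - b2))
  list(tau = tau, slope_initial = b1, slope_final = b2, flagged = FALSE)
}

#' Stoichiometric inhibition coefficient f
#'
#' Fits the through-origin line of induction period versus inhibitor
#' concentration; from `tau = f [InH] / Vi`, `f = slope * Vi`.
#'
#' @param conc inhibitor concentrations, mol/L.
#' @param tau induction periods, seconds.
#' @param Vi initiation rate, mol L^-1 s^-1.
#' @return List with `f`, `se`.
#' @examples
#' fit_f_stoich(c(0.5e-6, 1.0e-6), c(100, 200), Vi = 1e-7)
#' @export
fit_f_stoich <- function(conc, tau, Vi) {
  stopifnot(length(conc) == length(tau), length(conc) >= 1L, Vi > 0)
  if (length(conc) == 1L) {
    slope <- tau / conc; slope_se <- 0
  } else {
    fit <- stats::lm(tau ~ 0 + conc)
    slope <- unname(stats::coef(fit))
    slope_se <- unname(summary(fit)$coefficients[1L, 2L])
  }
  if (slope < 0) stop("negative tau-vs-concentration slope")
  list(f = slope * Vi, se = slope_se * Vi)
}

#' Chain-termination rate constant k7
#'
#' `k7 = f*k7 / f`, with the standard error propagated in quadrature of the
#' relative errors; also reports `logk7 = log10(k7)`.
#'
#' @param fk7 effective inhibition constant (L mol^-1 s^-1), optionally with
#'   `fk7_se`.
#' @param f_stoich stoichiometric coefficient (> 0), optionally with `f_se`.
#' @param fk7_se,f_se standard errors (default 0).
#' @return List of class `inhibition_result` with `fk7`, `f_stoich`, `k7`,
#'   `k7_se`, `logk7` and the input SEs.
#' @examples
#' k7_from(1.08e6, 40)
#' @export
k7_from <- function(fk7, f_stoich, fk7_se = 0, f_se = 0) {
  if (f_stoich <= 0) stop("f must be positive")
  k7 <- fk7 / f_stoich
  rel <- sqrt((fk7_se / fk7)^2 + (f_se / f_stoich)^2)
  structure(list(fk7 = fk7, fk7_se = fk7_se,
                 f_stoich = f_stoich, f_se = f_se,
                 k7 = k7, k7_se = abs(k7) * rel, logk7 = log10(k7)),
            class = "inhibition_result")
}

#' @export
print.inhibition_result <- function(x, ...) {
  cat(sprintf("fk7 = %.3g +/- %.2g, f = %.3g +/- %.2g => k7 = %.3g +/- %.2g L/mol/s (logk7 = %.2f)\n",
              x$fk7, x$fk7_se, x$f_stoich, x$f_se, x$k7, x$k7_se, x$logk7))
  invisible(x)
}

#' Full kinetic determination from a rate table
#'
#' Convenience chain: [fit_fk7()] on the table, then [k7_from()] with a
#' supplied stoichiometric coefficient (from [fit_f_stoich()] or literature).
#'
#' @param table a [rate_table()].
#' @param f_stoich stoichiometric coefficient, with optional `f_se`.
#' @param constants a [kinetic_constants()].
#' @param f_se standard error of `f_stoich`.
#' @return An `inhibition_result`.
#' @export
determine_k7 <- function(table, f_stoich, constants = kinetic_constants(),
                         f_se = 0) {
  fit <- fit_fk7(table, constants)
  k7_from(fit$fk7, f_stoich, fk7_se = fit$se, f_se = f_se)
}
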