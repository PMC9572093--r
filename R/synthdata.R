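#' Simulated rate table from the quasi-steady-state inhibition law
#'
#' Inverts the F-parameter relation: for each concentration,
#' `F = fk7 * c / sqrt(2k6 * Vi)`, and since `F = V0/V - V/V0`, the rate
#' ratio is the positive quadratic root `V/V0 = (-F + sqrt(F^2 + 4)) / 2`.
#' Multiplicative Gaussian noise (relative sd `noise_sd`) is applied to the
#' inhibited rates; the `conc = 0` row carries `V0` exactly. This generative
#' law is the quasi-steady-state consequence of the inhibited radical-chain
#' mechanism, i.e. precisely the assumption the analysis equations make.
#'
#' @param fk7_true effective inhibition constant, L mol^-1 s^-1.
#' @param conc concentration grid, mol/L (default: the experimental grid
#'   (0.44, 1.24, 1.88, 2.50, 3.13)e-6).
#' @param V0 uninhibited rate, mol L^-1 s^-1 (default 2.3e-6).
#' @param constants a [kinetic_constants()].
#' @param noise_sd relative noise on rates (default 0).
#' @param seed integer seed (used when `noise_sd > 0`).
#' @param id inhibitor id.
#' @return A [rate_table()].
#' @examples
#' tab <- generate_rate_table(1.32e6)
#' fit_fk7(tab)$fk7
#' @export
generate_rate_table <- function(fk7_true,
                                conc = c(0.44, 1.24, 1.88, 2.50, 3.13) * 1e-6,
                                V0 = 2.3e-6,
                                constants = kinetic_constants(),
                                noise_sd = 0, seed = 1L, id = "sim") {
  stopifnot(fk7_true > 0, V0 > 0, all(conc > 0), noise_sd >= 0)
  F_vals <- fk7_true * conc / sqrt(constants$two_k6 * constants$Vi)
  ratio <- (-F_vals + sqrt(F_vals^2 + 4)) / 2
  V <- V0 * ratio
  if (noise_sd > 0) {
    set.seed(seed)
    V <- V * (1 + stats::rnorm(length(V), 0, noise_sd))
  }
  rate_table(c(0, conc), c(V0, V), id = id)
}

#' Simulated oxygen-uptake curves with induction periods
#'
#' Generates one curve per concentration under the piecewise-linear
#' quasi-steady-state picture: uptake grows with the inhibited slope
#' `V_inh(c)` (from the same law as [generate_rate_table()]) until the
#' induction period `tau = f_true * c / Vi`, then with the uninhibited slope
#' `V0`, continuous at the corner. The `conc = 0` curve is a straight line
#' of slope `V0`. A smoothing half-width (seconds) optionally rounds the
#' corner by quadratic blending, for robustness testing; additive Gaussian
#' noise (sd in mol/L) can be applied to the uptake.
#'
#' @param f_true stoichiometric inhibition coefficient.
#' @param fk7_true effective inhibition constant, L mol^-1 s^-1.
#' @param conc concentration grid, mol/L (0 allowed).
#' @param V0,constants as in [generate_rate_table()].
#' @param t_end,n_points time grid: `n_points` samples on `[0, t_end]`
#'   seconds (defaults 3000 s, 151 points).
#' @param smooth_halfwidth corner-rounding half-width, seconds (default 0).
#' @param noise_sd additive uptake noise, mol/L (default 0).
#' @param seed integer seed.
#' @return Named list of data frames (`time`, `uptake`), one per
#'   concentration, each with attributes `tau_true` and `conc`.
#' @export
generate_curves <- function(f_true, fk7_true,
                            conc = c(0, 0.44, 1.24, 1.88, 2.50, 3.13) * 1e-6,
                            V0 = 2.3e-6, constants = kinetic_constants(),
                            t_end = 3000, n_points = 151L,
                            smooth_halfwidth = 0, noise_sd = 0, seed = 1L) {
  stopifnot(f_true > 0, fk7_true > 0, all(conc >= 0), n_points >= 6L)
  tt <- seq(0, t_end, length.out = n_points)
  set.seed(seed)
  out <- lapply(conc, function(cc) {
    if (cc == 0) {
      tau <- 0
      up <- V0 * tt
    } else {
      F_c <- fk7_true * cc / sqrt(constants$two_k6 * constants$Vi)
      v_inh <- V0 * (-F_c + sqrt(F_c^2 + 4)) / 2
      tau <- f_true * cc / constants$Vi
      up <- ifelse(tt < tau, v_inh * tt, v_inh * tau + V0 * (tt - tau))
      if (smooth_halfwidth > 0) {
        w <- smooth_halfwidth
        inside <- abs(tt - tau) < w
        # quadratic blend matching both lines and slopes at tau -/+ w
        up[inside] <- v_inh * tt[inside] +
          (V0 - v_inh) * (tt[inside] - tau + w)^2 / (4 * w)
      }
    }
    if (noise_sd > 0) up <- up + stats::rnorm(length(up), 0, noise_sd)
    structure(data.frame(time = tt, uptake = up),
              tau_true = tau, conc = cc)
  })
  names(out) <- paste0("c", format(conc, scientific = TRUE, digits = 3))
  out
}

# substituent fragments used by the phenol grammar; ring-closure digits 3/4
# are safe inside the open aromatic ring
phenol_substituents <- function() {
  list(
    alkyl = c("", "C", "CC", "CCC", "C(C)(C)C", "CC(C)C", "CCCCC"),
    thio = c("", "SC", "SCC", "SCCC", "CSC"),
    bulky = c("", "C", "C(C)(C)C", "C3CCc4ccccc4O3", "C3Oc4ccccc4CC3")
  )
}

#' Synthetic structure-activity dataset with known ground truth
#'
#' Emulates a phenolic-antioxidant training series: structures are generated
#' from a combinatorial grammar (phenol core with ortho/para substituents
#' drawn from alkyl, alkylthio and chroman-like sets), and activities are an
#' exactly linear function of MNA descriptor counts plus Gaussian noise:
#' `logk7 = offset + sum(w * count) + N(0, noise_sd)`. The support weights
#' `w` are drawn over descriptors of intermediate prevalence and then scaled
#' so the noise-free activities span `activity_range`; the returned ground
#' truth enables parameter-recovery tests of the whole modelling chain.
#'
#' @param n_compounds number of records (>= 30 recommended; sampling is with
#'   replacement beyond the grammar capacity, with a warning).
#' @param noise_sd activity noise sd, log-units (default 0.3).
#' @param activity_range target span of the noise-free activities (default
#'   7.06 log-units).
#' @param activity_offset minimum noise-free activity (default 1.0).
#' @param n_support number of weighted descriptors (default 8).
#' @param max_level MNA level used for the generative signal (default 2).
#' @param seed integer seed; the generator is a pure function of its
#'   arguments.
#' @return List with `records` (an [activity_table()] with structures),
#'   `weights` (named true weights), `offset`, `scale`, `smiles`.
#' @export
generate_qspr_dataset <- function(n_compounds = 148L, noise_sd = 0.3,
                                  activity_range = 7.06,
                                  activity_offset = 1.0,
                                  n_support = 8L, max_level = 2L, seed = 7L) {
  stopifnot(n_compounds >= 2L, noise_sd >= 0, activity_range > 0)
  subs <- phenol_substituents()
  grid <- expand.grid(r2 = subs$alkyl, r4 = subs$thio, r6 = subs$bulky,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  grid <- grid[rowSums(grid != "") > 0, , drop = FALSE]  # skip bare phenol dup
  cap <- nrow(grid)
  set.seed(seed)
  if (n_compounds > cap) {
    warning("requested n exceeds grammar capacity (", cap,
            "); sampling with replacement")
    pick <- sample.int(cap, n_compounds, replace = TRUE)
  } else {
    pick <- sample.int(cap, n_compounds)
  }
  branch <- function(r) ifelse(r == "", "", paste0("(", r, ")"))
  smiles <- paste0("Oc1c", branch(grid$r2[pick]), "cc", branch(grid$r4[pick]),
                   "cc1", grid$r6[pick])
  ids <- sprintf("syn%03d", seq_len(n_compounds))
  graphs <- parse_structures(paste(smiles, ids), format = "smiles")

  M <- suppressMessages(descriptor_matrix(graphs, max_level = max_level))
  counts <- M[, setdiff(colnames(M), WHOLE_MOL_COLS), drop = FALSE]
  prev <- colMeans(counts > 0)
  cand <- colnames(counts)[prev >= 0.2 & prev <= 0.8]
  if (length(cand) < n_support) cand <- colnames(counts)[order(-pmin(prev, 1 - prev))]
  support <- sort(sample(cand, min(n_support, length(cand))), method = "radix")
  w_raw <- stats::rnorm(length(support), 0, 1)
  signal <- drop(counts[, support, drop = FALSE] %*% w_raw)
  span <- diff(range(signal))
  scale <- if (span > 0) activity_range / span else 1
  w <- w_raw * scale
  y0 <- (signal - min(signal)) * scale + activity_offset
  y <- y0 + if (noise_sd > 0) stats::rnorm(n_compounds, 0, noise_sd) else 0

  list(records = activity_table(ids, y, structure = graphs),
       weights = stats::setNames(w, support),
       offset = activity_offset - min(signal) * scale,
       scale = scale,
       smiles = stats::setNames(smiles, ids))
}
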