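# Independent brute-force oracle for the external-validation battery.
# Deliberately written as direct formula transcription with explicit loops,
# sharing no code with the package implementation.
oracle_metrics <- function(obs, pred, train_mean) {
  n <- length(obs)
  mo <- sum(obs) / n
  mp <- sum(pred) / n
  sxy <- sxx <- syy <- 0
  for (i in 1:n) {
    sxy <- sxy + (obs[i] - mo) * (pred[i] - mp)
    sxx <- sxx + (obs[i] - mo)^2
    syy <- syy + (pred[i] - mp)^2
  }
  r2 <- (sxy / sqrt(sxx * syy))^2
  k <- sum(obs * pred) / sum(pred * pred)
  kp <- sum(obs * pred) / sum(obs * obs)
  num0 <- nump <- 0
  for (i in 1:n) {
    num0 <- num0 + (obs[i] - k * pred[i])^2
    nump <- nump + (pred[i] - kp * obs[i])^2
  }
  r2_0 <- 1 - num0 / sxx
  r2p_0 <- 1 - nump / syy
  rm2 <- r2 * (1 - sqrt(abs(r2 - r2_0)))
  rm2p <- r2 * (1 - sqrt(abs(r2 - r2p_0)))
  ccc <- 2 * (sxy / n) / (sxx / n + syy / n + (mo - mp)^2)
  press <- 0
  for (i in 1:n) press <- press + (obs[i] - pred[i])^2
  q2f1 <- 1 - press / sum((obs - train_mean)^2)
  q2f2 <- 1 - press / sxx
  absres <- abs(obs - pred)
  mae <- sum(absres) / n
  sdv <- sqrt(sum((absres - mae)^2) / (n - 1))
  list(R2 = r2, R2_0 = r2_0, R2p_0 = r2p_0,
       rm2_avg = (rm2 + rm2p) / 2, rm2_delta = abs(rm2 - rm2p),
       CCC = ccc, Q2_F1 = q2f1, Q2_F2 = q2f2,
       RMSE = sqrt(press / n), MAE = mae, SD = sdv,
       MAE_plus_3SD = mae + 3 * sdv)
}

# parse a small shared set of molecules once per test run
shared_mols <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- suppressWarnings(parse_structures(c(
        "C methane",
        "CCO ethanol",
        "CO methanol",
        "CCCC butane",
        "C1CCCCC1 cyclohexane",
        "c1ccccc1 benzene",
        "Oc1ccccc1 phenol",
        "C[NH3+] methylammonium",
        "CC1CCc2ccccc2O1 methylchroman"), "smiles"))
    }
    cache
  }
})

# hand-built metric_report for classification-rule tests
fake_report <- function(MAE, MAE_plus_3SD, rfam = 0.99, rm2_avg = 0.95,
                        rm2_delta = 0.05) {
  structure(list(n_used = 20L, R2 = rfam, R2_0 = rfam, R2p_0 = rfam,
                 rm2_avg = rm2_avg, rm2_delta = rm2_delta, rm2_flag = FALSE,
                 CCC = rfam, Q2_F1 = rfam, Q2_F2 = rfam,
                 RMSE = MAE, MAE = MAE, SD = (MAE_plus_3SD - MAE) / 3,
                 MAE_plus_3SD = MAE_plus_3SD, systematic_error = FALSE),
            class = "metric_report")
}
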