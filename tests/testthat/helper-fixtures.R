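# small in-code builders shared across the suite

make_records <- function(beta, n, significant = NULL, country = "X",
                         predictor = "performance expectancy",
                         outcome = "behavioral intention") {
  k <- length(beta)
  if (is.null(significant)) significant <- rep(TRUE, k)
  path_records(data.frame(
    dataset_id = sprintf("d%03d", seq_len(k)),
    country = rep_len(country, k),
    predictor = rep_len(predictor, k),
    outcome = rep_len(outcome, k),
    beta = beta,
    n = rep_len(n, k),
    significant = significant,
    stringsAsFactors = FALSE
  ))
}

make_effects <- function(z, se) {
  effect_points_from_z(
    data.frame(dataset_id = sprintf("e%03d", seq_along(z)),
               effect_z = z, se_z = se),
    se_from_n = FALSE)
}

# independently coded direct-summation pooling oracle (kept free of any
# package internals so it can vouch for them)
oracle_pool <- function(z, se, conf_level = 0.95) {
  k <- length(z)
  w <- se^-2
  zf <- sum(w * z) / sum(w)
  Q <- 0
  for (i in seq_len(k)) Q <- Q + w[i] * (z[i] - zf)^2
  tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (se^2 + tau2)
  zr <- sum(ws * z) / sum(ws)
  ser <- sqrt(1 / sum(ws))
  crit <- qnorm(1 - (1 - conf_level) / 2)
  list(z_fixed = zf, Q = Q, tau2 = tau2, z_random = zr, se_random = ser,
       ci_z = c(zr - crit * ser, zr + crit * ser),
       i2 = if (Q > 0) max(0, (Q - (k - 1)) / Q) * 100 else 0)
}

# closed-form OLS via the normal equations, independent of stats::lm
oracle_ols <- function(x, y) {
  n <- length(x)
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  res <- y - a - b * x
  s2 <- sum(res^2) / (n - 2)
  se_b <- sqrt(s2 / sum((x - mean(x))^2))
  se_a <- sqrt(s2 * (1 / n + mean(x)^2 / sum((x - mean(x))^2)))
  list(a = a, b = b, se_a = se_a, se_b = se_b)
}

# two-tailed power of the Fisher z significance test at effect r, size n
oracle_power <- function(r, n, alpha = 0.05) {
  crit <- qnorm(1 - alpha / 2)
  ncp <- atanh(r) * sqrt(n - 3)
  pnorm(-crit - ncp) + pnorm(ncp - crit)
}
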