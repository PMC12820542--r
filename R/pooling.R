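#' Fixed-effect (inverse-variance) pooling on the Fisher z scale
#'
#' Pools study effects with weights `w_i = 1 / se_i^2` and computes the
#' Cochran heterogeneity statistic `Q = sum w_i (z_i - z_fixed)^2` together
#' with each study's contribution to it. `Q` is invariant to the order of
#' the studies and the per-study components sum to `Q` exactly.
#'
#' @param effects an `effect_points` data frame (needs `z`, `se_z`; at least
#'   two studies).
#' @return a list with elements `z_fixed`, `Q`, and `contributions`, a data
#'   frame of per-study `dataset_id`, `w_fixed` and `q_component`.
#' @export
pool_fixed <- function(effects) {
  z <- effects$z
  se <- effects$se_z
  k <- length(z)
  if (k < 2) stop("pool_fixed: need at least 2 effects", call. = FALSE)
  if (any(se <= 0)) stop("pool_fixed: standard errors must be positive",
                         call. = FALSE)
  w <- 1 / se^2
  z_fixed <- sum(w * z) / sum(w)
  q_comp <- w * (z - z_fixed)^2
  list(
    z_fixed = z_fixed,
    Q = sum(q_comp),
    contributions = data.frame(
      dataset_id = if (!is.null(effects$dataset_id)) effects$dataset_id
                   else as.character(seq_len(k)),
      w_fixed = w,
      q_component = q_comp,
      stringsAsFactors = FALSE
    )
  )
}

#' DerSimonian-Laird between-study variance
#'
#' One-step moment estimator
#' `tau2 = max(0, (Q - (k - 1)) / (sum(w) - sum(w^2)/sum(w)))`
#' with `w` the fixed-effect weights. Not iterated.
#'
#' @param effects an `effect_points` data frame.
#' @param Q optional Cochran Q from [pool_fixed()] on the same effects;
#'   computed if missing.
#' @return the non-negative between-study variance on the Fisher z scale.
#' @export
dl_tau2 <- function(effects, Q = NULL) {
  w <- 1 / effects$se_z^2
  k <- length(w)
  if (is.null(Q)) Q <- pool_fixed(effects)$Q
  denom <- sum(w) - sum(w^2) / sum(w)
  if (!is.finite(denom) || denom <= sqrt(.Machine$double.eps)) {
    stop("dl_tau2: degenerate weight configuration (effectively all weight ",
         "in one study)", call. = FALSE)
  }
  max(0, (Q - (k - 1)) / denom)
}

#' I-squared heterogeneity percentage
#'
#' `I2 = max(0, (Q - (k - 1)) / Q) * 100`, the share of total effect-size
#' variability attributable to true between-study heterogeneity rather than
#' sampling error. Values above 75% are conventionally read as substantial
#' heterogeneity.
#'
#' @param Q Cochran Q statistic (>= 0).
#' @param k number of studies (>= 2).
#' @return a percentage in \[0, 100\]; `Q = 0` yields 0.
#' @export
i_squared <- function(Q, k) {
  stopifnot(Q >= 0, k >= 2)
  if (Q == 0) return(0)
  max(0, (Q - (k - 1)) / Q) * 100
}

#' DerSimonian-Laird random-effects pooling
#'
#' Full random-effects synthesis of Fisher z effects: fixed-effect pooling
#' for `Q`, the DerSimonian-Laird `tau2`, random-effects weights
#' `1 / (se_i^2 + tau2)`, a normal-theory 95% confidence interval, a
#' two-tailed p value, `I2`, and the back-transform of the pooled effect and
#' its interval to the correlation scale via `tanh`. When `tau2 = 0` the
#' random- and fixed-effect estimates coincide.
#'
#' @param effects an `effect_points` data frame with at least two studies.
#' @param conf_level confidence level (default 0.95, giving the normal
#'   critical value 1.959964; a z interval, not a t interval).
#' @return an object of class `pool_result`: a list with `k`, `z_fixed`,
#'   `Q`, `tau2`, `z_random`, `se_random`, `ci_z`, `zscore`, `p`, `i2`, `r`,
#'   `ci_r`, `conf_level` and the per-study `contributions` (fixed and
#'   random weights and Q components).
#' @export
pool_random <- function(effects, conf_level = 0.95) {
  fx <- pool_fixed(effects)
  k <- nrow(effects)
  tau2 <- dl_tau2(effects, Q = fx$Q)
  w_star <- 1 / (effects$se_z^2 + tau2)
  z_random <- sum(w_star * effects$z) / sum(w_star)
  se_random <- 1 / sqrt(sum(w_star))
  crit <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci_z <- c(z_random - crit * se_random, z_random + crit * se_random)
  zscore <- z_random / se_random
  contributions <- fx$contributions
  contributions$w_random <- w_star
  structure(list(
    k = k,
    z_fixed = fx$z_fixed,
    Q = fx$Q,
    tau2 = tau2,
    z_random = z_random,
    se_random = se_random,
    ci_z = ci_z,
    zscore = zscore,
    p = 2 * stats::pnorm(-abs(zscore)),
    i2 = i_squared(fx$Q, k),
    r = tanh(z_random),
    ci_r = tanh(ci_z),
    conf_level = conf_level,
    contributions = contributions
  ), class = "pool_result")
}

#' @export
print.pool_result <- function(x, digits = 3, ...) {
  f <- function(v) formatC(v, format = "f", digits = digits)
  cat("Random-effects pooling (DerSimonian-Laird), k = ", x$k, "\n", sep = "")
  cat("  pooled r = ", f(x$r), ", ", round(100 * x$conf_level), "% CI ",
      f(x$ci_r[1]), " to ", f(x$ci_r[2]), "\n", sep = "")
  cat("  Fisher z = ", f(x$z_random), " (SE ", f(x$se_random), "), z score ",
      f(x$zscore), ", P ", format_p(x$p), "\n", sep = "")
  cat("  Q = ", f(x$Q), ", tau2 = ", f(x$tau2), ", I2 = ", f(x$i2), "%\n",
      sep = "")
  invisible(x)
}

# report-layer p-value style: "<.001" below a thousandth, else ".49"
format_p <- function(p, digits = 3) {
  ifelse(p < 0.001, "<.001",
         sub("^0", "", formatC(p, format = "f", digits = digits)))
}

#' Random-effects pooling within subgroups
#'
#' Pools each subgroup independently, re-estimating `tau2` within each
#' group (no common heterogeneity model). The default grouping contrasts
#' studies conducted in China with all remaining studies, the usual
#' regional-bias check when one country dominates the evidence base.
#'
#' @param effects an `effect_points` data frame.
#' @param groups a vector of group labels, one per effect; defaults to
#'   `"China"` versus `"Other countries"` from the `country` column.
#' @param conf_level passed to [pool_random()].
#' @return a named list of `pool_result` objects, one per group label (in
#'   label order).
#' @export
pool_subgroups <- function(effects, groups = NULL, conf_level = 0.95) {
  if (is.null(groups)) {
    if (all(is.na(effects$country))) {
      stop("pool_subgroups: no country labels and no explicit grouping",
           call. = FALSE)
    }
    groups <- ifelse(effects$country == "China", "China", "Other countries")
  }
  stopifnot(length(groups) == nrow(effects))
  if (anyNA(groups)) {
    stop("pool_subgroups: every effect must be assigned exactly one group",
         call. = FALSE)
  }
  out <- list()
  for (g in sort(unique(as.character(groups)))) {
    sub <- effects[groups == g, , drop = FALSE]
    if (nrow(sub) < 2) {
      stop("pool_subgroups: group '", g, "' has fewer than 2 effects",
           call. = FALSE)
    }
    out[[g]] <- pool_random(sub, conf_level = conf_level)
  }
  out
}

#' Pool every grouped path of a corpus
#'
#' Runs [effect_points()] and [pool_random()] per path group, skipping
#' groups with fewer than two usable beta coefficients, and assembles the
#' standard meta-analysis report table.
#'
#' @param groups a `path_groups` data frame from [group_paths()].
#' @param lambda,negative_lambda_zero,conf_level passed through.
#' @param quiet suppress skip messages.
#' @return a data frame with one row per pooled path: `outcome`,
#'   `predictor`, `k`, `r`, `ci_lower`, `ci_upper`, `Q`, `tau2`, `zscore`,
#'   `p`, `i2`; `attr(, "pools")` holds the underlying `pool_result`
#'   objects keyed `"outcome|predictor"`.
#' @export
pool_paths <- function(groups, lambda = 1, negative_lambda_zero = FALSE,
                       conf_level = 0.95, quiet = FALSE) {
  rows <- list()
  pools <- list()
  for (i in seq_len(nrow(groups))) {
    recs <- groups$records[[i]]
    usable <- sum(!is.na(recs$beta))
    if (usable < 2) {
      if (!quiet) {
        message("pool_paths: skipped ", groups$predictor[i], " -> ",
                groups$outcome[i], " (", usable, " usable beta)")
      }
      next
    }
    ep <- effect_points(path_records(recs), lambda = lambda,
                        negative_lambda_zero = negative_lambda_zero,
                        quiet = TRUE)
    pr <- pool_random(ep, conf_level = conf_level)
    key <- paste(groups$outcome[i], groups$predictor[i], sep = "|")
    pools[[key]] <- pr
    rows[[key]] <- data.frame(
      outcome = groups$outcome[i], predictor = groups$predictor[i],
      k = pr$k, r = pr$r, ci_lower = pr$ci_r[1], ci_upper = pr$ci_r[2],
      Q = pr$Q, tau2 = pr$tau2, zscore = pr$zscore, p = pr$p, i2 = pr$i2,
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows) > 0) do.call(rbind, rows)
         else data.frame(outcome = character(), predictor = character(),
                         k = integer(), r = numeric(), ci_lower = numeric(),
                         ci_upper = numeric(), Q = numeric(),
                         tau2 = numeric(), zscore = numeric(), p = numeric(),
                         i2 = numeric())
  out <- out[order(out$outcome, out$predictor, method = "radix"), ]
  rownames(out) <- NULL
  attr(out, "pools") <- pools
  out
}
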