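#' Egger regression test for small-study asymmetry
#'
#' Unweighted ordinary least squares of the standard normal deviate
#' `SND_i = z_i / se_i` on precision `1 / se_i`, with intercept. Under a
#' symmetric funnel the intercept is zero; a nonzero intercept signals
#' small-study asymmetry and possible publication bias (conventionally
#' flagged at `P < .10`). Coefficient standard errors are classical OLS;
#' p values and confidence intervals use the t distribution with `k - 2`
#' degrees of freedom.
#'
#' @param effects an `effect_points` data frame with at least 3 studies.
#' @param conf_level confidence level for the coefficient intervals.
#' @return an object of class `egger_result`: a list with `k`, `df`, and
#'   `coefficients`, a two-row data frame (`intercept`, `slope`) of
#'   `estimate`, `se`, `t`, `p`, `ci_lower`, `ci_upper`.
#' @export
egger_test <- function(effects, conf_level = 0.95) {
  k <- nrow(effects)
  if (k < 3) stop("egger_test: need at least 3 effects", call. = FALSE)
  if (any(effects$se_z <= 0)) {
    stop("egger_test: standard errors must be positive", call. = FALSE)
  }
  prec <- 1 / effects$se_z
  if (stats::var(prec) < .Machine$double.eps) {
    stop("egger_test: all precisions identical, design matrix singular",
         call. = FALSE)
  }
  snd <- effects$z / effects$se_z
  fit <- stats::lm(snd ~ prec)
  sm <- summary(fit)$coefficients
  df <- k - 2
  crit <- stats::qt(1 - (1 - conf_level) / 2, df)
  coefs <- data.frame(
    term = c("intercept", "slope"),
    estimate = sm[, "Estimate"],
    se = sm[, "Std. Error"],
    t = sm[, "t value"],
    p = 2 * stats::pt(-abs(sm[, "t value"]), df),
    ci_lower = sm[, "Estimate"] - crit * sm[, "Std. Error"],
    ci_upper = sm[, "Estimate"] + crit * sm[, "Std. Error"],
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(k = k, df = df, coefficients = coefs,
                 conf_level = conf_level),
            class = "egger_result")
}

#' @export
print.egger_result <- function(x, digits = 3, ...) {
  cat("Egger regression (SND on precision, unweighted OLS), k = ", x$k,
      ", df = ", x$df, "\n", sep = "")
  y <- x$coefficients
  for (col in c("estimate", "se", "t", "ci_lower", "ci_upper")) {
    y[[col]] <- formatC(y[[col]], format = "f", digits = digits)
  }
  y$p <- format_p(y$p)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Funnel-plot data
#'
#' Scatter of study effects against their standard errors around the pooled
#' estimate, with pseudo-confidence contours: at level `l` and standard
#' error `s` the contour spans `center +- qnorm(1 - (1 - l)/2) * s`, so the
#' half-width shrinks to zero as `s` does. The data structure is
#' orientation-free; the usual rendering puts the SE on the y axis
#' increasing downward.
#'
#' @param effects an `effect_points` data frame.
#' @param pooled a `pool_result` computed on the same effects; its random-
#'   effects estimate is the funnel center.
#' @param levels pseudo-confidence levels for the contours.
#' @param n_se number of SE grid points per contour.
#' @return an object of class `funnel_data`: list with `points` (one row
#'   per study: `dataset_id`, `z`, `se_z`), `center`, and `contours`
#'   (`level`, `se`, `lower`, `upper`).
#' @export
funnel_data <- function(effects, pooled, levels = c(0.95, 0.99),
                        n_se = 50) {
  stopifnot(inherits(pooled, "pool_result"))
  se_grid <- seq(0, max(effects$se_z), length.out = n_se)
  contours <- do.call(rbind, lapply(levels, function(l) {
    crit <- stats::qnorm(1 - (1 - l) / 2)
    data.frame(level = l, se = se_grid,
               lower = pooled$z_random - crit * se_grid,
               upper = pooled$z_random + crit * se_grid)
  }))
  structure(list(
    points = data.frame(
      dataset_id = if (!is.null(effects$dataset_id)) effects$dataset_id
                   else as.character(seq_len(nrow(effects))),
      z = effects$z, se_z = effects$se_z, stringsAsFactors = FALSE),
    center = pooled$z_random,
    contours = contours
  ), class = "funnel_data")
}

#' Duval-Tweedie trim-and-fill adjustment
#'
#' Estimates the number `k0` of studies presumed missing from one flank of
#' the funnel, trims the `k0` most extreme effects on the opposite flank,
#' iterates the center estimate until `k0` stabilizes, then imputes `k0`
#' mirror-image studies (`2 * center - z`, donor's SE) and re-pools the
#' augmented set with random effects (tau-squared re-estimated on the
#' augmented set) for the bias-adjusted estimate.
#'
#' @param effects an `effect_points` data frame with at least 3 studies.
#' @param side flank holding the surplus of extreme effects (the side that
#'   gets trimmed): `"auto"` (default) picks the flank by the sign of the
#'   Kendall rank correlation between centered effects and standard errors
#'   (a positive association - larger effects in smaller studies - implies
#'   suppression of small effects, i.e. a surplus on the right), `"right"`
#'   or `"left"`.
#' @param estimator `"L0"` (default, rank-sum based) or `"R0"` (rightmost-
#'   run based) missing-study estimator.
#' @param maxiter iteration cap; non-convergence is an error carrying the
#'   last iterate.
#' @param conf_level passed to the adjusted pooling.
#' @return an object of class `trimfill_result`: list with `k0`, `side`,
#'   `estimator`, `center` (the final trimmed fixed-effect center about
#'   which the mirror images are reflected), `adjusted` (a `pool_result`
#'   on observed + imputed
#'   effects), `unadjusted`, and `imputed` (the mirror-image effect rows,
#'   empty when `k0 = 0`, in which case the adjusted pooling equals the
#'   unadjusted one).
#' @export
trim_and_fill <- function(effects, side = c("auto", "right", "left"),
                          estimator = c("L0", "R0"), maxiter = 50L,
                          conf_level = 0.95) {
  side <- match.arg(side)
  estimator <- match.arg(estimator)
  k <- nrow(effects)
  if (k < 3) stop("trim_and_fill: need at least 3 effects", call. = FALSE)
  unadjusted <- pool_random(effects, conf_level = conf_level)

  if (side == "auto") {
    centered <- effects$z - unadjusted$z_fixed
    tau_cor <- suppressWarnings(
      stats::cor(centered, effects$se_z, method = "kendall"))
    side <- if (!is.na(tau_cor) && tau_cor < 0) "left" else "right"
  }
  # mirror so the surplus flank is always the right one internally
  flip <- if (side == "left") -1 else 1
  z <- flip * effects$z
  se <- effects$se_z

  est_k0 <- function(z_all, center, kk) {
    d <- z_all - center
    rk <- rank(abs(d), ties.method = "first")
    if (estimator == "L0") {
      t_n <- sum(rk[d > 0])
      (4 * t_n - kk * (kk + 1)) / (2 * kk - 1)
    } else {
      ord <- order(rk)                      # studies by |d| ascending
      signs <- d[ord] > 0
      gamma <- 0                            # rightmost run of positives
      for (i in rev(seq_along(signs))) {
        if (signs[i]) gamma <- gamma + 1 else break
      }
      gamma - 1
    }
  }

  fe_center <- function(zz, ss) {
    w <- 1 / ss^2
    sum(w * zz) / sum(w)
  }

  k0 <- 0L
  converged <- FALSE
  for (iter in seq_len(maxiter)) {
    keep <- seq_len(k - k0)                 # by ascending z: trim the top
    ord <- order(z)
    center <- fe_center(z[ord][keep], se[ord][keep])
    k0_new <- max(0L, min(k - 2L, as.integer(round(est_k0(z, center, k)))))
    if (k0_new == k0 && iter > 1) { converged <- TRUE; break }
    k0 <- k0_new
  }
  if (!converged && maxiter > 1) {
    stop("trim_and_fill: k0 did not stabilize after ", maxiter,
         " iterations (last iterate k0 = ", k0, ")", call. = FALSE)
  }

  if (k0 == 0) {
    imputed <- effects[0, , drop = FALSE]
    adjusted <- unadjusted
    center <- flip * fe_center(z, se)
  } else {
    ord <- order(z)
    trimmed_idx <- ord[(k - k0 + 1):k]
    center <- fe_center(z[ord][seq_len(k - k0)], se[ord][seq_len(k - k0)])
    imputed <- effects[trimmed_idx, , drop = FALSE]
    imputed$z <- flip * (2 * center - z[trimmed_idx])
    imputed$r <- tanh(imputed$z)
    imputed$dataset_id <- paste0("filled_", seq_len(k0))
    augmented <- rbind(as.data.frame(effects), as.data.frame(imputed))
    adjusted <- pool_random(as_effect_points(augmented),
                            conf_level = conf_level)
    center <- flip * center
  }
  structure(list(k0 = as.integer(k0), side = side, estimator = estimator,
                 center = center, adjusted = adjusted,
                 unadjusted = unadjusted, imputed = imputed),
            class = "trimfill_result")
}

#' @export
print.trimfill_result <- function(x, digits = 3, ...) {
  cat("Trim-and-fill (", x$estimator, ", surplus flank: ", x$side,
      "): k0 = ", x$k0, " imputed studies\n", sep = "")
  cat("  unadjusted pooled r = ",
      formatC(x$unadjusted$r, format = "f", digits = digits),
      ", adjusted pooled r = ",
      formatC(x$adjusted$r, format = "f", digits = digits), "\n", sep = "")
  invisible(x)
}
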