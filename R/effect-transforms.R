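#' Convert standardized beta coefficients to approximate correlations
#'
#' Uses the Peterson-Brown approximation `r = beta + 0.05 * lambda`. The
#' default applies `lambda = 1` to every coefficient, including negative
#' ones; set `negative_lambda_zero = TRUE` for the original Peterson-Brown
#' convention in which `lambda = 0` when `beta < 0`.
#'
#' @param beta numeric vector of standardized regression coefficients.
#' @param lambda conversion constant, 0 or 1 (default 1).
#' @param negative_lambda_zero apply `lambda = 0` to negative betas.
#' @return approximate correlation(s) in (-1, 1).
#' @details The conversion is affine, so differences in beta are preserved.
#'   A result at or beyond +-1 cannot be Fisher z-transformed; rather than
#'   silently clamping, the function stops and asks the caller to exclude or
#'   correct the offending coefficient (or to reconsider `lambda`).
#' @export
beta_to_r <- function(beta, lambda = 1, negative_lambda_zero = FALSE) {
  stopifnot(all(is.finite(beta)), length(lambda) == 1, lambda %in% c(0, 1))
  lam <- rep(lambda, length(beta))
  if (negative_lambda_zero) lam[beta < 0] <- 0
  r <- beta + 0.05 * lam
  if (any(abs(r) >= 1)) {
    stop("beta_to_r: converted correlation(s) at or beyond +-1 (beta = ",
         paste(beta[abs(r) >= 1], collapse = ", "),
         "); exclude or correct these coefficients rather than clamping",
         call. = FALSE)
  }
  r
}

#' Fisher z transform
#'
#' `z = atanh(r) = 0.5 * log((1 + r) / (1 - r))`, the variance-stabilizing
#' transform for correlation coefficients.
#'
#' @param r correlation(s), strictly inside (-1, 1).
#' @return Fisher z value(s).
#' @export
r_to_z <- function(r) {
  if (any(!is.finite(r) | abs(r) >= 1)) {
    stop("r_to_z: correlations must be finite and strictly inside (-1, 1)",
         call. = FALSE)
  }
  atanh(r)
}

#' Inverse Fisher z transform
#'
#' @param z finite Fisher z value(s).
#' @return correlation(s) `tanh(z)` in (-1, 1). Monotone, so transformed
#'   interval bounds keep their order.
#' @export
z_to_r <- function(z) {
  stopifnot(all(is.finite(z)))
  tanh(z)
}

#' Standard error of a Fisher z effect
#'
#' `se = 1 / sqrt(n - 3)`; strictly decreasing in the sample size.
#'
#' @param n sample size(s), at least 4.
#' @return standard error(s) on the z scale.
#' @export
se_of_z <- function(n) {
  if (any(!is.finite(n) | n < 4)) {
    stop("se_of_z: sample size must be at least 4 (se = 1/sqrt(n - 3))",
         call. = FALSE)
  }
  1 / sqrt(n - 3)
}

#' Build meta-analysis effect points from path records
#'
#' Converts each record's standardized beta to a correlation
#' ([beta_to_r()]), Fisher z-transforms it, and attaches the standard error
#' `1/sqrt(n - 3)`. Records without a usable beta are dropped (reported via
#' `message()`): they remain usable for weight analysis but cannot enter the
#' meta-analysis, so the two analyses may legitimately draw on different
#' record subsets.
#'
#' @param records a `path_records` data frame.
#' @param lambda,negative_lambda_zero passed to [beta_to_r()].
#' @param quiet suppress the dropped-record message.
#' @return an `effect_points` data frame with columns `dataset_id`,
#'   `predictor`, `outcome`, `r`, `z`, `se_z`, `n`, `significant`, `country`.
#' @export
effect_points <- function(records, lambda = 1, negative_lambda_zero = FALSE,
                          quiet = FALSE) {
  df <- as.data.frame(records)
  has_beta <- !is.na(df$beta)
  if (any(!has_beta) && !quiet) {
    message("effect_points: dropped ", sum(!has_beta),
            " record(s) without a usable beta")
  }
  df <- df[has_beta, , drop = FALSE]
  if (any(df$n < 4)) {
    stop("effect_points: sample size below 4 for dataset(s) ",
         paste(df$dataset_id[df$n < 4], collapse = ", "),
         "; the Fisher z standard error requires n - 3 > 0", call. = FALSE)
  }
  r <- beta_to_r(df$beta, lambda = lambda,
                 negative_lambda_zero = negative_lambda_zero)
  out <- data.frame(
    dataset_id = df$dataset_id,
    predictor = df$predictor,
    outcome = df$outcome,
    r = r,
    z = r_to_z(r),
    se_z = se_of_z(df$n),
    n = df$n,
    significant = df$significant,
    country = df$country,
    stringsAsFactors = FALSE
  )
  as_effect_points(out)
}

#' Assemble effect points from effects already on the Fisher z scale
#'
#' For inputs such as published per-study effect tables that report the
#' Fisher z effect directly. The standard error is recomputed from the exact
#' sample size as `1/sqrt(n - 3)` when `n` is available (`se_from_n = TRUE`,
#' the default), since a printed SE column is typically a rounded derivative
#' of `n`; set `se_from_n = FALSE` to keep a supplied `se_z` column.
#'
#' @param df data frame with columns `dataset_id`, `effect_z` (or `z`), and
#'   `n` and/or `se_z`; optional `significance`/`significant` and `country`.
#' @param se_from_n recompute `se_z` from `n`.
#' @return an `effect_points` data frame.
#' @export
effect_points_from_z <- function(df, se_from_n = TRUE) {
  z <- if ("effect_z" %in% names(df)) df$effect_z else df$z
  if (is.null(z)) stop("need an 'effect_z' or 'z' column", call. = FALSE)
  n <- if ("n" %in% names(df)) df$n else NA_integer_
  se <- if (se_from_n && !all(is.na(n))) se_of_z(n)
        else if ("se_z" %in% names(df)) df$se_z
        else stop("need 'n' or 'se_z' to form standard errors", call. = FALSE)
  sig <- if ("significant" %in% names(df)) df$significant
         else if ("significance" %in% names(df)) df$significance
         else NA
  if (!all(is.na(sig))) sig <- parse_significance(sig)
  out <- data.frame(
    dataset_id = if ("dataset_id" %in% names(df)) as.character(df$dataset_id)
                 else sprintf("s%02d", seq_along(z)),
    predictor = if ("predictor" %in% names(df)) df$predictor else NA_character_,
    outcome = if ("outcome" %in% names(df)) df$outcome else NA_character_,
    r = tanh(z),
    z = z,
    se_z = se,
    n = if (all(is.na(n))) NA_integer_ else as.integer(n),
    significant = sig,
    country = if ("country" %in% names(df)) as.character(df$country)
              else NA_character_,
    stringsAsFactors = FALSE
  )
  as_effect_points(out)
}

as_effect_points <- function(df) {
  stopifnot(is.data.frame(df), all(c("z", "se_z") %in% names(df)))
  if (any(!is.finite(df$z))) stop("non-finite Fisher z effect", call. = FALSE)
  if (any(!is.finite(df$se_z) | df$se_z <= 0)) {
    stop("standard errors must be finite and positive", call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- unique(c("effect_points", class(df)))
  df
}
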