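#' Weight of a predictor-outcome path
#'
#' The weight of a relationship is the fraction of examinations in which it
#' was found statistically significant, `W = S / E`. A weight of 1 means the
#' path was significant in every study that examined it; 0 means it never
#' was.
#'
#' @param S number of significant examinations (0 <= S <= E).
#' @param E total number of examinations (>= 1).
#' @return the weight(s), in full double precision (report-layer rounding to
#'   3 decimals is left to [weight_table()] printing).
#' @export
compute_weight <- function(S, E) {
  if (any(E < 1)) stop("compute_weight: E must be at least 1", call. = FALSE)
  if (any(S < 0 | S > E)) {
    stop("compute_weight: S must satisfy 0 <= S <= E", call. = FALSE)
  }
  S / E
}

#' Classify a predictor from its weight and examination count
#'
#' Thresholds (all boundaries inclusive):
#' * `best` - examined at least 5 times with a weight of 0.800 or higher;
#' * `promising` - examined fewer than 5 times with a perfect weight of 1;
#' * `well-utilized` - examined at least 5 times, weight below 0.800;
#' * `experimental` - the residual class (fewer than 5 examinations,
#'   weight below 1).
#'
#' @param W weight(s) in \[0, 1\].
#' @param E examination count(s), >= 1.
#' @return character vector of classification labels; a total function of
#'   `(W, E)`.
#' @export
classify_predictor <- function(W, E) {
  if (any(W < 0 | W > 1)) {
    stop("classify_predictor: W must lie in [0, 1]", call. = FALSE)
  }
  if (any(E < 1)) stop("classify_predictor: E must be at least 1",
                       call. = FALSE)
  perfect <- W >= 1 - 1e-12
  ifelse(E >= 5 & W >= 0.800, "best",
  ifelse(E < 5 & perfect, "promising",
  ifelse(E >= 5, "well-utilized", "experimental")))
}

#' Weight-analysis table over grouped paths
#'
#' One row per retained path with its significant count, nonsignificant
#' count, total, weight and classification, deterministically ordered by
#' `(outcome, predictor)`.
#'
#' @param groups a `path_groups` data frame from [group_paths()], already
#'   filtered by the minimum-examinations rule.
#' @return a `weight_table` data frame with columns `outcome`, `predictor`,
#'   `S`, `nonsignificant`, `E`, `W`, `classification`.
#' @export
weight_table <- function(groups) {
  df <- as.data.frame(groups)
  out <- data.frame(
    outcome = df$outcome,
    predictor = df$predictor,
    S = df$S,
    nonsignificant = df$E - df$S,
    E = df$E,
    W = compute_weight(df$S, df$E),
    stringsAsFactors = FALSE
  )
  out$classification <- classify_predictor(out$W, out$E)
  out <- out[order(out$outcome, out$predictor, method = "radix"), ]
  rownames(out) <- NULL
  class(out) <- c("weight_table", class(out))
  out
}

#' @export
print.weight_table <- function(x, digits = 3, ...) {
  y <- as.data.frame(x)
  y$W <- formatC(y$W, format = "f", digits = digits)
  cat("Weight analysis (", nrow(y), " paths)\n\n", sep = "")
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}
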