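#' Path to a packaged data file
#'
#' @param file file name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return full path (or a vector of file names).
#' @export
mw_extdata <- function(file = NULL) {
  dir <- system.file("extdata", package = "metaweight", mustWork = TRUE)
  if (is.null(file)) return(list.files(dir))
  path <- file.path(dir, file)
  if (!file.exists(path)) stop("no packaged file '", file, "'", call. = FALSE)
  path
}

#' Load the packaged 77-study effect table
#'
#' The published per-study Fisher z effects, sample sizes, significance
#' labels and countries for the performance-expectancy to
#' behavioral-intention path (32 studies from China, 45 from other
#' countries). Standard errors are recomputed from the exact sample sizes
#' as `1/sqrt(n - 3)` by default; the table's printed 3-decimal SE column is
#' available with `se_from_n = FALSE`.
#'
#' @param se_from_n passed to [effect_points_from_z()].
#' @return an `effect_points` data frame with 77 rows.
#' @export
read_effect_fixture <- function(se_from_n = TRUE) {
  df <- utils::read.csv(mw_extdata("table5_pe_bi.csv"),
                        stringsAsFactors = FALSE)
  df$predictor <- "performance expectancy"
  df$outcome <- "behavioral intention"
  effect_points_from_z(df, se_from_n = se_from_n)
}

#' Load the packaged per-path significance counts
#'
#' Significant / nonsignificant / total examination counts for the 67
#' relationships (across six outcome constructs) retained by the
#' three-examinations inclusion rule, together with the published weights
#' for comparison.
#'
#' @return a data frame with columns `outcome`, `predictor`, `significant`,
#'   `nonsignificant`, `total`, `weight`.
#' @export
read_count_fixture <- function() {
  utils::read.csv(mw_extdata("table3_counts.csv"), stringsAsFactors = FALSE)
}

#' Expand per-path counts into weight-only path records
#'
#' Reconstructs a corpus of path records from aggregated significant /
#' nonsignificant counts: each count becomes one record with the
#' appropriate significance label, a synthetic dataset id and no beta.
#' Such records support the weight analysis exactly (it depends only on
#' `S` and `E`) but are excluded from meta-analysis, which needs effect
#' sizes.
#'
#' @param counts a data frame as returned by [read_count_fixture()].
#' @param n_placeholder sample size attached to the synthetic records
#'   (irrelevant to weight analysis).
#' @return a `path_records` data frame with `sum(counts$total)` rows.
#' @export
records_from_counts <- function(counts, n_placeholder = 100L) {
  stopifnot(all(c("outcome", "predictor", "significant", "nonsignificant")
                %in% names(counts)))
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    s <- counts$significant[i]
    ns <- counts$nonsignificant[i]
    data.frame(
      dataset_id = sprintf("count%03d_%03d", i, seq_len(s + ns)),
      paper_id = NA_character_,
      country = NA_character_,
      predictor = counts$predictor[i],
      outcome = counts$outcome[i],
      beta = NA_real_,
      n = n_placeholder,
      significant = rep(c(TRUE, FALSE), c(s, ns)),
      theory_tags = NA_character_,
      stringsAsFactors = FALSE
    )
  })
  path_records(do.call(rbind, rows))
}
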