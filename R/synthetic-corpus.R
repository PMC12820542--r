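#' Specify a synthetic study corpus
#'
#' Describes the random-effects data-generating process the synthesis
#' assumes: a mean true correlation, between-study heterogeneity on the
#' Fisher z scale, per-study sample sizes, two-tailed significance
#' labelling, and an optional selective-publication mechanism that
#' suppresses nonsignificant studies. The defaults mirror the conditions of
#' the performance-expectancy to behavioral-intention evidence base: 77
#' studies, a true correlation of 0.34, between-study SD 0.25, and sample
#' sizes spanning 67 to 1292.
#'
#' @param true_r mean true correlation on the r scale, |true_r| < 1.
#' @param tau between-study SD on the Fisher z scale (>= 0).
#' @param n_studies number of studies generated before any suppression.
#' @param n_range integer (min, max) per-study sample size, min >= 10.
#' @param bias_prob probability in \[0, 1\] that a nonsignificant study is
#'   suppressed (never published); significant studies are never dropped.
#' @param group_specs optional list of `list(label =, true_r =, n_studies =)`
#'   entries for subgroup scenarios; when present, `true_r`/`n_studies` at
#'   the top level are ignored and records carry the group label as their
#'   country.
#' @param seed random seed recorded in the spec and used by
#'   [generate_corpus()].
#' @return a validated list of class `corpus_spec`.
#' @export
corpus_spec <- function(true_r = 0.34, tau = 0.25, n_studies = 77,
                        n_range = c(67, 1292), bias_prob = 0,
                        group_specs = NULL, seed = 1L) {
  spec <- list(true_r = true_r, tau = tau, n_studies = as.integer(n_studies),
               n_range = as.integer(n_range), bias_prob = bias_prob,
               group_specs = group_specs, seed = as.integer(seed))
  if (abs(true_r) >= 1) stop("corpus_spec: |true_r| must be < 1",
                             call. = FALSE)
  if (tau < 0) stop("corpus_spec: tau must be non-negative", call. = FALSE)
  if (length(n_range) != 2 || n_range[1] < 10 || n_range[2] < n_range[1]) {
    stop("corpus_spec: n_range must be (min, max) with min >= 10",
         call. = FALSE)
  }
  if (bias_prob < 0 || bias_prob > 1) {
    stop("corpus_spec: bias_prob must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(group_specs)) {
    for (g in group_specs) {
      if (!all(c("label", "true_r", "n_studies") %in% names(g))) {
        stop("corpus_spec: each group spec needs label, true_r, n_studies",
             call. = FALSE)
      }
    }
  }
  class(spec) <- "corpus_spec"
  spec
}

# run code under a seed without disturbing the caller's RNG stream
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Generate a synthetic study corpus
#'
#' For each study: a true Fisher z effect is drawn from
#' `Normal(atanh(true_r), tau^2)`; the sample size uniformly from
#' `n_range`; the observed effect from `Normal(z_i, 1/(n_i - 3))`; the
#' standardized beta is reconstructed by inverting the Peterson-Brown
#' conversion (`beta = tanh(z_obs) - 0.05`), so a round trip through
#' [beta_to_r()] is exact; the significance label is the two-tailed Fisher z
#' test at alpha = .05 (`|z_obs| * sqrt(n_i - 3) > 1.959964`), a stand-in
#' for the heterogeneous tests of primary studies that keeps statistical
#' power analytically checkable. With probability `bias_prob` a
#' nonsignificant study is suppressed. Identical spec and seed yield an
#' identical corpus.
#'
#' @param spec a [corpus_spec()].
#' @param predictor,outcome construct names attached to every record.
#' @return a `path_records` data frame; suppressed studies are absent.
#'   `attr(, "spec")` carries the generating spec.
#' @export
generate_corpus <- function(spec, predictor = "performance expectancy",
                            outcome = "behavioral intention") {
  stopifnot(inherits(spec, "corpus_spec"))
  groups <- spec$group_specs
  if (is.null(groups)) {
    groups <- list(list(label = "synthetic", true_r = spec$true_r,
                        n_studies = spec$n_studies))
  }
  records <- with_local_seed(spec$seed, {
    out <- list()
    idx <- 0L
    for (g in groups) {
      for (j in seq_len(g$n_studies)) {
        idx <- idx + 1L
        z_true <- stats::rnorm(1, atanh(g$true_r), spec$tau)
        n_i <- spec$n_range[1] + sample.int(spec$n_range[2] -
                                            spec$n_range[1] + 1L, 1L) - 1L
        se_i <- 1 / sqrt(n_i - 3)
        z_obs <- stats::rnorm(1, z_true, se_i)
        sig <- abs(z_obs) / se_i > 1.959964
        if (!sig && spec$bias_prob > 0 &&
            stats::runif(1) < spec$bias_prob) {
          next  # suppressed: nonsignificant result never published
        }
        out[[length(out) + 1L]] <- data.frame(
          dataset_id = sprintf("sim%04d", idx),
          paper_id = sprintf("paper%04d", idx),
          country = g$label,
          predictor = predictor,
          outcome = outcome,
          beta = tanh(z_obs) - 0.05,
          n = n_i,
          significant = sig,
          theory_tags = NA_character_,
          stringsAsFactors = FALSE
        )
      }
    }
    do.call(rbind, out)
  })
  if (is.null(records)) {
    stop("generate_corpus: every study was suppressed; lower bias_prob",
         call. = FALSE)
  }
  records <- suppressWarnings(path_records(records))
  attr(records, "spec") <- spec
  records
}

#' Generate a multi-path corpus over a theory's edges
#'
#' Concatenates per-edge corpora so that grouped weight analysis, pooling
#' and theory-graph construction can be exercised end to end on constructs
#' from the packaged technology-acceptance vocabulary.
#'
#' @param edge_specs list of `list(predictor =, outcome =, true_r =,
#'   n_studies =)` entries, each with `n_studies >= 3`; duplicate
#'   (predictor, outcome) pairs are a configuration error.
#' @param spec a [corpus_spec()] providing tau, n_range, bias_prob and the
#'   seed (per-edge streams are derived deterministically from it).
#' @return a `path_records` data frame covering all edges.
#' @export
generate_theory_corpus <- function(edge_specs, spec = corpus_spec()) {
  stopifnot(inherits(spec, "corpus_spec"), length(edge_specs) > 0)
  keys <- vapply(edge_specs, function(e) paste(e$predictor, e$outcome,
                                               sep = "->"), character(1))
  if (anyDuplicated(keys)) {
    stop("generate_theory_corpus: duplicate edge spec(s): ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "),
         call. = FALSE)
  }
  parts <- lapply(seq_along(edge_specs), function(i) {
    e <- edge_specs[[i]]
    if (is.null(e$n_studies) || e$n_studies < 3) {
      stop("generate_theory_corpus: each edge needs n_studies >= 3",
           call. = FALSE)
    }
    sub <- corpus_spec(true_r = e$true_r, tau = spec$tau,
                       n_studies = e$n_studies, n_range = spec$n_range,
                       bias_prob = spec$bias_prob,
                       seed = (spec$seed + 7919L * i) %% .Machine$integer.max)
    recs <- generate_corpus(sub, predictor = e$predictor,
                            outcome = e$outcome)
    recs$dataset_id <- sprintf("edge%02d_%s", i, recs$dataset_id)
    recs$paper_id <- sprintf("edge%02d_%s", i, recs$paper_id)
    as.data.frame(recs)
  })
  out <- suppressWarnings(path_records(do.call(rbind, parts)))
  attr(out, "spec") <- spec
  out
}
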