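#' Configuration for a full synthesis run
#'
#' Bundles the file locations and analysis parameters of
#' [run_full_analysis()]. All defaults reproduce the reference analysis:
#' three-examination inclusion, 95% normal-theory intervals, Peterson-Brown
#' conversion with `lambda = 1` for all betas, Egger asymmetry flagged at
#' `P < .10`, L0 trim-and-fill, and a China-versus-rest subgroup split.
#'
#' @param records path to the path-records CSV (see [read_path_records()]).
#' @param merge_map optional path to a construct-alias merge map CSV.
#' @param out_dir output directory (created if absent).
#' @param min_examinations inclusion rule for grouping (default 3).
#' @param conf_level confidence level (default 0.95).
#' @param lambda Peterson-Brown constant (default 1).
#' @param negative_lambda_zero use `lambda = 0` for negative betas.
#' @param egger_alpha significance threshold on the Egger intercept used to
#'   flag asymmetry (default 0.10).
#' @param estimator trim-and-fill estimator, `"L0"` or `"R0"`.
#' @param subgroup_country country contrasted against all others in the
#'   subgroup analysis (default `"China"`).
#' @param bias_path `c(predictor, outcome)` naming the path for the
#'   publication-bias workup; default `NULL` picks the path with the most
#'   pooled effects.
#' @param columns optional column mapping for [read_path_records()].
#' @param seed seed for any stochastic reporting.
#' @return a list of class `run_config`.
#' @export
run_config <- function(records, merge_map = NULL, out_dir = "metaweight-out",
                       min_examinations = 3, conf_level = 0.95, lambda = 1,
                       negative_lambda_zero = FALSE, egger_alpha = 0.10,
                       estimator = c("L0", "R0"), subgroup_country = "China",
                       bias_path = NULL, columns = NULL, seed = 1L) {
  structure(list(records = records, merge_map = merge_map, out_dir = out_dir,
                 min_examinations = min_examinations,
                 conf_level = conf_level, lambda = lambda,
                 negative_lambda_zero = negative_lambda_zero,
                 egger_alpha = egger_alpha,
                 estimator = match.arg(estimator),
                 subgroup_country = subgroup_country, bias_path = bias_path,
                 columns = columns, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full weight + meta-analysis pipeline
#'
#' Orchestrates every stage on one corpus: read and harmonize records,
#' group paths under the inclusion rule, weight analysis, per-path
#' random-effects pooling with per-study contributions, Egger regression,
#' funnel data and trim-and-fill on the bias path, country subgroup
#' pooling, theory graphs for every packaged vocabulary entry, and a
#' machine-readable manifest (configuration, package version, output
#' checksums). Stage outputs are pure functions of the input files and the
#' configuration; the manifest's checksums make this assertable.
#'
#' @param config a [run_config()].
#' @param quiet suppress per-stage progress messages.
#' @return invisibly, a list with the in-memory stage results (`records`,
#'   `groups`, `weights`, `meta`, `egger`, `trimfill`, `funnel`,
#'   `subgroups`, `graphs`, `manifest`). Files are written under
#'   `config$out_dir`.
#' @export
run_full_analysis <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message("[metaweight] ", ...)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outfile <- function(f) file.path(config$out_dir, f)

  records <- read_path_records(config$records, columns = config$columns)
  say("read ", nrow(records), " path records")
  if (!is.null(config$merge_map)) {
    records <- canonicalize(records, read_merge_map(config$merge_map),
                            quiet = quiet)
    say("harmonized construct names")
  }
  groups <- group_paths(records, config$min_examinations, quiet = quiet)
  say(nrow(groups), " paths retained (>= ", config$min_examinations,
      " examinations), ", nrow(attr(groups, "excluded")), " excluded")

  weights <- weight_table(groups)
  utils::write.csv(as.data.frame(weights), outfile("weights.csv"),
                   row.names = FALSE)

  meta <- pool_paths(groups, lambda = config$lambda,
                     negative_lambda_zero = config$negative_lambda_zero,
                     conf_level = config$conf_level, quiet = quiet)
  utils::write.csv(meta, outfile("meta.csv"), row.names = FALSE)
  pools <- attr(meta, "pools")
  contrib <- do.call(rbind, lapply(names(pools), function(key) {
    cbind(path = key, pools[[key]]$contributions)
  }))
  if (!is.null(contrib)) {
    utils::write.csv(contrib, outfile("contributions.csv"),
                     row.names = FALSE)
  }
  say("pooled ", nrow(meta), " paths")

  # publication-bias workup on the most-examined pooled path
  egger <- trimfill <- funnel <- subgroups <- NULL
  bias_key <- NULL
  if (nrow(meta) > 0) {
    bias_key <- if (!is.null(config$bias_path)) {
      paste(config$bias_path[2], config$bias_path[1], sep = "|")
    } else {
      paste(meta$outcome, meta$predictor, sep = "|")[which.max(meta$k)]
    }
    if (!bias_key %in% names(pools)) {
      stop("bias stage: path '", bias_key, "' was not pooled", call. = FALSE)
    }
    gi <- match(bias_key, paste(groups$outcome, groups$predictor, sep = "|"))
    ep <- effect_points(path_records(groups$records[[gi]]),
                        lambda = config$lambda,
                        negative_lambda_zero = config$negative_lambda_zero,
                        quiet = TRUE)
    pooled <- pools[[bias_key]]
    if (nrow(ep) >= 3) {
      egger <- egger_test(ep, conf_level = config$conf_level)
      trimfill <- trim_and_fill(ep, estimator = config$estimator,
                                conf_level = config$conf_level)
      funnel <- funnel_data(ep, pooled)
      utils::write.csv(funnel$points, outfile("funnel_points.csv"),
                       row.names = FALSE)
      utils::write.csv(funnel$contours, outfile("funnel_contours.csv"),
                       row.names = FALSE)
      bias_json <- list(
        path = bias_key,
        egger = c(list(k = egger$k, df = egger$df,
                       asymmetry_flagged =
                         egger$coefficients$p[1] < config$egger_alpha),
                  list(coefficients = egger$coefficients)),
        trim_and_fill = list(k0 = trimfill$k0, side = trimfill$side,
                             estimator = trimfill$estimator,
                             r_unadjusted = trimfill$unadjusted$r,
                             r_adjusted = trimfill$adjusted$r)
      )
      jsonlite::write_json(bias_json, outfile("bias.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      say("bias diagnostics on ", bias_key, ": Egger intercept p = ",
          format_p(egger$coefficients$p[1]), ", trim-and-fill k0 = ",
          trimfill$k0)
    }
    country <- ep$country
    split_ok <- !all(is.na(country)) &&
      sum(country == config$subgroup_country, na.rm = TRUE) >= 2 &&
      sum(country != config$subgroup_country, na.rm = TRUE) >= 2
    if (split_ok) {
      labels <- ifelse(country == config$subgroup_country,
                       config$subgroup_country, "Other countries")
      subgroups <- pool_subgroups(ep, labels,
                                  conf_level = config$conf_level)
      sub_df <- do.call(rbind, lapply(names(subgroups), function(gl) {
        pr <- subgroups[[gl]]
        data.frame(subgroup = gl, k = pr$k, r = pr$r,
                   ci_lower = pr$ci_r[1], ci_upper = pr$ci_r[2], p = pr$p,
                   i2 = pr$i2, stringsAsFactors = FALSE)
      }))
      utils::write.csv(sub_df, outfile("subgroups.csv"), row.names = FALSE)
      say("subgroup analysis (", config$subgroup_country, " vs rest) on ",
          bias_key)
    }
  }

  graphs <- list()
  vocab <- theory_vocab()
  for (th in names(vocab)) {
    g <- suppressWarnings(
      build_theory_graph(th, weights, meta, vocab = vocab))
    graphs[[th]] <- g
    safe <- gsub("[^A-Za-z0-9]+", "_", th)
    export_graph(g, "dot", outfile(paste0("graph_", safe, ".dot")))
    export_graph(g, "json", outfile(paste0("graph_", safe, ".json")))
  }
  say("exported ", length(graphs), " theory graphs")

  outputs <- list.files(config$out_dir, full.names = TRUE)
  outputs <- outputs[basename(outputs) != "manifest.json"]
  manifest <- list(
    package = "metaweight",
    version = as.character(utils::packageVersion("metaweight")),
    config = unclass(config),
    n_records = nrow(records),
    n_paths_retained = nrow(groups),
    n_paths_excluded = nrow(attr(groups, "excluded")),
    n_paths_pooled = nrow(meta),
    bias_path = bias_key,
    checksums = as.list(tools::md5sum(sort(outputs))[basename(sort(outputs))])
  )
  names(manifest$checksums) <- basename(sort(outputs))
  jsonlite::write_json(manifest, outfile("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  say("wrote manifest with ", length(manifest$checksums), " checksums")

  invisible(list(records = records, groups = groups, weights = weights,
                 meta = meta, egger = egger, trimfill = trimfill,
                 funnel = funnel, subgroups = subgroups, graphs = graphs,
                 manifest = manifest))
}
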