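#' Read study-level path records from a CSV file
#'
#' A path record is one examined predictor -> outcome relationship from one
#' dataset of a primary study: the standardized regression coefficient (beta),
#' the sample size, the significance label the primary authors reported, and
#' bookkeeping columns. Records are the long-format input of the whole
#' pipeline: weight analysis consumes the significance labels, the
#' meta-analysis consumes beta and n.
#'
#' @param source path to a comma-separated, UTF-8 encoded file with a header
#'   row, or a connection.
#' @param columns named character vector mapping the standard column names
#'   (`dataset_id`, `predictor`, `outcome`, `n`, `significant`, and optionally
#'   `beta`, `country`, `paper_id`, `theory_tags`) to the names used in the
#'   file. Defaults to the identity mapping.
#' @return A `path_records` data frame with columns `dataset_id`, `paper_id`,
#'   `country`, `predictor`, `outcome`, `beta`, `n`, `significant`,
#'   `theory_tags`. Missing beta values are `NA`, never zero. Multi-country
#'   datasets should carry the single reserved country label `"multiple"`.
#' @details Significance labels are parsed case-insensitively from
#'   `significant`/`nonsignificant` or `1`/`0`; any other value is a row-level
#'   parse error. Duplicate `(dataset_id, predictor, outcome)` triples are
#'   rejected: within a corpus one dataset examines a path at most once.
#'   Standardized coefficients occasionally exceed 1 in primary studies, but
#'   `|beta| > 1.2` is flagged with a warning as a likely transcription error.
#' @seealso [write_path_records()], [canonicalize()], [group_paths()]
#' @export
read_path_records <- function(source, columns = NULL) {
  raw <- utils::read.csv(source, stringsAsFactors = FALSE,
                         check.names = FALSE, fileEncoding = "UTF-8")
  std <- c("dataset_id", "paper_id", "country", "predictor", "outcome",
           "beta", "n", "significant", "theory_tags")
  map <- stats::setNames(std, std)
  if (!is.null(columns)) {
    stopifnot(is.character(columns), !is.null(names(columns)))
    map[names(columns)] <- columns
  }
  mandatory <- c("dataset_id", "predictor", "outcome", "n", "significant")
  for (col in mandatory) {
    file_col <- map[[col]]
    # accept the bare label "significance" as a courtesy alias
    if (col == "significant" && !file_col %in% names(raw) &&
        "significance" %in% names(raw)) {
      map[[col]] <- file_col <- "significance"
    }
    if (!file_col %in% names(raw)) {
      stop("missing mandatory column '", file_col, "' in path records file",
           call. = FALSE)
    }
  }
  n_raw <- raw[[map[["n"]]]]
  n_num <- suppressWarnings(as.numeric(n_raw))
  bad_n <- which(is.na(n_num) | n_num <= 0 | n_num != round(n_num))
  if (length(bad_n) > 0) {
    stop("non-numeric or non-positive sample size in row(s) ",
         paste(bad_n, collapse = ", "), " (column '", map[["n"]], "')",
         call. = FALSE)
  }
  sig <- parse_significance(raw[[map[["significant"]]]])

  get_opt <- function(col, default) {
    fc <- map[[col]]
    if (fc %in% names(raw)) raw[[fc]] else rep(default, nrow(raw))
  }
  beta_raw <- get_opt("beta", NA)
  beta <- suppressWarnings(as.numeric(beta_raw))
  supplied <- !(is.na(beta_raw) | trimws(as.character(beta_raw)) == "")
  if (any(is.na(beta) & supplied)) {
    stop("non-numeric beta in row(s) ",
         paste(which(is.na(beta) & supplied), collapse = ", "), call. = FALSE)
  }
  blank2na <- function(x) {
    x <- as.character(x)
    x[!is.na(x) & trimws(x) == ""] <- NA_character_
    x
  }
  out <- data.frame(
    dataset_id = as.character(raw[[map[["dataset_id"]]]]),
    paper_id   = blank2na(get_opt("paper_id", NA_character_)),
    country    = blank2na(get_opt("country", NA_character_)),
    predictor  = as.character(raw[[map[["predictor"]]]]),
    outcome    = as.character(raw[[map[["outcome"]]]]),
    beta       = beta,
    n          = as.integer(n_num),
    significant = sig,
    theory_tags = blank2na(get_opt("theory_tags", NA_character_)),
    stringsAsFactors = FALSE
  )
  path_records(out)
}

#' Construct and validate a path-records data frame
#'
#' @param df a data frame carrying at least `dataset_id`, `predictor`,
#'   `outcome`, `n`, `significant`; `beta`, `country`, `paper_id` and
#'   `theory_tags` are filled with `NA` when absent.
#' @return the validated data frame with class `path_records`.
#' @export
path_records <- function(df) {
  stopifnot(is.data.frame(df))
  needed <- c("dataset_id", "predictor", "outcome", "n", "significant")
  miss <- setdiff(needed, names(df))
  if (length(miss) > 0) {
    stop("path records lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("paper_id", "country", "theory_tags")) {
    if (!col %in% names(df)) df[[col]] <- NA_character_
    df[[col]] <- as.character(df[[col]])
  }
  if (!"beta" %in% names(df)) df$beta <- NA_real_
  df$beta <- as.numeric(df$beta)
  df$n <- as.integer(df$n)
  key <- paste(df$dataset_id, df$predictor, df$outcome, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- df[duplicated(key), c("dataset_id", "predictor", "outcome")]
    stop("duplicate (dataset_id, predictor, outcome) record(s): ",
         paste(unique(sprintf("%s: %s -> %s", dup$dataset_id, dup$predictor,
                              dup$outcome)), collapse = "; "), call. = FALSE)
  }
  if (!is.logical(df$significant)) {
    df$significant <- parse_significance(df$significant)
  }
  if (any(!is.na(df$beta) & !is.finite(df$beta))) {
    stop("non-finite beta value(s) in path records", call. = FALSE)
  }
  big <- !is.na(df$beta) & abs(df$beta) > 1.2
  if (any(big)) {
    warning("|beta| > 1.2 in dataset(s) ",
            paste(df$dataset_id[big], collapse = ", "),
            "; standardized coefficients this large usually indicate a ",
            "transcription error", call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- unique(c("path_records", class(df)))
  df
}

parse_significance <- function(x) {
  if (is.logical(x)) return(x)
  lab <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(lab))
  out[lab %in% c("significant", "1", "true")] <- TRUE
  out[lab %in% c("nonsignificant", "non-significant", "0", "false")] <- FALSE
  if (anyNA(out)) {
    stop("unparseable significance label(s) in row(s) ",
         paste(which(is.na(out)), collapse = ", "),
         " (expected 'significant'/'nonsignificant' or 1/0)", call. = FALSE)
  }
  out
}

#' Write path records back to CSV
#'
#' Inverse of [read_path_records()]: a read/write round trip preserves all
#' field values (beta to the precision of the input decimals).
#'
#' @param records a `path_records` data frame.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_path_records <- function(records, file) {
  df <- as.data.frame(records)
  df$significant <- ifelse(df$significant, "significant", "nonsignificant")
  utils::write.csv(df, file, row.names = FALSE, na = "", quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(file)
}

#' Read a construct-alias merge map
#'
#' Primary studies name the same construct differently (e.g. "perceived
#' usefulness" for performance expectancy); a merge map lists `alias ->
#' canonical` pairs used to harmonize names before grouping. The mapping is
#' many-to-one: aliases must be unique, canonical names may repeat.
#'
#' @param source CSV path or connection with columns `alias`, `canonical`.
#' @return a data frame with columns `alias`, `canonical`.
#' @export
read_merge_map <- function(source) {
  mm <- utils::read.csv(source, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  if (!all(c("alias", "canonical") %in% names(mm))) {
    stop("merge map needs columns 'alias' and 'canonical'", call. = FALSE)
  }
  validate_merge_map(mm[c("alias", "canonical")])
}

validate_merge_map <- function(map) {
  stopifnot(is.data.frame(map), all(c("alias", "canonical") %in% names(map)))
  map$alias <- trimws(as.character(map$alias))
  map$canonical <- trimws(as.character(map$canonical))
  dup <- unique(map$alias[duplicated(map$alias)])
  # an alias repeated with the same canonical is harmless; two targets is not
  for (a in dup) {
    tg <- unique(map$canonical[map$alias == a])
    if (length(tg) > 1) {
      stop("alias '", a, "' maps to multiple canonicals: ",
           paste(tg, collapse = ", "), call. = FALSE)
    }
  }
  unique(map)
}

#' Harmonize construct names with a merge map
#'
#' Replaces every predictor and outcome name that matches an alias by its
#' canonical name. Replacement is single-pass: a chain `a -> b` with `b`
#' itself an alias elsewhere is *not* resolved transitively, so merge maps
#' must be written in canonical-target form. Unmatched names pass through
#' unchanged (reported via `message()`); the record count never changes.
#' Applying the same map twice therefore equals applying it once, provided
#' the map has no chains.
#'
#' @param records a `path_records` data frame.
#' @param map a merge map data frame (`alias`, `canonical`), e.g. from
#'   [read_merge_map()].
#' @param quiet suppress the unmatched-name message.
#' @return the records with harmonized `predictor`/`outcome` names.
#' @export
canonicalize <- function(records, map, quiet = FALSE) {
  map <- validate_merge_map(map)
  if (nrow(map) == 0) return(records)
  lookup <- stats::setNames(map$canonical, map$alias)
  swap <- function(x) {
    hit <- x %in% names(lookup)
    x[hit] <- unname(lookup[x[hit]])
    x
  }
  unmatched <- setdiff(unique(c(records$predictor, records$outcome)),
                       c(names(lookup), unname(lookup)))
  if (length(unmatched) > 0 && !quiet) {
    message("canonicalize: ", length(unmatched),
            " construct name(s) not in the merge map pass through unchanged")
  }
  records$predictor <- swap(records$predictor)
  records$outcome <- swap(records$outcome)
  path_records(as.data.frame(records))
}

#' Group path records by (predictor, outcome) and apply the inclusion rule
#'
#' Synthesis is restricted to relationships investigated at least
#' `min_examinations` times (default 3, the usual weight-analysis inclusion
#' rule). Each retained group carries `S`, the number of records labelled
#' significant, and `E`, the total number of examinations.
#'
#' @param records a `path_records` data frame.
#' @param min_examinations minimum number of examinations for a path to be
#'   retained (>= 1).
#' @param quiet suppress the exclusion message.
#' @return a `path_groups` data frame with columns `outcome`, `predictor`,
#'   `S`, `E` and a list-column `records` holding each group's rows, ordered
#'   by `(outcome, predictor)`. Excluded groups (E below the threshold) are
#'   attached as `attr(, "excluded")` with their counts, so that the sum of
#'   `E` over emitted and excluded groups equals the input record count.
#' @export
group_paths <- function(records, min_examinations = 3, quiet = FALSE) {
  stopifnot(min_examinations >= 1)
  if (nrow(records) == 0) {
    out <- data.frame(outcome = character(), predictor = character(),
                      S = integer(), E = integer())
    out$records <- list()
    attr(out, "excluded") <- out[0, c("outcome", "predictor", "S", "E")]
    class(out) <- c("path_groups", class(out))
    return(out)
  }
  key <- interaction(records$outcome, records$predictor, drop = TRUE,
                     sep = "\r")
  pieces <- split(as.data.frame(records), key)
  grp <- data.frame(
    outcome = vapply(pieces, function(p) p$outcome[1], character(1)),
    predictor = vapply(pieces, function(p) p$predictor[1], character(1)),
    S = vapply(pieces, function(p) sum(p$significant), integer(1)),
    E = vapply(pieces, nrow, integer(1)),
    stringsAsFactors = FALSE
  )
  grp$records <- unname(pieces)
  ord <- order(grp$outcome, grp$predictor, method = "radix")
  grp <- grp[ord, ]
  keep <- grp$E >= min_examinations
  excluded <- grp[!keep, c("outcome", "predictor", "S", "E")]
  rownames(excluded) <- NULL
  if (nrow(excluded) > 0 && !quiet) {
    message("group_paths: excluded ", nrow(excluded), " path(s) examined ",
            "fewer than ", min_examinations, " times (",
            sum(excluded$E), " records)")
  }
  out <- grp[keep, ]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  class(out) <- c("path_groups", class(out))
  out
}
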