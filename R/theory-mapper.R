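#' Packaged theory vocabularies
#'
#' The construct-level path structure of the adoption models covered by the
#' synthesis (TAM, UTAUT, HBM+PMT, TTF, PCT, TPB, DOI), stored as an
#' editable JSON configuration: data, not code.
#'
#' @param file optional path to an alternative vocabulary file.
#' @return named list; each theory holds a `label` and an `edges` list of
#'   `(predictor, outcome)` pairs.
#' @export
theory_vocab <- function(file = NULL) {
  if (is.null(file)) file <- mw_extdata("theory_vocab.json")
  jsonlite::fromJSON(file, simplifyVector = FALSE)
}

#' Build an adoption-model graph from weight and meta-analysis results
#'
#' Combines the two syntheses into one annotated graph: constructs are
#' nodes; each theoretical path found in the results becomes an edge
#' carrying the weight `W`, the examination count `E`, the pooled
#' back-transformed effect `r` and its p value. An edge is drawn thick when
#' `W >= 0.700` (boundary inclusive) and flagged significant when
#' `p < .05`. Paths present only in the weight results (no usable effect
#' sizes anywhere) keep their weight but have `r`/`p` absent and are marked
#' `weight_only` (rendered dashed, without a numeric label). Paths absent
#' from both result sets are omitted with a warning.
#'
#' @param theory theory key in the vocabulary (e.g. `"TAM"`), or a list
#'   with `label` and `edges` in the same layout.
#' @param weights a `weight_table` data frame.
#' @param pools a pooled-paths data frame from [pool_paths()] (columns
#'   `outcome`, `predictor`, `r`, `p`), or `NULL` for weight-only graphs.
#' @param vocab vocabulary list, defaults to [theory_vocab()].
#' @return an object of class `theory_graph`: list with `name`, `label`,
#'   `nodes` (every construct named by the theory's edge list) and `edges`
#'   (data frame: `predictor`, `outcome`, `W`, `E`, `r`, `p`, `thick`,
#'   `significant`, `weight_only`).
#' @export
build_theory_graph <- function(theory, weights, pools = NULL,
                               vocab = theory_vocab()) {
  if (is.character(theory)) {
    if (!theory %in% names(vocab)) {
      stop("unknown theory '", theory, "'; vocabulary has: ",
           paste(names(vocab), collapse = ", "), call. = FALSE)
    }
    spec <- vocab[[theory]]
    name <- theory
  } else {
    spec <- theory
    name <- spec$name %||% spec$label
  }
  edge_list <- lapply(spec$edges, unlist)
  nodes <- sort(unique(unlist(edge_list)))
  wkey <- paste(weights$predictor, weights$outcome, sep = "\r")
  pkey <- if (!is.null(pools)) paste(pools$predictor, pools$outcome,
                                     sep = "\r") else character()
  rows <- list()
  for (e in edge_list) {
    key <- paste(e[1], e[2], sep = "\r")
    wi <- match(key, wkey)
    pi <- match(key, pkey)
    if (is.na(wi) && is.na(pi)) {
      warning("theory path ", e[1], " -> ", e[2],
              " absent from both result sets; edge omitted", call. = FALSE)
      next
    }
    W <- if (!is.na(wi)) weights$W[wi] else NA_real_
    E <- if (!is.na(wi)) weights$E[wi] else NA_integer_
    r <- if (!is.na(pi)) pools$r[pi] else NA_real_
    p <- if (!is.na(pi)) pools$p[pi] else NA_real_
    rows[[key]] <- data.frame(
      predictor = e[1], outcome = e[2], W = W, E = E, r = r, p = p,
      thick = !is.na(W) && W >= 0.700,
      significant = if (!is.na(p)) p < 0.05 else NA,
      weight_only = is.na(pi),
      stringsAsFactors = FALSE
    )
  }
  edges <- if (length(rows) > 0) do.call(rbind, rows)
           else data.frame(predictor = character(), outcome = character(),
                           W = numeric(), E = integer(), r = numeric(),
                           p = numeric(), thick = logical(),
                           significant = logical(), weight_only = logical())
  edges <- edges[order(edges$predictor, edges$outcome, method = "radix"), ]
  rownames(edges) <- NULL
  structure(list(name = name, label = spec$label %||% name, nodes = nodes,
                 edges = edges),
            class = "theory_graph")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a theory graph
#'
#' Deterministic export in two formats. `"dot"` writes a Graphviz digraph
#' whose pen width grows with the weight (`1 + 3 W`), dashing weight-only
#' edges and labelling the rest with the pooled effect and p value.
#' `"json"` writes a structured record that [import_graph()] reads back to
#' an identical graph. Identical graphs serialize to identical bytes.
#'
#' @param graph a `theory_graph`.
#' @param format `"dot"` or `"json"`.
#' @param file optional output path; the serialized text is returned either
#'   way.
#' @return the serialized document as a character scalar (invisibly when
#'   written to `file`).
#' @export
export_graph <- function(graph, format = c("dot", "json"), file = NULL) {
  stopifnot(inherits(graph, "theory_graph"))
  format <- match.arg(format)
  txt <- if (format == "dot") graph_to_dot(graph) else graph_to_json(graph)
  if (!is.null(file)) {
    writeLines(txt, file, useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}

graph_to_dot <- function(graph) {
  q <- function(x) paste0("\"", gsub("\"", "\\\\\"", x), "\"")
  lines <- c(sprintf("digraph %s {", q(graph$name)),
             sprintf("  label=%s;", q(graph$label)),
             "  rankdir=LR;",
             sprintf("  %s;", q(graph$nodes)))
  e <- graph$edges
  for (i in seq_len(nrow(e))) {
    attrs <- c(sprintf("penwidth=%.3f", 1 + 3 * (e$W[i] %|NA|% 0)))
    if (e$weight_only[i]) {
      attrs <- c(attrs, "style=dashed")
    } else {
      attrs <- c(attrs, sprintf("label=%s",
                 q(sprintf("r=%.3f, P%s", e$r[i],
                           ifelse(e$p[i] < 0.001, "<.001",
                                  paste0("=", format_p(e$p[i], 2)))))))
    }
    if (isTRUE(e$thick[i])) attrs <- c(attrs, "color=black")
    else attrs <- c(attrs, "color=gray50")
    lines <- c(lines, sprintf("  %s -> %s [%s];", q(e$predictor[i]),
                              q(e$outcome[i]), paste(attrs, collapse = ", ")))
  }
  paste(c(lines, "}"), collapse = "\n")
}

`%|NA|%` <- function(a, b) ifelse(is.na(a), b, a)

graph_to_json <- function(graph) {
  jsonlite::toJSON(list(name = graph$name, label = graph$label,
                        nodes = graph$nodes, edges = graph$edges),
                   auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
}

#' Read a JSON-serialized theory graph back
#'
#' Inverse of `export_graph(format = "json")`.
#'
#' @param file path to (or literal text of) the JSON export.
#' @return a `theory_graph`.
#' @export
import_graph <- function(file) {
  obj <- jsonlite::fromJSON(file, simplifyDataFrame = TRUE)
  edges <- as.data.frame(obj$edges)
  if (nrow(edges) > 0) {
    edges$E <- as.integer(edges$E)
  }
  structure(list(name = obj$name, label = obj$label,
                 nodes = as.character(obj$nodes), edges = edges),
            class = "theory_graph")
}

#' @export
print.theory_graph <- function(x, ...) {
  cat("Theory graph: ", x$label, " (", length(x$nodes), " nodes, ",
      nrow(x$edges), " edges)\n", sep = "")
  if (nrow(x$edges) > 0) print.data.frame(x$edges, row.names = FALSE)
  invisible(x)
}
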