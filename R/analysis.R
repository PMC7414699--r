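#' End-to-end path-specific effect analysis
#'
#' Enumerates every directed path from `source` to `sink`, runs the chosen
#' two-group test on each, and (optionally) writes a results TSV with one
#' row per path plus a JSON provenance sidecar (seed, B, configuration hash)
#' sufficient to reproduce the output byte-for-byte.
#'
#' @param graph a `causal_dag`, or path to an edge-list file for
#'   [read_graph()].
#' @param data a data frame, or path to a CSV/TSV file with a header; column
#'   names must match graph node names exactly (case-sensitive).
#' @param group name of the binary group column.
#' @param source,sink exposure and outcome node names.
#' @param test `"permutation"` or a bootstrap CI method (`"normal"`,
#'   `"basic"`, `"percentile"`, `"bca"`).
#' @param labels optional group labels `c(g0, g1)`.
#' @param B resamples for the test.
#' @param alpha rejection level.
#' @param seed integer root seed (per-path seeds are derived from it).
#' @param adjust_extra character vector of global covariate columns (for
#'   example age and sex analogues) appended to every edge's adjustment set.
#' @param out optional output TSV path; a sidecar `<out>.json` is written
#'   next to it.
#' @param kinds_file,B_se,B_inner passed through to [read_graph()] and the
#'   tests.
#' @return Invisibly, a data frame with columns `path`, `pse1`, `pse0`,
#'   `diff` (`PSE_1 - PSE_0`), `se1`, `se0`, `p_value` or `ci_lo`/`ci_hi`,
#'   `reject`, `n1`, `n0`, `B`, `seed`.  A Bonferroni-adjusted significance
#'   count over the enumerated paths is reported as an attribute
#'   `bonferroni_m` (no correction is applied to the per-path values).
#' @export
run_analysis <- function(graph, data, group, source, sink,
                         test = c("permutation", "normal", "basic",
                                  "percentile", "bca"),
                         labels = NULL, B = 999L, alpha = 0.05, seed = 1L,
                         adjust_extra = character(0L), out = NULL,
                         kinds_file = NULL, B_se = 200L, B_inner = 50L) {
  test <- match.arg(test)
  if (is.character(graph)) graph <- read_graph(graph, kinds_file = kinds_file)
  if (is.character(data)) {
    sep <- if (grepl("\\.tsv$", data)) "\t" else ","
    data <- utils::read.table(data, header = TRUE, sep = sep,
                              check.names = FALSE)
  }
  missing_cols <- setdiff(c(dag_nodes(graph), group, adjust_extra),
                          names(data))
  if (length(missing_cols))
    stop2("data is missing column(s) for: ",
          paste(missing_cols, collapse = ", "))
  grouped <- grouped_dataset(data, group, labels)
  paths <- enumerate_paths(graph, source, sink)

  rows <- lapply(seq_along(paths), function(i) {
    p <- paths[[i]]
    if (length(adjust_extra))
      p$adjustment <- lapply(p$adjustment, function(s)
        sort(unique(c(s, adjust_extra))))
    ps <- derive_seed(seed, i)
    pair <- pse_per_group(grouped, graph, p, B = B_se, seed = ps)
    if (test == "permutation") {
      tr <- permutation_test(grouped, graph, p, B = B, alpha = alpha,
                             seed = derive_seed(ps, 1L), B_se = B_se)
      data.frame(path = format(p), pse1 = pair$pse1, pse0 = pair$pse0,
                 diff = tr$statistic, se1 = pair$se1, se0 = pair$se0,
                 p_value = tr$p_value, ci_lo = NA_real_, ci_hi = NA_real_,
                 reject = tr$reject)
    } else {
      tr <- bootstrap_test(grouped, graph, p, B = max(B, 200L),
                           alpha = alpha, method = test,
                           seed = derive_seed(ps, 1L), B_se = B_se,
                           B_inner = B_inner)
      data.frame(path = format(p), pse1 = pair$pse1, pse0 = pair$pse0,
                 diff = tr$statistic, se1 = pair$se1, se0 = pair$se0,
                 p_value = NA_real_, ci_lo = tr$ci[[1L]], ci_hi = tr$ci[[2L]],
                 reject = tr$reject)
    }
  })
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(path = character(0L), pse1 = numeric(0L), pse0 = numeric(0L),
               diff = numeric(0L), se1 = numeric(0L), se0 = numeric(0L),
               p_value = numeric(0L), ci_lo = numeric(0L),
               ci_hi = numeric(0L), reject = logical(0L))
  if (!length(rows))
    warning("no directed path from ", source, " to ", sink, call. = FALSE)
  res$n1 <- rep(grouped$n1, nrow(res))
  res$n0 <- rep(grouped$n0, nrow(res))
  res$B <- rep(B, nrow(res))
  res$seed <- rep(seed, nrow(res))
  attr(res, "bonferroni_m") <- length(paths)

  if (!is.null(out)) {
    utils::write.table(res, out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    cfg <- list(group = group, source = source, sink = sink, test = test,
                B = B, alpha = alpha, seed = seed,
                adjust_extra = adjust_extra, n1 = grouped$n1,
                n0 = grouped$n0, n_paths = length(paths),
                package_version = as.character(utils::packageVersion("psepath")))
    cfg$config_hash <- sum(utf8ToInt(paste(
      vapply(cfg, function(x) paste(x, collapse = ","), character(1L)),
      collapse = "|")))
    jsonlite::write_json(cfg, paste0(out, ".json"), auto_unbox = TRUE,
                         pretty = TRUE)
  }
  invisible(res)
}

#' Run a reference simulation design to files
#'
#' Thin wrapper over [table_experiment()]: runs the grid and writes the
#' per-cell rejection rates as TSV.
#'
#' @inheritParams table_experiment
#' @param out output TSV path (written with [utils::write.table()]).
#' @param fast use the reduced profile (`reps = 200`, `B = 199`).
#' @param reps,B replication and resampling counts (default to the full
#'   profile `reps = 1000`, `B = 999` unless `fast`).
#' @return Invisibly, the results data frame.
#' @export
run_simulation <- function(table_id, out = NULL, reps = NULL, seed = 1L,
                           fast = FALSE, B = NULL, ...) {
  reps <- reps %||% (if (fast) 200L else 1000L)
  B <- B %||% (if (fast) 199L else 999L)
  res <- table_experiment(table_id, reps = reps, seed = seed, B = B, ...)
  if (!is.null(out))
    utils::write.table(res, out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(res)
}
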