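#' Reference networks for simulation studies
#'
#' `mi_network()` returns the binary myocardial-infarction network used by
#' the simulation harness: calorific excess (`ca`) and physical inactivity
#' (`ph`) drive visceral adiposity (`vi`), which drives the inflammatory
#' milieu (`inf`); atherosclerosis (`at`) collects `inf` plus the clinical
#' risk factors HDL (`hdl`), triglycerides (`tr`), hypertension (`hy`) and
#' glucose (`glu`) and causes myocardial infarction (`my`); `vi` and `inf`
#' also feed the off-path children platelets (`pl`) and insulin (`ins`).
#' All nodes are binary.  The canonical target path is
#' `ca -> vi -> inf -> at -> my`.
#'
#' `three_path_network()` returns the small continuous graph with edges
#' `X1 -> X2`, `X2 -> X3`, `X1 -> X3`, `X2 -> Y`, `X3 -> Y`, which carries
#' exactly three directed paths from `X1` to `Y`.
#'
#' @return A `causal_dag`.
#' @export
mi_network <- function() {
  edges <- rbind(
    c("ph", "vi"), c("ca", "vi"),
    c("vi", "inf"),
    c("inf", "at"), c("hdl", "at"), c("tr", "at"), c("hy", "at"),
    c("glu", "at"),
    c("at", "my"),
    c("vi", "pl"), c("vi", "ins"), c("inf", "ins"))
  nodes <- sort(unique(as.vector(edges)))
  parse_graph(edges, var_kind = stats::setNames(rep("binary", length(nodes)),
                                                nodes))
}

#' @rdname mi_network
#' @export
three_path_network <- function() {
  parse_graph(rbind(c("X1", "X2"), c("X2", "X3"), c("X1", "X3"),
                    c("X2", "Y"), c("X3", "Y")))
}

#' @rdname mi_network
#' @export
mi_target_path <- function() c("ca", "vi", "inf", "at", "my")

edge_keys <- function(dag) paste(dag$edges$parent, dag$edges$child, sep = "->")

#' Two-group generative scenario
#'
#' Describes how synthetic data are generated for a two-condition study on a
#' causal network: per-group edge coefficients, node intercepts, noise, root
#' distributions and group sizes.  Binary nodes are generated in topological
#' order from logistic models `logit P(child = 1 | parents) =
#' alpha0 + sum(beta * parent)`, continuous nodes from linear models with
#' Gaussian noise.  Groups differ only on the edges whose two coefficient
#' maps differ (the differential edges, with per-edge difference
#' `delta = beta1 - beta0`).
#'
#' Unstated generating constants default to symmetric, non-degenerate
#' values: intercepts 0, root prevalence 0.5 (binary) or standard normal
#' (continuous), noise SD 1, and every edge coefficient 0.5 in both groups
#' unless overridden.
#'
#' @param dag a `causal_dag`.
#' @param coef0,coef1 named numeric vectors of edge coefficients keyed
#'   `"parent->child"`, for the control (g0) and case (g1) group.  Keys not
#'   supplied default to `base_coef`; `coef1` defaults to `coef0`.
#' @param base_coef default coefficient for unspecified edges.
#' @param intercepts named numeric vector of node intercepts (default 0).
#' @param noise_sd named positive vector of noise SDs for continuous nodes
#'   (default 1).
#' @param root_p prevalence of binary root nodes.
#' @param root_mean,root_sd distribution of continuous root nodes.
#' @param n_per_group rows generated per group.
#' @param target_path node sequence of the path under test (default: none).
#' @param id optional scenario label.
#' @return A `scenario` object.
#' @export
scenario <- function(dag, coef0 = NULL, coef1 = NULL, base_coef = 0.5,
                     intercepts = NULL, noise_sd = NULL, root_p = 0.5,
                     root_mean = 0, root_sd = 1, n_per_group = 1000L,
                     target_path = NULL, id = NULL) {
  keys <- edge_keys(dag)
  fill <- function(x) {
    out <- stats::setNames(rep(base_coef, length(keys)), keys)
    if (!is.null(x)) {
      unknown <- setdiff(names(x), keys)
      if (length(unknown))
        stop2("coefficient(s) for unknown edge(s): ",
              paste(unknown, collapse = ", "))
      out[names(x)] <- x
    }
    out
  }
  b0 <- fill(coef0)
  b1 <- if (is.null(coef1)) b0 else fill(coef1)
  ic <- stats::setNames(rep(0, length(dag$nodes)), dag$nodes)
  if (!is.null(intercepts)) ic[names(intercepts)] <- intercepts
  ns <- stats::setNames(rep(1, length(dag$nodes)), dag$nodes)
  if (!is.null(noise_sd)) ns[names(noise_sd)] <- noise_sd
  if (any(ns <= 0)) stop2("noise_sd must be positive")
  if (!is_count(n_per_group)) stop2("n_per_group must be a positive integer")
  diff_edges <- keys[b1 != b0]
  tp <- if (!is.null(target_path)) specific_path(dag, target_path)
  structure(list(dag = dag, coef0 = b0, coef1 = b1, intercepts = ic,
                 noise_sd = ns, root_p = root_p, root_mean = root_mean,
                 root_sd = root_sd, n_per_group = as.integer(n_per_group),
                 target_path = tp, differential_edges = diff_edges,
                 delta = if (length(diff_edges))
                   unname(b1[diff_edges] - b0[diff_edges]) else numeric(0L),
                 id = id %||% "scenario"),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("scenario '%s': %d nodes, n = %d per group\n", x$id,
              length(x$dag$nodes), x$n_per_group))
  if (length(x$differential_edges))
    cat("  differential edges:",
        paste(sprintf("%s (%g vs %g)", x$differential_edges,
                      x$coef0[x$differential_edges],
                      x$coef1[x$differential_edges]), collapse = ", "), "\n")
  else cat("  no differential edges (null scenario)\n")
  if (!is.null(x$target_path))
    cat("  target path:", format(x$target_path), "\n")
  invisible(x)
}

#' Myocardial-infarction network scenario
#'
#' Convenience constructor for [scenario()] on [mi_network()]: every edge
#' defaults to coefficient 0.5 in both groups; `edges0`/`edges1` override
#' individual edges per group.
#'
#' @param edges0,edges1 named numeric overrides keyed `"parent->child"`.
#' @param n_per_group rows per group.
#' @param id scenario label.
#' @export
mi_scenario <- function(edges0 = NULL, edges1 = NULL, n_per_group = 1000L,
                        id = "mi") {
  ## group-1 coefficients start from the group-0 overrides, then apply edges1
  e1 <- edges0 %||% numeric(0L)
  if (!is.null(edges1)) e1[names(edges1)] <- edges1
  scenario(mi_network(), coef0 = edges0,
           coef1 = if (length(e1)) e1 else NULL,
           n_per_group = n_per_group,
           target_path = mi_target_path(), id = id)
}

#' Continuous three-path scenario
#'
#' [scenario()] on [three_path_network()] with the differential directed
#' edge `X2 -> Y` (coefficient `base` in the control group, `base + delta`
#' in the case group), making `X1 -> X2 -> Y` the unique differential path
#' from `X1` to `Y`.
#'
#' @param delta coefficient difference on `X2 -> Y`.
#' @param base baseline coefficient of every edge.
#' @param n_per_group rows per group.
#' @export
continuous_scenario <- function(delta = 1, base = 0.5, n_per_group = 1000L) {
  scenario(three_path_network(),
           coef0 = c("X2->Y" = base), coef1 = c("X2->Y" = base + delta),
           base_coef = base, n_per_group = n_per_group,
           target_path = c("X1", "X2", "Y"),
           id = sprintf("three-path delta=%g", delta))
}

#' Generate synthetic data from a scenario
#'
#' `generate_binary_network()` draws one group's rows node-by-node in
#' topological order: roots from `Bernoulli(root_p)`, children from logistic
#' models on their parents.  `generate_continuous_network()` does the same
#' with linear-Gaussian models.  `generate_grouped()` draws both groups and
#' stacks them with a group column, dispatching on the node kinds.
#'
#' @param scn a [scenario()].
#' @param group `0` (control) or `1` (case), selecting the coefficient map.
#' @param seed integer seed.
#' @return A data frame with `n_per_group` rows and one column per node;
#'   `generate_grouped()` returns a [grouped_dataset()] with labels `0`/`1`.
#' @export
generate_binary_network <- function(scn, group, seed = NULL) {
  kinds <- var_kinds(scn$dag)
  if (!all(kinds == "binary"))
    stop2("scenario contains non-binary nodes; use generate_grouped()")
  generate_network_data(scn, group, seed)
}

#' @rdname generate_binary_network
#' @export
generate_continuous_network <- function(scn, group, seed = NULL) {
  kinds <- var_kinds(scn$dag)
  if (!all(kinds == "continuous"))
    stop2("scenario contains non-continuous nodes; use generate_grouped()")
  generate_network_data(scn, group, seed)
}

generate_network_data <- function(scn, group, seed = NULL) {
  stopifnot(group %in% c(0, 1))
  beta <- if (group == 1) scn$coef1 else scn$coef0
  dag <- scn$dag
  kinds <- var_kinds(dag)
  n <- scn$n_per_group
  with_seed(seed, {
    cols <- vector("list", length(dag$nodes))
    names(cols) <- dag$nodes
    for (nd in topo_order(dag)) {
      pars <- dag_parents(dag, nd)
      if (!length(pars)) {
        cols[[nd]] <- if (kinds[[nd]] == "continuous")
          stats::rnorm(n, scn$root_mean, scn$root_sd)
        else stats::rbinom(n, 1L, scn$root_p)
        next
      }
      lp <- rep(scn$intercepts[[nd]], n)
      for (p in pars)
        lp <- lp + beta[[paste(p, nd, sep = "->")]] * cols[[p]]
      if (kinds[[nd]] == "continuous") {
        cols[[nd]] <- lp + stats::rnorm(n, 0, scn$noise_sd[[nd]])
      } else {
        pr <- stats::plogis(lp)
        if (all(pr < 1e-9) || all(pr > 1 - 1e-9))
          warning(sprintf("node %s is numerically constant (|linear predictor| large)",
                          nd), call. = FALSE)
        cols[[nd]] <- stats::rbinom(n, 1L, pr)
      }
    }
    as.data.frame(cols)
  })
}

#' @rdname generate_binary_network
#' @param group_col name of the group column added by `generate_grouped()`.
#' @export
generate_grouped <- function(scn, seed = NULL, group_col = "group") {
  with_seed(seed, {
    d0 <- generate_network_data(scn, 0)
    d1 <- generate_network_data(scn, 1)
    d0[[group_col]] <- 0L
    d1[[group_col]] <- 1L
    grouped_dataset(rbind(d0, d1), group_col, labels = c(0L, 1L))
  })
}

#' Monte-Carlo rejection-rate experiment
#'
#' Repeatedly generates both groups from a scenario, runs the chosen test(s)
#' on the target (the scenario's path, or the total effect of its endpoints),
#' and reports per-method rejection rates with Monte-Carlo standard errors
#' `sqrt(r (1 - r) / reps)`.  Replication seeds are derived deterministically
#' from `seed`, so results are independent of execution order.
#'
#' @param scn a [scenario()] with a target path.
#' @param methods subset of `"permutation"`, `"normal"`, `"basic"`,
#'   `"percentile"`, `"bca"`; bootstrap methods share one set of draws per
#'   replication.
#' @param reps number of simulated datasets (>= 50).
#' @param seed integer root seed.
#' @param target `"pse"` tests the scenario's target path; `"tce"` tests the
#'   total causal effect of the path's first node on its last.
#' @param B permutation / outer-bootstrap resamples per replication.
#' @param statistic permutation statistic, see [permutation_test()].
#' @param B_se,B_inner standardizing bootstrap sizes (see
#'   [permutation_test()], [bootstrap_test()]).
#' @param alpha rejection level.
#' @return A data frame, one row per method: `scenario`, `target`, `method`,
#'   `n`, `reps`, `rejection_rate`, `mc_se`, `seed`.  More than 5% failed
#'   replications is an error listing the failure messages.
#' @export
run_mc <- function(scn, methods = "permutation", reps = 200L, seed = 1L,
                   target = c("pse", "tce"), B = 199L,
                   statistic = c("raw", "standardized"), B_se = 50L,
                   B_inner = 50L, alpha = 0.05) {
  statistic <- match.arg(statistic)
  target <- match.arg(target)
  if (!is_count(reps) || reps < 50L) stop2("reps must be an integer >= 50")
  methods <- match.arg(methods,
                       c("permutation", "normal", "basic", "percentile",
                         "bca"), several.ok = TRUE)
  if (is.null(scn$target_path)) stop2("scenario has no target path")
  path <- if (target == "pse") scn$target_path
          else total_effect_path(scn$dag, scn$target_path$nodes[[1L]],
                                 utils::tail(scn$target_path$nodes, 1L))
  boot_methods <- setdiff(methods, "permutation")
  rej <- matrix(NA, reps, length(methods),
                dimnames = list(NULL, methods))
  failures <- character(0L)
  for (r in seq_len(reps)) {
    rs <- derive_seed(seed, r)
    res <- tryCatch({
      grouped <- generate_grouped(scn, seed = rs)
      out <- list()
      if ("permutation" %in% methods)
        out$permutation <- permutation_test(grouped, scn$dag, path, B = B,
                                            alpha = alpha,
                                            seed = derive_seed(rs, 1L),
                                            statistic = statistic,
                                            B_se = B_se)$reject
      if (length(boot_methods)) {
        bt <- bootstrap_test(grouped, scn$dag, path, B = max(B, 200L),
                             alpha = alpha, method = boot_methods,
                             seed = derive_seed(rs, 2L),
                             B_se = B_se, B_inner = B_inner)
        if (inherits(bt, "pse_test_result")) bt <- list(bt)
        for (m in boot_methods)
          out[[m]] <- if (length(boot_methods) == 1L) bt[[1L]]$reject
                      else bt[[m]]$reject
      }
      out
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, conditionMessage(res))
    } else {
      for (m in methods) rej[r, m] <- res[[m]]
    }
  }
  if (length(failures) > 0.05 * reps) {
    tab <- sort(table(failures), decreasing = TRUE)
    stop2(sprintf("%d/%d replications failed; most common: %s",
                  length(failures), reps,
                  paste(sprintf("'%s' (%d)", names(tab), tab),
                        collapse = "; ")))
  }
  rates <- colMeans(rej, na.rm = TRUE)
  used <- colSums(!is.na(rej))
  data.frame(scenario = scn$id, target = target, method = methods,
             n = scn$n_per_group, reps = used,
             rejection_rate = unname(rates),
             mc_se = unname(sqrt(rates * (1 - rates) / used)),
             seed = seed, row.names = NULL)
}

ALL_METHODS <- c("permutation", "normal", "basic", "percentile", "bca")

#' Reference simulation designs
#'
#' Instantiates the type-I-error and power grids of the reference simulation study and
#' runs [run_mc()] on every cell:
#' \describe{
#'   \item{T1/T2}{null scenarios (all edges 0.5 in both groups) across sample
#'     sizes 200-1000; T1 tests the total effect of `ca` on `my`, T2 the
#'     path `ca -> vi -> inf -> at -my`; all five methods.}
#'   \item{T3/T4}{the four target-path edges at `e` vs `e + 1` for
#'     `e = 0.2, ..., 1.0` (effect difference 1); T3 total effect with five
#'     methods, T4 path effect with permutation.}
#'   \item{T5/T6}{edges `ca->vi`, `inf->at`, `at->my` at `0.5` vs
#'     `0.5 + delta` for `delta = 0.5, ..., 3.0`; T5 total effect, T6 path
#'     effect.}
#'   \item{T7}{target path fixed at `0.5` vs `1.5` (the delta = 1 row of T6);
#'     the on-path nodes' parent edges `ph->vi`, `hdl->at`, `tr->at`,
#'     `hy->at`, `glu->at` swept over `e` vs `e + 1`.}
#'   \item{T8}{same base; the off-path child edges `vi->pl`, `vi->ins`,
#'     `inf->ins` swept over `e` vs `e + 1`.}
#' }
#'
#' @param table_id one of `"T1"` ... `"T8"`.
#' @param reps replications per cell.
#' @param seed root seed (each cell derives its own).
#' @param n_per_group group size for the effect-size grids (T3-T8).
#' @param methods optional override of the per-table method set.
#' @param ... passed to [run_mc()] (e.g. `B`, `B_se`).
#' @return Data frame of [run_mc()] rows, one block per grid cell, with a
#'   `cell` label column.
#' @export
table_experiment <- function(table_id, reps = 200L, seed = 1L,
                             n_per_group = 1000L, methods = NULL, ...) {
  table_id <- match.arg(table_id, paste0("T", 1:8))
  grid <- switch(table_id,
    T1 = , T2 = {
      lapply(c(200L, 400L, 600L, 800L, 1000L), function(n) list(
        cell = sprintf("n=%d", n),
        scn = mi_scenario(n_per_group = n,
                          id = sprintf("%s null n=%d", table_id, n))))
    },
    T3 = , T4 = {
      lapply(c(0.2, 0.4, 0.6, 0.8, 1.0), function(e) {
        tgt <- c("ca->vi", "vi->inf", "inf->at", "at->my")
        list(cell = sprintf("%g vs %g", e, e + 1),
             scn = mi_scenario(
               edges0 = stats::setNames(rep(e, 4L), tgt),
               edges1 = stats::setNames(rep(e + 1, 4L), tgt),
               n_per_group = n_per_group,
               id = sprintf("%s path %g vs %g", table_id, e, e + 1)))
      })
    },
    T5 = , T6 = {
      lapply(c(0.5, 1, 1.5, 2, 2.5, 3), function(delta) {
        tgt <- c("ca->vi", "inf->at", "at->my")
        list(cell = sprintf("delta=%g", delta),
             scn = mi_scenario(
               edges0 = stats::setNames(rep(0.5, 3L), tgt),
               edges1 = stats::setNames(rep(0.5 + delta, 3L), tgt),
               n_per_group = n_per_group,
               id = sprintf("%s delta=%g", table_id, delta)))
      })
    },
    T7 = {
      lapply(c(0.2, 0.4, 0.6, 0.8, 1.0), function(e) {
        tgt <- c("ca->vi", "inf->at", "at->my")
        par <- c("ph->vi", "hdl->at", "tr->at", "hy->at", "glu->at")
        list(cell = sprintf("parents %g vs %g", e, e + 1),
             scn = mi_scenario(
               edges0 = stats::setNames(c(rep(0.5, 3L), rep(e, 5L)),
                                        c(tgt, par)),
               edges1 = stats::setNames(c(rep(1.5, 3L), rep(e + 1, 5L)),
                                        c(tgt, par)),
               n_per_group = n_per_group,
               id = sprintf("T7 parents %g vs %g", e, e + 1)))
      })
    },
    T8 = {
      lapply(c(0.2, 0.4, 0.6, 0.8, 1.0), function(e) {
        tgt <- c("ca->vi", "inf->at", "at->my")
        kid <- c("vi->pl", "vi->ins", "inf->ins")
        list(cell = sprintf("children %g vs %g", e, e + 1),
             scn = mi_scenario(
               edges0 = stats::setNames(c(rep(0.5, 3L), rep(e, 3L)),
                                        c(tgt, kid)),
               edges1 = stats::setNames(c(rep(1.5, 3L), rep(e + 1, 3L)),
                                        c(tgt, kid)),
               n_per_group = n_per_group,
               id = sprintf("T8 children %g vs %g", e, e + 1)))
      })
    })
  target <- if (table_id %in% c("T1", "T3", "T5")) "tce" else "pse"
  methods <- methods %||%
    if (table_id %in% c("T1", "T2", "T3", "T5")) ALL_METHODS else "permutation"
  out <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    res <- run_mc(grid[[i]]$scn, methods = methods, reps = reps,
                  seed = derive_seed(seed, i), target = target, ...)
    res$cell <- grid[[i]]$cell
    res$table <- table_id
    out[[i]] <- res
  }
  do.call(rbind, out)
}
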