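#' Two-condition dataset
#'
#' Binds a data table to its binary group column (case/exposure versus
#' control/non-exposure) for the two-group path-effect comparison.
#'
#' @param data data frame, one row per subject, one column per network node,
#'   plus the group column.
#' @param group name of the group column.
#' @param labels length-2 vector `c(g0, g1)`: the control/non-exposure label
#'   first, the case/exposure label second.  Defaults to the sorted unique
#'   values of the group column.
#' @return A `grouped_dataset` object.
#' @export
grouped_dataset <- function(data, group, labels = NULL) {
  assert_columns(data, group)
  gv <- data[[group]]
  labels <- labels %||% sort(unique(gv))
  if (length(labels) != 2L)
    stop2("group column must have exactly two labels")
  n0 <- sum(gv == labels[[1L]]); n1 <- sum(gv == labels[[2L]])
  if (n0 == 0L || n1 == 0L)
    stop2("empty group: ", labels[[which(c(n0, n1) == 0L)[1L]]])
  if (n0 + n1 != length(gv))
    stop2("group column contains values outside the declared labels")
  structure(list(data = data, group = group,
                 g0 = labels[[1L]], g1 = labels[[2L]],
                 n0 = n0, n1 = n1),
            class = "grouped_dataset")
}

#' @export
print.grouped_dataset <- function(x, ...) {
  cat(sprintf("grouped_dataset: %d rows; %s: %s (n=%d) vs %s (n=%d)\n",
              nrow(x$data), x$group, x$g1, x$n1, x$g0, x$n0))
  invisible(x)
}

group_rows <- function(grouped, which = c("g1", "g0")) {
  which <- match.arg(which)
  grouped$data[grouped$data[[grouped$group]] == grouped[[which]], ,
               drop = FALSE]
}

#' Bootstrap standard error of a path effect
#'
#' Nonparametric bootstrap standard deviation of the product-form path effect
#' over `B` resamples of the rows (with replacement).  Resamples on which the
#' path is inestimable (an empty stratum or rank-deficient design) are
#' skipped and counted; more than 10% skips is an error.
#'
#' @param data data frame (typically one group's rows).
#' @param dag a `causal_dag`.
#' @param path a `specific_path` (or character vector of path nodes).
#' @param B number of bootstrap resamples, at least 100.
#' @param seed integer seed; the result is deterministic at fixed seed.
#' @param engine `"auto"` (default) uses the vectorised contingency-table
#'   engine when all involved variables are discrete, otherwise row-index
#'   resampling with per-resample fits.
#' @return The bootstrap standard error (positive scalar) with attributes
#'   `estimate` (the observed path effect) and `skipped` (skip fraction).
#' @export
ace_standard_error <- function(data, dag, path, B = 500L, seed = NULL,
                               engine = c("auto", "cell", "generic")) {
  if (!is_count(B) || B < 100L) stop2("B must be an integer >= 100")
  if (is.character(path)) path <- specific_path(dag, path)
  eng <- make_engine(path, path$adjustment, var_kinds(dag), dag$levels,
                     data, engine = match.arg(engine))
  tok <- eng$tokens(data)
  draws <- with_seed(seed, eng$boot(tok, as.integer(B)))
  se <- se_from_draws(draws)
  structure(se, estimate = eng$point(tok), skipped = mean(is.na(draws)))
}

## internal: ACE, SE and standardized effect for one group's tokens.
## When B_pse > 0, additionally produces draws of the *standardized* effect
## (each outer resample re-estimates its own SE from B_inner inner resamples),
## giving a bootstrap variance for PSE_g itself.
group_pse <- function(eng, tok, B_se, B_pse = 0L, B_inner = 50L) {
  ace <- eng$point(tok)
  if (is.na(ace))
    stop2("path effect inestimable on the observed data (empty stratum or ",
          "degenerate design)")
  draws <- eng$boot(tok, B_se)
  se <- se_from_draws(draws)
  out <- list(ace = ace, se = se,
              pse = if (se > 0) ace / se else sign(ace) * Inf)
  if (B_pse > 0L) {
    n <- length(tok)
    pse_draws <- vapply(seq_len(B_pse), function(b) {
      tk <- tok[sample.int(n, n, replace = TRUE)]
      a <- eng$point(tk)
      if (is.na(a)) return(NA_real_)
      s <- tryCatch(se_from_draws(eng$boot(tk, B_inner)),
                    error = function(e) NA_real_)
      if (is.na(s) || s == 0) NA_real_ else a / s
    }, numeric(1L))
    out$pse_draws <- pse_draws
    out$var_pse <- stats::var(pse_draws[!is.na(pse_draws)])
  }
  out
}

#' Standardized path effects per group
#'
#' Computes the standardized path-specific effect `PSE_g = ACE_g / S(ACE_g)`
#' independently in each group: the product-form path effect on that group's
#' rows, divided by its bootstrap standard error.
#'
#' @param grouped a [grouped_dataset()].
#' @param dag a `causal_dag`.
#' @param path a `specific_path` (or character vector of path nodes), or a
#'   [total_effect_path()] contrast.
#' @param B bootstrap resamples for each group's standard error.
#' @param B_var outer resamples used to estimate the variance of each
#'   standardized effect (each re-estimates its own SE from `B_inner` inner
#'   resamples); `0` skips this and [pse_statistic()] then treats each
#'   standardized effect as unit-variance.
#' @param B_inner inner resamples per outer draw.
#' @param seed integer seed.
#' @param engine see [ace_standard_error()].
#' @return A `path_effect_pair`: `pse1`, `pse0`, `ace1`, `ace0`, `se1`,
#'   `se0`, and (when `B_var > 0`) `var_pse1`, `var_pse0`.
#' @export
pse_per_group <- function(grouped, dag, path, B = 500L, B_var = 0L,
                          B_inner = 50L, seed = NULL,
                          engine = c("auto", "cell", "generic")) {
  if (!is_count(B) || B < 100L) stop2("B must be an integer >= 100")
  if (is.character(path)) path <- specific_path(dag, path)
  kinds <- var_kinds(dag)
  d1 <- group_rows(grouped, "g1")
  d0 <- group_rows(grouped, "g0")
  ncov <- max(lengths(path$adjustment))
  for (nm in c("g1", "g0")) {
    ng <- grouped[[if (nm == "g1") "n1" else "n0"]]
    if (ng <= ncov + 2L)
      stop2(sprintf("group %s too small (n = %d) for the adjusted fits",
                    grouped[[nm]], ng))
  }
  with_seed(seed, {
    eng1 <- make_engine(path, path$adjustment, kinds, dag$levels, d1,
                        engine = match.arg(engine))
    eng0 <- make_engine(path, path$adjustment, kinds, dag$levels, d0,
                        engine = match.arg(engine))
    r1 <- group_pse(eng1, eng1$tokens(d1), B, B_var, B_inner)
    r0 <- group_pse(eng0, eng0$tokens(d0), B, B_var, B_inner)
    structure(list(pse1 = r1$pse, pse0 = r0$pse,
                   ace1 = r1$ace, ace0 = r0$ace,
                   se1 = r1$se, se0 = r0$se,
                   var_pse1 = r1$var_pse, var_pse0 = r0$var_pse,
                   path = path, B = B, seed = seed),
              class = "path_effect_pair")
  })
}

#' @export
print.path_effect_pair <- function(x, ...) {
  cat(sprintf("path_effect_pair [%s]\n", format(x$path)))
  cat(sprintf("  case   : ACE = %.6g  SE = %.6g  PSE = %.4g\n",
              x$ace1, x$se1, x$pse1))
  cat(sprintf("  control: ACE = %.6g  SE = %.6g  PSE = %.4g\n",
              x$ace0, x$se0, x$pse0))
  invisible(x)
}

#' Studentized two-group path-effect statistic
#'
#' `PSE = (PSE_1 - PSE_0) / sqrt(Var(PSE_1 - PSE_0))`.  The groups are
#' disjoint samples, so the variance of the difference is the sum of the two
#' per-group variances.  When the pair carries bootstrap variance estimates
#' of the standardized effects (see `B_var` in [pse_per_group()]) those are
#' used; otherwise each standardized effect is treated as unit-variance
#' (its construction divides by its own standard error), giving
#' `Var = 2`.
#'
#' @param pair a `path_effect_pair`.
#' @param var_estimate optional explicit variance of the difference
#'   (positive).
#' @return The studentized statistic (scalar); antisymmetric under swapping
#'   the group labels.
#' @export
pse_statistic <- function(pair, var_estimate = NULL) {
  v <- var_estimate %||%
    (if (!is.null(pair$var_pse1) && !is.null(pair$var_pse0))
       pair$var_pse1 + pair$var_pse0 else 2)
  if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
    stop2("variance estimate must be a positive scalar")
  (pair$pse1 - pair$pse0) / sqrt(v)
}
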