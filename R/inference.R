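#' Permutation test of equal path-specific effects
#'
#' Tests `H0: PSE_1 = PSE_0` by randomly reassigning the group labels across
#' rows (sampling without replacement, preserving the group sizes) and
#' rebuilding the statistic's null distribution.  The default statistic is
#' the raw difference of the per-group path-effect products,
#' `ACE_1 - ACE_0`: the permutation distribution supplies the reference, so
#' no studentization is needed, and the raw difference preserves the
#' monotone growth of power in the underlying effect sizes that per-group
#' standardization destroys once both groups' effects are individually
#' well-resolved (see the methods vignette).  `statistic = "standardized"`
#' uses `PSE_1 - PSE_0` with each group effect divided by its own
#' within-permutation bootstrap SE.  The two-sided p-value uses the add-one
#' convention `(1 + #{|T_b| >= |T_obs|}) / (B + 1)`.
#'
#' @param grouped a [grouped_dataset()].
#' @param dag a `causal_dag`.
#' @param path a `specific_path`, character vector of path nodes, or a
#'   [total_effect_path()] contrast.
#' @param B number of label permutations, at least 99.
#' @param alpha rejection level.
#' @param seed integer seed; results are reproducible at fixed seed.
#' @param statistic `"raw"` (default): the plain difference of path-effect
#'   products `ACE_1 - ACE_0`, needing no inner bootstrap and fully
#'   deterministic given the permutation; `"standardized"`: `PSE_1 - PSE_0`,
#'   each group effect divided by its own bootstrap SE (re-estimated within
#'   every permutation from `B_se` resamples).
#' @param B_se inner bootstrap resamples for each group SE
#'   (`statistic = "standardized"` only).
#' @param exhaustive enumerate all label assignments instead of sampling;
#'   only allowed when `choose(n, n1)` does not exceed `max_exhaustive`.  The
#'   p-value is then the exact proportion of assignments with
#'   `|T| >= |T_obs|` (the observed assignment included).
#' @param max_exhaustive ceiling on enumerated assignments.
#' @param engine see [ace_standard_error()].
#' @return A `pse_test_result`: `method = "permutation"`, `statistic`
#'   (observed value), `p_value`, `reject`, `B`, `alpha`, `seed`, and the
#'   fraction of `failed` permutations (inestimable path; more than 10%
#'   is an error).
#' @export
permutation_test <- function(grouped, dag, path, B = 999L, alpha = 0.05,
                             seed = NULL,
                             statistic = c("raw", "standardized"),
                             B_se = 100L, exhaustive = FALSE,
                             max_exhaustive = 5000L,
                             engine = c("auto", "cell", "generic")) {
  statistic <- match.arg(statistic)
  if (!exhaustive && (!is_count(B) || B < 99L))
    stop2("B must be an integer >= 99")
  if (!(alpha > 0 && alpha <= 0.5)) stop2("alpha must lie in (0, 0.5]")
  if (is.character(path)) path <- specific_path(dag, path)

  data <- grouped$data
  eng <- make_engine(path, path$adjustment, var_kinds(dag), dag$levels,
                     data, engine = match.arg(engine))
  tok <- eng$tokens(data)
  in_g1 <- data[[grouped$group]] == grouped$g1
  n <- length(tok); n1 <- sum(in_g1)

  stat_fun <- function(t1, t0) {
    if (statistic == "raw") {
      a1 <- eng$point(t1); a0 <- eng$point(t0)
      if (is.na(a1) || is.na(a0)) return(NA_real_)
      a1 - a0
    } else {
      r <- tryCatch({
        g1 <- group_pse(eng, t1, B_se)
        g0 <- group_pse(eng, t0, B_se)
        g1$pse - g0$pse
      }, error = function(e) NA_real_)
      r
    }
  }

  with_seed(seed, {
    t_obs <- stat_fun(tok[in_g1], tok[!in_g1])
    if (is.na(t_obs))
      stop2("statistic inestimable on the observed grouping")

    if (exhaustive) {
      if (choose(n, n1) > max_exhaustive)
        stop2(sprintf("choose(%d, %d) assignments exceed max_exhaustive", n, n1))
      assigns <- utils::combn(n, n1)
      t_perm <- apply(assigns, 2L, function(ix)
        stat_fun(tok[ix], tok[-ix]))
      failed <- mean(is.na(t_perm))
      p <- mean(abs(t_perm[!is.na(t_perm)]) >= abs(t_obs) - 1e-12)
      B_used <- ncol(assigns)
    } else {
      t_perm <- vapply(seq_len(B), function(b) {
        ix <- sample.int(n, n1)
        stat_fun(tok[ix], tok[-ix])
      }, numeric(1L))
      failed <- mean(is.na(t_perm))
      if (failed > 0.1)
        stop2(sprintf(
          "path inestimable in %.0f%% of permutations (n1 = %d, n0 = %d); ",
          100 * failed, n1, n - n1),
          "consider larger groups or the model-based standardization")
      ok <- t_perm[!is.na(t_perm)]
      p <- (1 + sum(abs(ok) >= abs(t_obs))) / (length(ok) + 1)
      B_used <- B
    }

    new_pse_test_result("permutation", statistic = t_obs, p_value = p,
                        ci = NULL, reject = p < alpha, B = B_used,
                        alpha = alpha, seed = seed, failed = failed)
  })
}

#' Bootstrap confidence-interval tests of equal path-specific effects
#'
#' Resamples rows with replacement within each group independently,
#' recomputes `theta* = PSE_1 - PSE_0` on every resample (see `draw_se` for
#' how each draw is standardized), builds a confidence interval for
#' `theta = PSE_1 - PSE_0`, and rejects `H0` when the interval excludes
#' zero.
#'
#' Interval constructions follow this naming (which swaps the conventional
#' "basic"/"percentile" labels; see Details):
#' \describe{
#'   \item{normal}{`theta_hat -/+ z_{1-alpha/2} * se_B(theta*)`}
#'   \item{basic}{the order-statistic interval
#'     `(theta*_[(B+1)alpha/2], theta*_[(B+1)(1-alpha/2)])`}
#'   \item{percentile}{the reflected interval
#'     `(2 theta_hat - theta*_[(B+1)(1-alpha/2)], 2 theta_hat -
#'     theta*_[(B+1)alpha/2])`}
#'   \item{bca}{bias-corrected and accelerated, with median-bias constant
#'     `z0 = qnorm(#\{theta* < theta_hat\}/B)` and jackknife acceleration
#'     (see [bca_constants()])}
#' }
#'
#' @details The names `basic` and `percentile` here follow the formula
#'   printed under each label in the reference methodology: `basic` is the plain
#'   order-statistic (conventionally "percentile") interval and `percentile`
#'   is the reflected (conventionally "basic") interval.  Use the aliases
#'   `percentile_conventional = "basic"` and `basic_conventional =
#'   "percentile"` to translate.  The BCa jackknife perturbs the path-effect
#'   products while freezing the per-group SE denominators at their observed
#'   values; a degenerate acceleration falls back to the order-statistic
#'   interval with a warning.
#'
#' @inheritParams permutation_test
#' @param B outer bootstrap resamples, at least 200 (999 or more recommended
#'   for `bca`).
#' @param method one or more of `"normal"`, `"basic"`, `"percentile"`,
#'   `"bca"`.
#' @param B_se resamples for the observed per-group SEs.
#' @param draw_se how each outer draw is standardized: `"fixed"` (default)
#'   divides the resampled path-effect products by the *observed* group SEs,
#'   so the draws are rescaled copies of the product bootstrap;
#'   `"resample"` re-estimates each group SE inside every outer draw from
#'   `B_inner` inner resamples (a double bootstrap, considerably slower).
#' @param B_inner inner resamples per outer draw when
#'   `draw_se = "resample"`.
#' @return A `pse_test_result` for a single method, otherwise a named list of
#'   them (sharing one set of bootstrap draws).
#' @export
bootstrap_test <- function(grouped, dag, path, B = 999L, alpha = 0.05,
                           method = c("normal", "basic", "percentile", "bca"),
                           seed = NULL, B_se = 200L,
                           draw_se = c("fixed", "resample"), B_inner = 50L,
                           engine = c("auto", "cell", "generic")) {
  draw_se <- match.arg(draw_se)
  method <- match.arg(method, several.ok = TRUE)
  if (!is_count(B) || B < 200L) stop2("B must be an integer >= 200")
  if (!(alpha > 0 && alpha <= 0.5)) stop2("alpha must lie in (0, 0.5]")
  if (is.character(path)) path <- specific_path(dag, path)

  data <- grouped$data
  eng <- make_engine(path, path$adjustment, var_kinds(dag), dag$levels,
                     data, engine = match.arg(engine))
  tok <- eng$tokens(data)
  in_g1 <- data[[grouped$group]] == grouped$g1
  t1 <- tok[in_g1]; t0 <- tok[!in_g1]
  n1 <- length(t1); n0 <- length(t0)

  with_seed(seed, {
    obs1 <- group_pse(eng, t1, B_se)
    obs0 <- group_pse(eng, t0, B_se)
    theta_hat <- obs1$pse - obs0$pse

    if (draw_se == "fixed") {
      draws <- eng$boot(t1, B) / obs1$se - eng$boot(t0, B) / obs0$se
    } else {
      boot_group <- function(tg) {
        ng <- length(tg)
        tk <- tg[sample.int(ng, ng, replace = TRUE)]
        a <- eng$point(tk)
        if (is.na(a)) return(NA_real_)
        s <- tryCatch(se_from_draws(eng$boot(tk, B_inner)),
                      error = function(e) NA_real_)
        if (is.na(s) || s == 0) NA_real_ else a / s
      }
      draws <- vapply(seq_len(B), function(b) {
        boot_group(t1) - boot_group(t0)
      }, numeric(1L))
    }
    failed <- mean(is.na(draws))
    if (failed > 0.1)
      stop2(sprintf("%.0f%% of bootstrap resamples were degenerate", 100 * failed))
    draws_ok <- draws[!is.na(draws)]

    jack <- NULL
    if ("bca" %in% method) {
      j1 <- jackknife_aces(eng, t1) / obs1$se   # frozen SE denominators
      j0 <- jackknife_aces(eng, t0) / obs0$se
      jack <- c(j1 - obs0$pse, obs1$pse - j0)
    }

    results <- lapply(method, function(m) {
      ci <- tryCatch(
        bootstrap_ci(theta_hat, draws_ok, method = m, alpha = alpha,
                     jackknife_draws = jack),
        psepath_bca_degenerate = function(cond) {
          warning("degenerate BCa acceleration; falling back to the ",
                  "order-statistic interval", call. = FALSE)
          bootstrap_ci(theta_hat, draws_ok, method = "basic", alpha = alpha)
        })
      new_pse_test_result(m, statistic = theta_hat, p_value = NULL,
                          ci = ci, reject = ci[[1L]] > 0 || ci[[2L]] < 0,
                          B = B, alpha = alpha, seed = seed, failed = failed)
    })
    names(results) <- method
    if (length(results) == 1L) results[[1L]] else results
  })
}

## leave-one-out path-effect products; cell engine collapses identical rows
jackknife_aces <- function(eng, tok) {
  n <- length(tok)
  if (eng$type == "cell") {
    cnt <- tabulate(tok, eng$ncells)
    occ <- which(cnt > 0L)
    C <- matrix(cnt, eng$ncells, length(occ))
    C[cbind(occ, seq_along(occ))] <- C[cbind(occ, seq_along(occ))] - 1L
    vals <- eng$point_counts(C)
    rep(vals, cnt[occ])
  } else {
    vapply(seq_len(n), function(i) eng$point(tok[-i]), numeric(1L))
  }
}

#' Bootstrap confidence interval constructions
#'
#' Builds a two-sided `1 - alpha` interval for a scalar statistic from its
#' bootstrap draws.  See [bootstrap_test()] for the four constructions and
#' the naming caveat.  Order statistics use index `ceiling((B+1) * q)`
#' clipped to `[1, B]`.
#'
#' @param theta_hat observed statistic.
#' @param draws numeric vector of bootstrap replicates (no `NA`s).
#' @param method one of `"normal"`, `"basic"`, `"percentile"`, `"bca"`.
#' @param alpha two-sided level.
#' @param jackknife_draws leave-one-out replicates, required for `"bca"`.
#' @return Length-2 numeric `c(lower, upper)`.
#' @export
bootstrap_ci <- function(theta_hat, draws,
                         method = c("normal", "basic", "percentile", "bca"),
                         alpha = 0.05, jackknife_draws = NULL) {
  method <- match.arg(method)
  B <- length(draws)
  if (B < 2L) stop2("need at least 2 bootstrap draws")
  ord <- function(q) sort(draws)[min(max(ceiling((B + 1) * q), 1L), B)]
  switch(method,
    normal = {
      z <- stats::qnorm(1 - alpha / 2)
      se <- stats::sd(draws)
      c(theta_hat - z * se, theta_hat + z * se)
    },
    basic = c(ord(alpha / 2), ord(1 - alpha / 2)),
    percentile = c(2 * theta_hat - ord(1 - alpha / 2),
                   2 * theta_hat - ord(alpha / 2)),
    bca = {
      if (is.null(jackknife_draws))
        stop2("bca needs jackknife_draws")
      zc <- bca_constants(theta_hat, draws, jackknife_draws)
      if (is.na(zc[["a"]]))
        stop(structure(class = c("psepath_bca_degenerate", "error",
                                 "condition"),
                       list(message = "degenerate acceleration",
                            call = NULL)))
      z0 <- zc[["z0"]]; a <- zc[["a"]]
      adj <- function(zq) stats::pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
      c(ord(adj(stats::qnorm(alpha / 2))),
        ord(adj(stats::qnorm(1 - alpha / 2))))
    })
}

#' Bias-correction and acceleration constants for BCa intervals
#'
#' `z0 = qnorm(#\{theta* < theta_hat\} / B)` measures median bias of the
#' bootstrap distribution; the acceleration is the jackknife skewness
#' `a = sum((m - t_i)^3) / (6 * (sum((m - t_i)^2))^{3/2})` with `m` the mean
#' of the leave-one-out replicates `t_i`.
#'
#' @param theta_hat observed statistic.
#' @param boot_draws bootstrap replicates.
#' @param jackknife_draws at least 3 leave-one-out replicates.
#' @return Named numeric `c(z0 = ..., a = ...)`; `a` is `NA` when the
#'   jackknife replicates have zero variance.  All bootstrap draws on one
#'   side of `theta_hat` is an error (larger `B` advised).
#' @export
bca_constants <- function(theta_hat, boot_draws, jackknife_draws) {
  if (length(jackknife_draws) < 3L)
    stop2("need at least 3 jackknife draws")
  prop <- mean(boot_draws < theta_hat)
  if (prop == 0 || prop == 1)
    stop2("all bootstrap draws fall on one side of the estimate; ",
          "the bias constant is infinite - increase B")
  z0 <- stats::qnorm(prop)
  d <- mean(jackknife_draws) - jackknife_draws
  denom <- sum(d^2)
  a <- if (denom == 0) NA_real_ else sum(d^3) / (6 * denom^1.5)
  c(z0 = z0, a = a)
}

new_pse_test_result <- function(method, statistic, p_value, ci, reject,
                                B, alpha, seed, failed = 0) {
  if (!is.null(ci) && ci[[1L]] > ci[[2L]]) ci <- sort(ci)
  structure(list(method = method, statistic = statistic, p_value = p_value,
                 ci = ci, reject = reject, B = B, alpha = alpha,
                 seed = seed, failed = failed),
            class = "pse_test_result")
}

#' @export
print.pse_test_result <- function(x, ...) {
  cat(sprintf("pse_test_result [%s]: statistic = %.6g", x$method, x$statistic))
  if (!is.null(x$p_value)) cat(sprintf(", p = %.4g", x$p_value))
  if (!is.null(x$ci)) cat(sprintf(", %d%% CI = [%.6g, %.6g]",
                                  round(100 * (1 - x$alpha)), x$ci[[1L]],
                                  x$ci[[2L]]))
  cat(sprintf(", reject = %s (B = %d)\n", x$reject, x$B))
  invisible(x)
}
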