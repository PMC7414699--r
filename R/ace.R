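#' Per-edge average causal effect, continuous child
#'
#' Back-door-adjusted effect of `A` on a continuous child `B`: the
#' coefficient of `A` in the least-squares fit of `B` on `A` and the
#' covariates.  This is the derivative dE(B | A, C)/dA, a unit-change effect,
#' so it contributes no extra scale divisor to a path product.
#'
#' @param data data frame containing all referenced columns.
#' @param edge length-2 character vector `c(parent, child)`.
#' @param covariates character vector of adjustment covariates (may be empty).
#' @param na_action `"error"` (default) or `"omit"` (complete-case with a
#'   reported count).
#' @return An `edge_ace` object: `estimate`, `edge`, `contrast` (`NULL`, slope
#'   convention), `n_used`.
#' @examples
#' d <- data.frame(A = rnorm(100))
#' d$B <- 2 * d$A + rnorm(100, sd = 0.1)
#' edge_ace_continuous(d, c("A", "B"))
#' @export
edge_ace_continuous <- function(data, edge, covariates = character(0L),
                                na_action = c("error", "omit")) {
  cols <- unique(c(edge, covariates))
  assert_columns(data, cols)
  data <- handle_missing(data, cols, na_action)
  n <- nrow(data)
  if (n <= length(covariates) + 2L)
    stop2("too few rows for the adjusted fit")
  y <- as.numeric(data[[edge[[2L]]]])
  X <- cbind(`(Intercept)` = 1, as.numeric(data[[edge[[1L]]]]))
  colnames(X)[2L] <- edge[[1L]]
  for (cv in covariates) X <- cbind(X, as.numeric(data[[cv]]))
  colnames(X) <- c("(Intercept)", edge[[1L]], covariates)
  if (stats::sd(y) == 0)
    return(new_edge_ace(edge, 0, NULL, n))
  qr_X <- qr(X)
  if (qr_X$rank < ncol(X)) {
    dropped <- colnames(X)[qr_X$pivot[(qr_X$rank + 1L):ncol(X)]]
    stop2("collinear design; offending column(s): ",
          paste(dropped, collapse = ", "))
  }
  est <- qr.coef(qr_X, y)[[edge[[1L]]]]
  new_edge_ace(edge, est, NULL, n)
}

#' Per-edge average causal effect, binary child
#'
#' Standardized risk difference of `A` on a binary child `B`:
#' `sum_c [P(B=1 | A=x', C=c) - P(B=1 | A=x'', C=c)] P(C=c)`, averaging the
#' stratum-specific contrasts over the empirical covariate distribution.
#'
#' @inheritParams edge_ace_continuous
#' @param x1,x0 the two intervention levels of `A` being contrasted
#'   (`do(x')` vs `do(x'')`), default `1` vs `0`.
#' @param method `"stratified"` computes the nonparametric stratified sum
#'   (exact saturated-model standardization; default with discrete
#'   covariates); `"model"` fits a main-effects logistic regression of `B` on
#'   `A` and the covariates and averages predicted probabilities over the
#'   empirical covariate rows (usable with many or continuous covariates);
#'   `"auto"` picks `"stratified"` when all covariates are discrete with a
#'   stratum table small relative to `n`.
#' @param on_empty for `"stratified"`: `"error"` (default) rejects strata with
#'   positive weight but no observations at a contrast level; `"model"` falls
#'   back to model-based standardization.
#' @return An `edge_ace` object; the estimate lies in `[-1, 1]`.
#' @export
edge_ace_binary <- function(data, edge, covariates = character(0L),
                            x1 = 1, x0 = 0,
                            method = c("auto", "stratified", "model"),
                            on_empty = c("error", "model"),
                            na_action = c("error", "omit")) {
  method <- match.arg(method)
  on_empty <- match.arg(on_empty)
  cols <- unique(c(edge, covariates))
  assert_columns(data, cols)
  data <- handle_missing(data, cols, na_action)
  b <- data[[edge[[2L]]]]
  if (!all(b %in% c(0, 1))) stop2(edge[[2L]], " is not binary (0/1)")
  if (identical(x1, x0)) return(new_edge_ace(edge, 0, c(x1, x0), nrow(data)))
  est <- standardized_mean_diff(data, edge, covariates, x1, x0,
                                method, on_empty)
  new_edge_ace(edge, est, c(x1, x0), nrow(data))
}

## shared standardization core (binary or discrete child; E(B | a, c) averaged
## over the empirical covariate distribution)
standardized_mean_diff <- function(data, edge, covariates, x1, x0,
                                   method, on_empty) {
  a <- data[[edge[[1L]]]]
  b <- as.numeric(data[[edge[[2L]]]])
  n <- nrow(data)
  discrete_covs <- all(vapply(data[covariates], function(x)
    length(unique(x)) <= 10 && all(x == round(x)), logical(1L))) ||
    length(covariates) == 0L
  if (method == "auto") {
    nstrata <- if (length(covariates))
      prod(vapply(data[covariates], function(x) length(unique(x)),
                  numeric(1L))) else 1
    method <- if (discrete_covs && nstrata * 4 <= n) "stratified" else "model"
  }
  if (method == "stratified") {
    if (!discrete_covs)
      stop2("stratified standardization needs discrete covariates")
    stratum <- if (length(covariates))
      interaction(data[covariates], drop = TRUE) else factor(rep(1L, n))
    w <- tabulate(stratum) / n
    m1 <- tapply(b[a == x1], stratum[a == x1], mean)
    m0 <- tapply(b[a == x0], stratum[a == x0], mean)
    lev <- levels(stratum)
    m1 <- m1[lev]; m0 <- m0[lev]
    if (anyNA(m1) || anyNA(m0)) {
      if (on_empty == "error")
        stop2("stratum with positive weight has no observations at a ",
              "contrast level of ", edge[[1L]],
              "; use on_empty = \"model\" for model-based extrapolation")
      return(standardized_mean_diff(data, edge, covariates, x1, x0,
                                    "model", on_empty))
    }
    sum(w * (m1 - m0))
  } else {
    X <- cbind(1, as.numeric(a))
    for (cv in covariates) X <- cbind(X, as.numeric(data[[cv]]))
    fit <- suppressWarnings(stats::glm.fit(X, b, family = stats::binomial()))
    if (any(is.na(fit$coefficients)))
      stop2("collinear design in the logistic standardization model for edge ",
            paste(edge, collapse = " -> "))
    beta <- fit$coefficients
    X1 <- X; X1[, 2L] <- as.numeric(x1)
    X0 <- X; X0[, 2L] <- as.numeric(x0)
    mean(stats::plogis(drop(X1 %*% beta))) -
      mean(stats::plogis(drop(X0 %*% beta)))
  }
}

#' Per-edge average causal effect, ordered discrete child
#'
#' For a child with ordered levels `0..M`, the standardized effect is
#' computed through the CDF-differencing form
#' `sum_c p(c) sum_m [F(m | c, x'') - F(m | c, x')]` over `m = 0..M-1`,
#' which equals the standardized difference of conditional means
#' `E(B | do(x')) - E(B | do(x''))` and reduces exactly to the binary
#' risk difference when `M = 1`.
#'
#' @inheritParams edge_ace_binary
#' @param levels the ordered level set of the child; defaults to the sorted
#'   unique observed values.  An explicit unordered declaration is rejected.
#' @export
edge_ace_discrete <- function(data, edge, covariates = character(0L),
                              x1 = 1, x0 = 0, levels = NULL,
                              na_action = c("error", "omit")) {
  cols <- unique(c(edge, covariates))
  assert_columns(data, cols)
  data <- handle_missing(data, cols, na_action)
  b <- data[[edge[[2L]]]]
  lv <- levels %||% sort(unique(b))
  if (is.unsorted(lv))
    stop2("levels of ", edge[[2L]],
          " must be declared in increasing order (the CDF form needs an ordering)")
  if (!all(b %in% lv)) stop2(edge[[2L]], " has values outside declared levels")
  if (identical(x1, x0) || length(lv) == 1L)
    return(new_edge_ace(edge, 0, c(x1, x0), nrow(data)))
  a <- data[[edge[[1L]]]]
  n <- nrow(data)
  stratum <- if (length(covariates))
    interaction(data[covariates], drop = TRUE) else factor(rep(1L, n))
  w <- tabulate(stratum) / n
  est <- 0
  M <- length(lv)
  for (s in seq_along(levels(stratum))) {
    in_s <- stratum == levels(stratum)[s]
    b1 <- b[in_s & a == x1]; b0 <- b[in_s & a == x0]
    if (w[s] == 0) next
    if (!length(b1) || !length(b0))
      stop2("stratum with positive weight has no observations at a contrast ",
            "level of ", edge[[1L]])
    ## sum over interior levels of the CDF difference, scaled by level gaps
    acc <- 0
    for (m in seq_len(M - 1L)) {
      gap <- lv[m + 1L] - lv[m]
      acc <- acc + gap * (mean(b0 <= lv[m]) - mean(b1 <= lv[m]))
    }
    est <- est + w[s] * acc
  }
  new_edge_ace(edge, est, c(x1, x0), n)
}

new_edge_ace <- function(edge, estimate, contrast, n_used) {
  if (!is.finite(estimate)) stop2("edge effect estimate is not finite")
  structure(list(edge = as.character(edge), estimate = estimate,
                 contrast = contrast, n_used = n_used),
            class = "edge_ace")
}

#' @export
print.edge_ace <- function(x, ...) {
  ct <- if (is.null(x$contrast)) "slope"
        else sprintf("do(%s) vs do(%s)", x$contrast[[1L]], x$contrast[[2L]])
  cat(sprintf("edge_ace %s -> %s: %.6g  [%s, n = %d]\n",
              x$edge[[1L]], x$edge[[2L]], x$estimate, ct, x$n_used))
  invisible(x)
}

#' Product-form path-specific effect
#'
#' Combines per-edge effects along `X1 -> X2 -> ... -> XK -> Y` into the
#' path effect `prod_i ACE_i / prod_{i=2}^{K} (x_i' - x_i'')`.  The divisor
#' applies one factor per interior mediator estimated on a level-contrast
#' scale; slope-estimated (continuous) mediators contribute 1 because a
#' regression slope is already a unit-change effect.
#'
#' @param edge_aces ordered list of `edge_ace` objects, upstream first.
#' @param mediator_contrasts optional list of `c(x', x'')` pairs, one per
#'   interior mediator (edges 2..K); taken from each edge's stored contrast
#'   when `NULL`.
#' @param path optional `specific_path` recorded on the result.
#' @return A `path_ace` object: `estimate`, `edge_aces`, `scale_divisor`.
#' @export
path_ace <- function(edge_aces, mediator_contrasts = NULL, path = NULL) {
  if (!length(edge_aces)) stop2("need at least one edge effect")
  if (inherits(edge_aces, "edge_ace")) edge_aces <- list(edge_aces)
  ests <- vapply(edge_aces, function(e) e$estimate, numeric(1L))
  k <- length(edge_aces)
  divisor <- 1
  if (k >= 2L) for (i in 2:k) {
    ct <- if (!is.null(mediator_contrasts)) mediator_contrasts[[i - 1L]]
          else edge_aces[[i]]$contrast
    if (!is.null(ct)) divisor <- divisor * (ct[[1L]] - ct[[2L]])
  }
  if (divisor == 0) stop2("zero scale divisor: mediator contrast levels coincide")
  structure(list(path = path, edge_aces = edge_aces,
                 estimate = prod(ests) / divisor,
                 scale_divisor = divisor),
            class = "path_ace")
}

#' @export
print.path_ace <- function(x, ...) {
  lbl <- if (!is.null(x$path)) format(x$path)
         else paste(vapply(x$edge_aces, function(e)
           paste(e$edge, collapse = "->"), character(1L)), collapse = ", ")
  cat(sprintf("path_ace [%s]: %.6g (divisor %.6g)\n",
              lbl, x$estimate, x$scale_divisor))
  invisible(x)
}

#' Total causal effect of an exposure on an outcome
#'
#' Back-door estimate of the effect summed over all directed routes,
#' adjusting only for the parents of the exposure: a regression slope for a
#' continuous outcome, a standardized risk difference for a binary outcome.
#' Contrasted with the single-path effect, the total effect is blind to
#' redistribution of effect across parallel paths.
#'
#' @param data data frame.
#' @param dag a `causal_dag` supplying the exposure's parents.
#' @param exposure,outcome node/column names, distinct.
#' @param x1,x0 contrast levels for a discrete exposure on a binary outcome.
#' @param ... passed to the underlying edge estimator.
#' @return An `edge_ace` object for the `(exposure, outcome)` contrast.
#' @export
total_ace <- function(data, dag, exposure, outcome, x1 = 1, x0 = 0, ...) {
  check_node(dag, exposure)
  check_node(dag, outcome)
  if (identical(exposure, outcome)) stop2("exposure and outcome must differ")
  covs <- dag_parents(dag, exposure)
  if (var_kinds(dag)[[outcome]] == "continuous")
    edge_ace_continuous(data, c(exposure, outcome), covs, ...)
  else
    edge_ace_binary(data, c(exposure, outcome), covs, x1 = x1, x0 = x0, ...)
}

#' Pseudo-path carrying a total-effect contrast
#'
#' Builds a one-edge contrast object (exposure -> outcome, adjusted for the
#' exposure's parents) in the shape of a [specific_path()], so the
#' permutation and bootstrap machinery can test total causal effects with the
#' same code path that tests path-specific effects.  The pair need not be an
#' edge of the DAG.
#'
#' @inheritParams total_ace
#' @return A `specific_path`-shaped object.
#' @export
total_effect_path <- function(dag, exposure, outcome) {
  check_node(dag, exposure)
  check_node(dag, outcome)
  if (identical(exposure, outcome)) stop2("exposure and outcome must differ")
  key <- paste(exposure, outcome, sep = "->")
  adj <- list(dag_parents(dag, exposure))
  names(adj) <- key
  edges <- list(c(exposure, outcome))
  names(edges) <- key
  structure(list(nodes = c(exposure, outcome), edges = edges,
                 adjustment = adj),
            class = "specific_path")
}

#' Estimate a path-specific effect from data
#'
#' Convenience wrapper: estimates each edge of `path` with the estimator
#' matching the child's declared kind and multiplies them with [path_ace()].
#'
#' @param data data frame with one column per involved node.
#' @param dag a `causal_dag`.
#' @param path a `specific_path` or character vector of path nodes.
#' @param method standardization method for discrete children, see
#'   [edge_ace_binary()].
#' @param na_action see [edge_ace_continuous()].
#' @return A `path_ace` object.
#' @export
estimate_path_ace <- function(data, dag, path,
                              method = c("auto", "stratified", "model"),
                              na_action = c("error", "omit")) {
  method <- match.arg(method)
  if (is.character(path)) path <- specific_path(dag, path)
  kinds <- var_kinds(dag)
  aces <- vector("list", length(path$edges))
  for (i in seq_along(path$edges)) {
    e <- path$edges[[i]]
    covs <- path$adjustment[[i]]
    kind_b <- kinds[[e[[2L]]]]
    aces[[i]] <- switch(kind_b,
      continuous = edge_ace_continuous(data, e, covs, na_action = na_action),
      binary = edge_ace_binary(data, e, covs, method = method,
                               na_action = na_action),
      discrete = edge_ace_discrete(data, e, covs,
                                   levels = dag$levels[[e[[2L]]]],
                                   na_action = na_action))
  }
  path_ace(aces, path = path)
}
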