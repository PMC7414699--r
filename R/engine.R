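## Internal estimation engines.
##
## A path estimate is a product of per-edge adjusted effects.  Two engines
## compute it under resampling:
##
##  * cell engine  - when every variable touched by the path (path nodes and
##    adjustment covariates) is binary/discrete, the sample reduces to a joint
##    contingency table.  A bootstrap resample of rows is then exactly a
##    multinomial draw over cells and a permutation of group labels is a
##    random split of the pooled cell-id vector, so resampling is vectorised
##    (rmultinom + rowsum collapses) instead of refitting models.
##  * generic engine - row-index resampling with per-resample least-squares /
##    logistic fits; covers continuous and mixed paths.
##
## Both estimate the same quantities; equality on discrete data is pinned by
## tests.

MAX_CELLS <- 4096L

## ---- estimation spec ------------------------------------------------------

## Describe how to estimate one path: per edge the parent `a`, child `b`,
## covariate set, child kind, and the parent contrast (x', x'') when the
## parent enters through a level contrast rather than a slope.
make_est_spec <- function(path, plan, kinds, levels, contrasts = NULL) {
  edges <- path$edges
  k <- length(edges)
  spec_edges <- vector("list", k)
  for (i in seq_len(k)) {
    a <- edges[[i]][[1L]]; b <- edges[[i]][[2L]]
    covs <- plan[[i]] %||% character(0L)
    kind_b <- kind_of(kinds, b)
    kind_a <- kind_of(kinds, a)
    contrast <- contrasts[[a]]
    if (is.null(contrast) && kind_a %in% c("binary", "discrete")) {
      lv <- levels[[a]] %||% c(0, 1)
      contrast <- c(max(lv), min(lv))
    }
    spec_edges[[i]] <- list(a = a, b = b, covs = covs,
                            kind_a = kind_a, kind_b = kind_b,
                            contrast = contrast)
  }
  ## scale divisor: contrasts of the interior mediators (edges 2..K have an
  ## interior mediator as parent); slope-estimated parents contribute 1
  divisor <- 1
  if (k >= 2L) for (i in 2:k) {
    ct <- spec_edges[[i]]$contrast
    if (!is.null(ct)) divisor <- divisor * (ct[[1L]] - ct[[2L]])
  }
  if (divisor == 0) stop2("zero scale divisor: mediator contrast levels coincide")
  vars <- unique(unlist(lapply(spec_edges, function(e) c(e$a, e$b, e$covs))))
  list(edges = spec_edges, divisor = divisor, vars = vars,
       label = paste(path$nodes, collapse = " -> "))
}

## kind lookup tolerating variables outside the declared graph (for example
## globally appended covariates), which default to continuous
kind_of <- function(kinds, v) {
  k <- kinds[v]
  if (is.null(k) || is.na(k)) "continuous" else unname(k)
}

spec_is_discrete <- function(spec, kinds) {
  all(vapply(spec$vars, function(v)
    kind_of(kinds, v) %in% c("binary", "discrete"), logical(1L)))
}

## ---- cell engine ----------------------------------------------------------

make_cell_engine <- function(spec, kinds, levels) {
  vars <- spec$vars
  lv <- lapply(vars, function(v) levels[[v]] %||% c(0, 1))
  names(lv) <- vars
  nlev <- vapply(lv, length, integer(1L))
  ncells <- prod(nlev)
  if (ncells > MAX_CELLS)
    stop2(sprintf("joint stratum table too large (%d cells)", ncells))

  ## joint cell index: mixed-radix over `vars`, var 1 fastest
  radix <- cumprod(c(1L, utils::head(nlev, -1L)))
  names(radix) <- vars

  ## per-cell value of each variable (level *values*, for expectations)
  grid_idx <- vector("list", length(vars))   # 0-based level index per cell
  for (j in seq_along(vars)) {
    reps_in <- radix[[j]]
    reps_out <- ncells / (reps_in * nlev[[j]])
    grid_idx[[j]] <- rep(rep(seq_len(nlev[[j]]) - 1L, each = reps_in),
                         times = reps_out)
  }
  names(grid_idx) <- vars
  cell_val <- lapply(vars, function(v) lv[[v]][grid_idx[[v]] + 1L])
  names(cell_val) <- vars

  ## per edge: collapse index of each joint cell into (a, b, stratum) and the
  ## pieces needed to form the standardized effect from collapsed counts
  edge_info <- lapply(spec$edges, function(e) {
    La <- nlev[[e$a]]; Lb <- nlev[[e$b]]
    a_idx <- grid_idx[[e$a]]; b_idx <- grid_idx[[e$b]]
    if (length(e$covs)) {
      s_idx <- integer(ncells)
      mult <- 1L
      for (cv in e$covs) {
        s_idx <- s_idx + grid_idx[[cv]] * mult
        mult <- mult * nlev[[cv]]
      }
      Ns <- mult
    } else {
      s_idx <- integer(ncells); Ns <- 1L
    }
    g <- 1L + a_idx + La * (b_idx + Lb * s_idx)
    ia <- match(e$contrast[[1L]], lv[[e$a]])
    ii <- match(e$contrast[[2L]], lv[[e$a]])
    if (is.na(ia) || is.na(ii))
      stop2(sprintf("contrast level not a declared level of %s", e$a))
    ## precomputed collapse helpers over the edge's (a, b, s) table:
    ## row order of rowsum(C, g) is (a fastest, then b, then s)
    abs_a <- rep(seq_len(La), times = Lb * Ns)
    abs_b <- rep(rep(seq_len(Lb), each = La), times = Ns)
    abs_s <- rep(seq_len(Ns), each = La * Lb)
    g_as <- abs_a + La * (abs_s - 1L)            # (a,b,s) -> (a,s)
    bw <- lv[[e$b]][abs_b]                       # child level value per row
    rows_ia <- ia + La * (seq_len(Ns) - 1L)      # (a = x', s) rows
    rows_ii <- ii + La * (seq_len(Ns) - 1L)
    s_of_as <- rep(seq_len(Ns), each = La)       # (a,s) -> s
    list(g = g, La = La, Lb = Lb, Ns = Ns, g_as = g_as, bw = bw,
         rows_ia = rows_ia, rows_ii = rows_ii, s_of_as = s_of_as)
  })

  tokens <- function(data) {
    id <- rep(1L, nrow(data))
    for (j in seq_along(vars)) {
      pos <- match(data[[vars[[j]]]], lv[[vars[[j]]]])
      if (anyNA(pos))
        stop2(sprintf("column %s contains values outside its declared levels",
                      vars[[j]]))
      id <- id + (pos - 1L) * radix[[j]]
    }
    id
  }

  ## standardized per-edge effect for each column of a cells-by-B count matrix
  edge_ace_counts <- function(info, C) {
    B <- ncol(C)
    E <- rowsum(C, info$g, reorder = TRUE)       # (La*Lb*Ns) x B, sorted by g
    den <- rowsum(E, info$g_as)                  # n[a,s] per column
    num <- rowsum(E * info$bw, info$g_as)        # sum of b-values
    ns <- rowsum(den, info$s_of_as)              # stratum sizes, Ns x B
    d <- num[info$rows_ia, , drop = FALSE] / den[info$rows_ia, , drop = FALSE] -
      num[info$rows_ii, , drop = FALSE] / den[info$rows_ii, , drop = FALSE]
    d[ns == 0] <- 0                              # empty stratum: weight 0
    w <- ns / rep(colSums(ns), each = info$Ns)
    .colSums(d * w, info$Ns, B)                  # NaN where a needed cell is 0
  }

  path_ace_counts <- function(counts, B = NULL) {
    C <- if (is.matrix(counts)) counts else matrix(counts, ncol = 1L)
    out <- rep(1, ncol(C))
    for (info in edge_info) out <- out * edge_ace_counts(info, C)
    res <- out / spec$divisor
    res[is.nan(res)] <- NA_real_
    res
  }

  list(
    type = "cell",
    tokens = tokens,
    ncells = ncells,
    point_counts = path_ace_counts,
    point = function(tok) path_ace_counts(tabulate(tok, ncells)),
    boot = function(tok, B) {
      n <- length(tok)
      cnt <- tabulate(tok, ncells)
      W <- stats::rmultinom(B, n, cnt)
      path_ace_counts(W)
    }
  )
}

## ---- generic engine -------------------------------------------------------

## slope of b on (a, covs) by QR least squares; NA if the design loses rank
fast_slope <- function(X, y) {
  fit <- .lm.fit(X, y)
  if (fit$rank < ncol(X)) return(NA_real_)
  fit$coefficients[[2L]]
}

make_generic_engine <- function(spec, data, kinds, std_method = "auto") {
  ## per edge: response vector and design matrix (intercept, a, covs)
  edge_fit <- lapply(spec$edges, function(e) {
    y <- as.numeric(data[[e$b]])
    X <- cbind(1, as.numeric(data[[e$a]]))
    for (cv in e$covs) X <- cbind(X, as.numeric(data[[cv]]))
    colnames(X) <- c("(Intercept)", e$a, e$covs)
    list(y = y, X = X, e = e)
  })

  est_edge <- function(ef, idx) {
    e <- ef$e
    if (e$kind_b == "continuous") {
      fast_slope(ef$X[idx, , drop = FALSE], ef$y[idx])
    } else {
      ## standardized risk difference via a logistic (binary) fit
      Xi <- ef$X[idx, , drop = FALSE]
      yi <- ef$y[idx]
      fit <- tryCatch(
        suppressWarnings(stats::glm.fit(Xi, yi,
                                        family = stats::binomial())),
        error = function(err) NULL)
      if (is.null(fit) || any(is.na(fit$coefficients))) return(NA_real_)
      beta <- fit$coefficients
      X1 <- Xi; X1[, 2L] <- e$contrast[[1L]]
      X0 <- Xi; X0[, 2L] <- e$contrast[[2L]]
      mean(stats::plogis(drop(X1 %*% beta))) -
        mean(stats::plogis(drop(X0 %*% beta)))
    }
  }

  point <- function(tok) {
    out <- 1
    for (ef in edge_fit) out <- out * est_edge(ef, tok)
    out / spec$divisor
  }

  list(
    type = "generic",
    tokens = function(d) {
      if (!identical(nrow(d), nrow(data)))
        stop2("generic engine prepared on different data")
      seq_len(nrow(d))
    },
    point = point,
    boot = function(tok, B) {
      n <- length(tok)
      vapply(seq_len(B), function(b)
        point(tok[sample.int(n, n, replace = TRUE)]), numeric(1L))
    }
  )
}

## pick the engine for a path on given data
make_engine <- function(path, plan, kinds, levels, data,
                        contrasts = NULL, engine = c("auto", "cell", "generic")) {
  engine <- match.arg(engine)
  spec <- make_est_spec(path, plan, kinds, levels, contrasts)
  assert_columns(data, spec$vars)
  use_cell <- spec_is_discrete(spec, kinds) &&
    all(vapply(spec$edges, function(e) !is.null(e$contrast), logical(1L)))
  if (engine == "cell" && !use_cell)
    stop2("cell engine requires all involved variables to be discrete")
  if (engine == "auto") engine <- if (use_cell) "cell" else "generic"
  eng <- if (engine == "cell") make_cell_engine(spec, kinds, levels)
         else make_generic_engine(spec, data, kinds)
  eng$spec <- spec
  eng
}

## bootstrap SE with the degenerate-resample policy: draws where the path is
## inestimable are skipped and counted; more than `max_skip` skips is an error
se_from_draws <- function(draws, max_skip = 0.1, context = "bootstrap") {
  bad <- mean(is.na(draws))
  if (bad > max_skip)
    stop2(sprintf("%.0f%% of %s resamples were degenerate (limit %.0f%%)",
                  100 * bad, context, 100 * max_skip))
  stats::sd(draws[!is.na(draws)])
}
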