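## internal helpers shared across modules

#' @importFrom stats coef glm lm pnorm qnorm quantile sd var predict
#' @importFrom utils head read.table write.table combn
NULL

VAR_KINDS <- c("binary", "discrete", "continuous")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

## Evaluate `expr` under a temporary RNG state seeded with `seed`; the
## caller's RNG stream is untouched.  seed = NULL runs on the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Deterministic child seed for independent sub-streams (replications,
## per-cell experiments).  Kept strictly below 2^31 - 1.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %%
               2147483629) + 1L
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == round(x) && x > 0

assert_columns <- function(data, cols, what = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing))
    stop2(sprintf("%s is missing required column(s): %s", what,
                  paste(missing, collapse = ", ")))
  invisible(TRUE)
}

## missing-value policy shared by the estimators: error by default,
## complete-case filtering on request (count reported via message)
handle_missing <- function(data, cols, na_action = c("error", "omit")) {
  na_action <- match.arg(na_action)
  sub <- data[cols]
  ok <- stats::complete.cases(sub)
  if (all(ok)) return(data)
  if (na_action == "error")
    stop2(sprintf("missing values in column(s) %s (%d row(s)); set na_action = \"omit\" to drop them",
                  paste(cols[vapply(sub, anyNA, logical(1))], collapse = ", "),
                  sum(!ok)))
  message(sprintf("dropping %d row(s) with missing values", sum(!ok)))
  data[ok, , drop = FALSE]
}
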