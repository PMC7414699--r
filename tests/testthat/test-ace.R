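test_that("continuous edge effect is the adjusted least-squares slope", {
  set.seed(11)
  n <- 400L
  d <- data.frame(A = rnorm(n))
  d$B <- 2 * d$A + rnorm(n, sd = 0.3)
  est <- edge_ace_continuous(d, c("A", "B"))
  ## closed-form least-squares oracle on the same sample
  oracle <- cov(d$A, d$B) / var(d$A)
  expect_equal(est$estimate, oracle, tolerance = 1e-10)
  expect_equal(est$estimate, 2, tolerance = 0.1)
  expect_identical(est$n_used, n)

  ## constant child
  d$B <- 5
  expect_identical(edge_ace_continuous(d, c("A", "B"))$estimate, 0)

  ## exact rank deficiency names the offender
  d$B <- rnorm(n)
  d$A2 <- d$A
  expect_error(edge_ace_continuous(d, c("A", "B"), covariates = "A2"),
               "collinear.*A2")

  ## missing values rejected unless explicitly dropped
  d$B[1] <- NA
  expect_error(edge_ace_continuous(d, c("A", "B")), "missing")
  expect_message(edge_ace_continuous(d, c("A", "B"), na_action = "omit"),
                 "dropping 1")
})

test_that("confounded slope is recovered only with adjustment", {
  set.seed(12)
  n <- 5000
  C <- rnorm(n)
  A <- C + rnorm(n, sd = 0.5)
  B <- 1.5 * A + 2 * C + rnorm(n, sd = 0.5)
  d <- data.frame(A = A, B = B, C = C)
  adj <- edge_ace_continuous(d, c("A", "B"), covariates = "C")
  expect_equal(adj$estimate, 1.5, tolerance = 0.05)
  unadj <- edge_ace_continuous(d, c("A", "B"))
  expect_gt(unadj$estimate, 2)
})

test_that("binary standardization matches the exhaustive stratified sum", {
  d <- toy_strat_table()
  est <- edge_ace_binary(d, c("A", "B"), covariates = "C",
                         method = "stratified")
  expect_equal(est$estimate, oracle_strat_rd(d), tolerance = 1e-12)
  expect_true(abs(est$estimate) <= 1)

  ## no covariates: collapses to the plain risk difference
  rd <- edge_ace_binary(d, c("A", "B"))
  expect_equal(rd$estimate, mean(d$B[d$A == 1]) - mean(d$B[d$A == 0]),
               tolerance = 1e-12)

  ## identical contrast levels give a null effect
  expect_identical(edge_ace_binary(d, c("A", "B"), x1 = 1, x0 = 1)$estimate, 0)
})

test_that("model-based and stratified standardization agree when the model is saturated", {
  d <- toy_strat_table()
  ## with no covariates a main-effects logistic model is saturated
  m <- edge_ace_binary(d, c("A", "B"), method = "model")
  s <- edge_ace_binary(d, c("A", "B"), method = "stratified")
  expect_equal(m$estimate, s$estimate, tolerance = 1e-8)
})

test_that("model standardization approximates the stratified estimand under a logistic law", {
  set.seed(21)
  n <- 20000
  C <- rbinom(n, 1, 0.5)
  A <- rbinom(n, 1, plogis(0.8 * C))
  B <- rbinom(n, 1, plogis(-0.3 + 1.1 * A + 0.7 * C))
  d <- data.frame(A = A, B = B, C = C)
  m <- edge_ace_binary(d, c("A", "B"), covariates = "C", method = "model")
  s <- edge_ace_binary(d, c("A", "B"), covariates = "C",
                       method = "stratified")
  expect_equal(m$estimate, s$estimate, tolerance = 0.01)
})

test_that("empty stratum is an error unless model extrapolation is requested", {
  d <- toy_strat_table()
  d <- d[!(d$A == 1 & d$C == 1), ]
  expect_error(edge_ace_binary(d, c("A", "B"), covariates = "C",
                               method = "stratified"),
               "stratum")
  est <- edge_ace_binary(d, c("A", "B"), covariates = "C",
                         method = "stratified", on_empty = "model")
  expect_true(is.finite(est$estimate))
})

test_that("discrete CDF-difference estimator reduces to binary and matches direct sums", {
  d <- toy_strat_table()
  bin <- edge_ace_binary(d, c("A", "B"), covariates = "C",
                         method = "stratified")
  dis <- edge_ace_discrete(d, c("A", "B"), covariates = "C",
                           levels = c(0, 1))
  expect_equal(dis$estimate, bin$estimate, tolerance = 1e-12)

  ## 3-level child: brute-force standardized mean difference oracle
  set.seed(31)
  n <- 3000
  C <- rbinom(n, 1, 0.4)
  A <- rbinom(n, 1, 0.5)
  p <- plogis(0.5 * A + 0.5 * C)
  B <- rbinom(n, 2, p)           # levels 0,1,2
  d3 <- data.frame(A = A, B = B, C = C)
  oracle <- {
    out <- 0
    for (cv in 0:1) {
      pc <- mean(C == cv)
      m1 <- mean(B[A == 1 & C == cv])
      m0 <- mean(B[A == 0 & C == cv])
      out <- out + pc * (m1 - m0)
    }
    out
  }
  est <- edge_ace_discrete(d3, c("A", "B"), covariates = "C",
                           levels = 0:2)
  expect_equal(est$estimate, oracle, tolerance = 1e-12)

  ## degenerate child: single observed level
  d1 <- data.frame(A = rbinom(50, 1, 0.5), B = rep(1, 50))
  expect_identical(edge_ace_discrete(d1, c("A", "B"), levels = 1)$estimate, 0)

  ## unordered level declaration is rejected
  expect_error(edge_ace_discrete(d3, c("A", "B"), levels = c(2, 0, 1)),
               "increasing order")
})

test_that("path products multiply and honour the mediator-contrast divisor", {
  e1 <- psepath:::new_edge_ace(c("X1", "X2"), 2, NULL, 100)
  e2 <- psepath:::new_edge_ace(c("X2", "Y"), 3, NULL, 100)
  expect_identical(path_ace(list(e1, e2))$estimate, 6)

  ## any zero edge nullifies the product
  e0 <- psepath:::new_edge_ace(c("X2", "Y"), 0, NULL, 100)
  expect_identical(path_ace(list(e1, e0))$estimate, 0)

  ## level-contrast mediator rescales by (x' - x'')
  eb <- psepath:::new_edge_ace(c("X2", "Y"), 0.6, c(3, 1), 100)
  expect_equal(path_ace(list(e1, eb))$estimate, 2 * 0.6 / 2)
  expect_error(path_ace(list(e1, eb), mediator_contrasts = list(c(1, 1))),
               "zero scale divisor")

  ## product commutativity: edge order does not change the value
  es <- list(psepath:::new_edge_ace(c("a", "b"), 0.4, c(1, 0), 10),
             psepath:::new_edge_ace(c("b", "c"), -0.5, c(1, 0), 10),
             psepath:::new_edge_ace(c("c", "d"), 0.25, c(1, 0), 10))
  for (perm in list(c(1, 2, 3), c(3, 1, 2), c(2, 3, 1)))
    expect_equal(path_ace(es[perm])$estimate,
                 path_ace(es)$estimate, tolerance = 1e-14)
})

test_that("theorem-style product identity holds against the interventional oracle", {
  ## linear-Gaussian chain with correlated confounders: the product of the
  ## two adjusted slopes equals the interventional effect of X1 on Y
  set.seed(41)
  n <- 1e4
  d <- gen_chain_sem(n)
  dag <- chain_sem_dag()
  pa <- estimate_path_ace(d, dag, c("X1", "X2", "Y"))
  ## closed form: beta_x1x2 * beta_x2y
  closed <- chain_sem_coefs$x1_x2 * chain_sem_coefs$x2_y
  ## interventional Monte-Carlo oracle, >= 1e5 draws per arm
  ey1 <- gen_chain_sem_do(2e5, 1)
  ey0 <- gen_chain_sem_do(2e5, 0)
  oracle <- ey1 - ey0
  expect_equal(oracle, closed, tolerance = 0.02)
  expect_equal(pa$estimate / oracle, 1, tolerance = 0.02)
})

test_that("total effect adjusts for the exposure's parents", {
  ## root exposure in a binary chain: unadjusted risk difference
  set.seed(51)
  n <- 2000
  A <- rbinom(n, 1, 0.5)
  Y <- rbinom(n, 1, plogis(-0.5 + A))
  g <- parse_graph(rbind(c("A", "Y")),
                   var_kind = c(A = "binary", Y = "binary"))
  d <- data.frame(A = A, Y = Y)
  tot <- total_ace(d, g, "A", "Y")
  expect_equal(tot$estimate, mean(Y[A == 1]) - mean(Y[A == 0]),
               tolerance = 1e-12)
  expect_error(total_ace(d, g, "A", "A"), "differ")

  ## linear SEM with one confounder: symbolic path-tracing oracle
  set.seed(52)
  cdag <- parse_graph(rbind(c("C", "A"), c("C", "Y"), c("A", "M"),
                            c("M", "Y"), c("A", "Y")))
  C <- rnorm(n); A2 <- 0.8 * C + rnorm(n)
  M <- 0.7 * A2 + rnorm(n)
  Y2 <- 0.5 * M + 0.4 * A2 + 0.9 * C + rnorm(n)
  d2 <- data.frame(C = C, A = A2, M = M, Y = Y2)
  tot2 <- total_ace(d2, cdag, "A", "Y")
  ## sum over directed routes: A->M->Y + A->Y
  expect_equal(tot2$estimate, 0.7 * 0.5 + 0.4, tolerance = 0.08)
})

test_that("estimate_path_ace matches the engine used by the resampling tests", {
  scn <- mi_scenario(n_per_group = 800)
  d <- generate_binary_network(scn, group = 1, seed = 9)
  g <- mi_network()
  p <- specific_path(g, mi_target_path())
  direct <- estimate_path_ace(d, g, p, method = "stratified")$estimate
  se <- ace_standard_error(d, g, p, B = 100, seed = 1)
  expect_equal(attr(se, "estimate"), direct, tolerance = 1e-12)
})
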