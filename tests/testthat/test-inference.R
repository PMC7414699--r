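test_that("permutation p-value matches exhaustive enumeration on a tiny sample", {
  ## n = 12 distinct rows, raw path-effect difference statistic; the oracle
  ## enumerates all C(12,6) label assignments directly from slope formulas
  set.seed(101)
  n <- 12
  d <- data.frame(A = rnorm(n))
  d$B <- 0.5 * d$A + rnorm(n)
  d$g <- rep(c(0, 1), each = 6)
  g <- parse_graph(rbind(c("A", "B")))
  gd <- grouped_dataset(d, "g")

  slope <- function(a, b) cov(a, b) / var(a)
  stat <- function(ix) {
    slope(d$A[ix], d$B[ix]) - slope(d$A[-ix], d$B[-ix])
  }
  obs <- stat(which(d$g == 1))
  all_t <- apply(combn(n, 6), 2, stat)
  p_oracle <- mean(abs(all_t) >= abs(obs) - 1e-12)

  res <- permutation_test(gd, g, c("A", "B"), exhaustive = TRUE,
                          statistic = "raw", seed = 1)
  expect_equal(res$p_value, p_oracle, tolerance = 1e-12)
  expect_equal(res$statistic, obs, tolerance = 1e-12)
  expect_identical(res$B, ncol(combn(n, 6)))
})

test_that("permutation p-value is invariant to swapping the group labels", {
  gd1 <- gen_three_path_grouped(n = 60, delta = 1, seed = 7)
  g <- three_path_network()
  gd2 <- grouped_dataset(gd1$data, "group", labels = c(1L, 0L))  # roles swapped
  r1 <- permutation_test(gd1, g, c("X1", "X2", "Y"), B = 199, seed = 5,
                         statistic = "raw")
  r2 <- permutation_test(gd2, g, c("X1", "X2", "Y"), B = 199, seed = 5,
                         statistic = "raw")
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
  expect_equal(r1$statistic, -r2$statistic, tolerance = 1e-12)
})

test_that("permutation test is deterministic and respects the add-one convention", {
  gd <- gen_three_path_grouped(n = 80, delta = 2, seed = 9)
  g <- three_path_network()
  r1 <- permutation_test(gd, g, c("X1", "X2", "Y"), B = 99, seed = 3,
                         B_se = 100)
  r2 <- permutation_test(gd, g, c("X1", "X2", "Y"), B = 99, seed = 3,
                         B_se = 100)
  expect_identical(r1$p_value, r2$p_value)
  expect_identical(r1$statistic, r2$statistic)
  expect_gte(r1$p_value, 1 / (99 + 1))
  expect_error(permutation_test(gd, g, c("X1", "X2", "Y"), B = 50),
               ">= 99")
  expect_error(permutation_test(gd, g, c("X1", "X2", "Y"), B = 99,
                                alpha = 0.7), "alpha")
})

test_that("order-statistic and reflected intervals match the sorting oracle", {
  set.seed(15)
  draws <- round(rnorm(20), 3)
  th <- 0.2
  s <- sort(draws)
  ## index ceiling((B+1) q) clipped to [1, B]: q = .025 -> 1, q = .975 -> 20
  expect_identical(bootstrap_ci(th, draws, "basic"), c(s[1], s[20]))
  expect_identical(bootstrap_ci(th, draws, "percentile"),
                   c(2 * th - s[20], 2 * th - s[1]))
  nrm <- bootstrap_ci(th, draws, "normal")
  expect_equal(nrm, th + c(-1, 1) * qnorm(0.975) * sd(draws),
               tolerance = 1e-12)
})

test_that("degenerate and symmetric bootstrap distributions behave as expected", {
  ## all draws equal: zero-width interval at that value
  expect_identical(bootstrap_ci(1, rep(1, 50), "basic"), c(1, 1))
  nrm <- bootstrap_ci(1, rep(1, 50), "normal")
  expect_equal(nrm[1], nrm[2])
  ## perfectly symmetric draws around theta_hat: basic == percentile up to
  ## one order statistic of granularity (adjacent draws differ by 0.1)
  sym <- c(-(50:1), 50:1) / 10
  gap <- max(abs(bootstrap_ci(0, sym, "basic") -
                   bootstrap_ci(0, sym, "percentile")))
  expect_lte(gap, 0.1 + 1e-12)
})

test_that("BCa constants match hand-computed values", {
  ## median-unbiased bootstrap: half the draws below theta_hat
  boot <- c(-(1:10), 1:10)
  zc <- bca_constants(0, boot, jackknife_draws = c(-1, 0, 1))
  expect_equal(unname(zc["z0"]), 0)
  expect_equal(unname(zc["a"]), 0)   # symmetric jackknife

  ## 5-point jackknife, arithmetic oracle evaluated longhand
  jd <- c(1, 2, 3, 5, 9)
  m <- mean(jd)
  a_hand <- sum((m - jd)^3) / (6 * sum((m - jd)^2)^1.5)
  zc2 <- bca_constants(0.5, boot, jd)
  expect_equal(unname(zc2["a"]), a_hand, tolerance = 1e-12)

  expect_error(bca_constants(0, boot, jackknife_draws = c(1, 2)),
               "at least 3")
  expect_error(bca_constants(100, boot, jd), "one side")
  ## zero jackknife variance: acceleration undefined (NA), caller falls back
  expect_true(is.na(bca_constants(0, boot, rep(2, 5))["a"]))
})

test_that("bootstrap test rejects exactly when the interval excludes zero", {
  gd <- gen_three_path_grouped(n = 250, delta = 2, seed = 17)
  g <- three_path_network()
  res <- bootstrap_test(gd, g, c("X1", "X2", "Y"), B = 200, seed = 19,
                        B_se = 100)
  for (m in names(res)) {
    r <- res[[m]]
    expect_identical(r$reject, r$ci[1] > 0 || r$ci[2] < 0)
    expect_lte(r$ci[1], r$ci[2])
  }
  ## determinism
  res2 <- bootstrap_test(gd, g, c("X1", "X2", "Y"), B = 200, seed = 19,
                         B_se = 100)
  expect_identical(res$bca$ci, res2$bca$ci)
  expect_error(bootstrap_test(gd, g, c("X1", "X2", "Y"), B = 150),
               ">= 200")
})

test_that("all methods agree on rejection for an overwhelming effect", {
  gd <- gen_three_path_grouped(n = 600, delta = 4, seed = 23)
  g <- three_path_network()
  p <- c("X1", "X2", "Y")
  perm <- permutation_test(gd, g, p, B = 199, seed = 25, B_se = 100)
  boots <- bootstrap_test(gd, g, p, B = 399, seed = 27, B_se = 100)
  expect_true(perm$reject)
  for (m in names(boots)) expect_true(boots[[m]]$reject)
})

test_that("total-effect contrasts run through the same testing machinery", {
  scn <- mi_scenario(edges0 = c("ca->vi" = 0.5), n_per_group = 400)
  gd <- generate_grouped(scn, seed = 29)
  g <- mi_network()
  tp <- total_effect_path(g, "ca", "my")
  r <- permutation_test(gd, g, tp, B = 99, seed = 31, B_se = 50)
  expect_true(is.finite(r$statistic))
  expect_gte(r$p_value, 1 / 100)
})
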