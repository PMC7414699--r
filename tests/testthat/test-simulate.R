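test_that("scenario validates coefficients and flags differential edges", {
  scn <- continuous_scenario(delta = 1)
  expect_identical(scn$differential_edges, "X2->Y")
  expect_identical(scn$delta, 1)
  expect_error(scenario(three_path_network(), coef0 = c("A->B" = 1)),
               "unknown edge")
  expect_error(scenario(three_path_network(), noise_sd = c(Y = -1)),
               "positive")
  scn0 <- mi_scenario(n_per_group = 100)
  expect_length(scn0$differential_edges, 0L)
})

test_that("null binary generator produces independent fair coins", {
  g2 <- parse_graph(rbind(c("A", "B"), c("B", "C")),
                    var_kind = c(A = "binary", B = "binary", C = "binary"))
  scn <- scenario(g2, base_coef = 0, n_per_group = 4000L)
  d <- generate_binary_network(scn, group = 0, seed = 2)
  ## every node ~ Bernoulli(0.5), three-sigma band
  for (nd in names(d))
    expect_lt(abs(mean(d[[nd]]) - 0.5), 3 * sqrt(0.25 / nrow(d)))
  ## pairwise independence sanity
  expect_gt(suppressWarnings(chisq.test(table(d$A, d$B)))$p.value, 1e-3)
  expect_gt(suppressWarnings(chisq.test(table(d$B, d$C)))$p.value, 1e-3)
})

test_that("logistic generator matches the closed-form conditional probabilities", {
  g2 <- parse_graph(rbind(c("A", "B")), var_kind = c(A = "binary", B = "binary"))
  scn <- scenario(g2, coef0 = c("A->B" = 1.2), n_per_group = 20000L)
  d <- generate_binary_network(scn, 0, seed = 3)
  p1 <- mean(d$B[d$A == 1])
  n1 <- sum(d$A == 1)
  expect_lt(abs(p1 - plogis(1.2)), 3 * sqrt(plogis(1.2) * (1 - plogis(1.2)) / n1))
  p0 <- mean(d$B[d$A == 0])
  expect_lt(abs(p0 - 0.5), 3 * sqrt(0.25 / sum(d$A == 0)))
})

test_that("myocardial-infarction generator reproduces its conditional laws", {
  tgt <- c("ca->vi", "vi->inf", "inf->at", "at->my")
  scn <- mi_scenario(edges0 = setNames(rep(0.2, 4), tgt),
                     edges1 = setNames(rep(1.2, 4), tgt),
                     n_per_group = 20000L)
  d <- generate_binary_network(scn, group = 1, seed = 5)
  expect_true(all(mi_target_path() %in% names(d)))
  expect_identical(sort(names(d)), sort(dag_nodes(mi_network())))
  ## vi | ca, ph follows expit(1.2 ca + 0.5 ph) in the case group
  for (ca in 0:1) for (ph in 0:1) {
    sel <- d$ca == ca & d$ph == ph
    want <- plogis(1.2 * ca + 0.5 * ph)
    expect_lt(abs(mean(d$vi[sel]) - want),
              3 * sqrt(want * (1 - want) / sum(sel)))
  }
  ## my | at follows expit(1.2 at)
  for (at in 0:1) {
    sel <- d$at == at
    want <- plogis(1.2 * at)
    expect_lt(abs(mean(d$my[sel]) - want),
              3 * sqrt(want * (1 - want) / sum(sel)))
  }
})

test_that("linear-Gaussian generator matches the covariance oracle", {
  chain <- parse_graph(rbind(c("X1", "X2"), c("X2", "Y")))
  scn <- scenario(chain, coef0 = c("X1->X2" = 0.8, "X2->Y" = 0.7),
                  n_per_group = 20000L)
  d <- generate_continuous_network(scn, 0, seed = 7)
  ## marginal slope of Y on X1 equals the product of path coefficients
  slope <- cov(d$X1, d$Y) / var(d$X1)
  expect_equal(slope, 0.8 * 0.7, tolerance = 0.05)

  ## zero coefficients: independent Gaussians
  scn0 <- scenario(chain, base_coef = 0, n_per_group = 20000L)
  d0 <- generate_continuous_network(scn0, 0, seed = 8)
  expect_lt(abs(cor(d0$X1, d0$X2)), 3 / sqrt(nrow(d0)))

  ## kind mismatches are rejected
  expect_error(generate_binary_network(scn, 0), "non-binary")
  expect_error(generate_continuous_network(mi_scenario(), 0),
               "non-continuous")
})

test_that("the continuous design has one differential path among three", {
  scn <- continuous_scenario(delta = 1, n_per_group = 200)
  paths <- enumerate_paths(scn$dag, "X1", "Y")
  expect_length(paths, 3L)
  on_diff <- vapply(paths, function(p)
    "X2->Y" %in% names(p$edges), logical(1L))
  expect_identical(sum(on_diff), 1L)
  expect_identical(paths[[which(on_diff)]]$nodes, c("X1", "X2", "Y"))
})

test_that("run_mc is deterministic and reports binomial Monte-Carlo error", {
  g2 <- parse_graph(rbind(c("A", "B"), c("B", "C")),
                    var_kind = c(A = "binary", B = "binary", C = "binary"))
  scn <- scenario(g2, coef0 = c("A->B" = 0.5, "B->C" = 0.5),
                  n_per_group = 150L, target_path = c("A", "B", "C"),
                  id = "chain-null")
  r1 <- run_mc(scn, methods = "permutation", reps = 50L, seed = 5,
               B = 99L, B_se = 50L)
  r2 <- run_mc(scn, methods = "permutation", reps = 50L, seed = 5,
               B = 99L, B_se = 50L)
  expect_identical(r1, r2)
  expect_equal(r1$mc_se,
               sqrt(r1$rejection_rate * (1 - r1$rejection_rate) / r1$reps))
  expect_error(run_mc(scn, reps = 10L), ">= 50")
})

test_that("table grids have the reference shapes", {
  ## T1 is the cheap grid (single-edge total-effect contrast): run it small
  res <- table_experiment("T1", reps = 50L, seed = 3, B = 99L, B_se = 50L)
  expect_identical(nrow(res), 25L)           # 5 sample sizes x 5 methods
  expect_setequal(unique(res$n), c(200L, 400L, 600L, 800L, 1000L))
  expect_setequal(unique(res$method),
                  c("permutation", "normal", "basic", "percentile", "bca"))
  expect_true(all(res$rejection_rate >= 0 & res$rejection_rate <= 1))
  expect_error(table_experiment("T9"), "arg")
})
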