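## fixture builders shared across test files

## linear-Gaussian chain X1 -> X2 -> Y with confounders C1 (of X1/X2) and
## C2 (of X2/Y), C1 -> C2; adjustment identifies both slopes
chain_sem_coefs <- list(c1_c2 = 0.7, c1_x1 = 0.8, c1_x2 = 0.6, c2_x2 = 0.5,
                        c2_y = 0.9, x1_x2 = 1.0, x2_y = 1.0)

chain_sem_dag <- function() {
  parse_graph(rbind(c("C1", "C2"), c("C1", "X1"), c("C1", "X2"),
                    c("C2", "X2"), c("C2", "Y"),
                    c("X1", "X2"), c("X2", "Y")))
}

## observational draw; noise_sd small keeps slope estimates tight
gen_chain_sem <- function(n, noise_sd = 0.5, cf = chain_sem_coefs) {
  C1 <- rnorm(n)
  C2 <- cf$c1_c2 * C1 + rnorm(n, sd = noise_sd)
  X1 <- cf$c1_x1 * C1 + rnorm(n, sd = noise_sd)
  X2 <- cf$x1_x2 * X1 + cf$c1_x2 * C1 + cf$c2_x2 * C2 + rnorm(n, sd = noise_sd)
  Y <- cf$x2_y * X2 + cf$c2_y * C2 + rnorm(n, sd = noise_sd)
  data.frame(C1 = C1, C2 = C2, X1 = X1, X2 = X2, Y = Y)
}

## interventional draw: X1 forced to x, incoming edges severed
gen_chain_sem_do <- function(n, x, noise_sd = 0.5, cf = chain_sem_coefs) {
  C1 <- rnorm(n)
  C2 <- cf$c1_c2 * C1 + rnorm(n, sd = noise_sd)
  X1 <- rep(x, n)
  X2 <- cf$x1_x2 * X1 + cf$c1_x2 * C1 + cf$c2_x2 * C2 + rnorm(n, sd = noise_sd)
  Y <- cf$x2_y * X2 + cf$c2_y * C2 + rnorm(n, sd = noise_sd)
  mean(Y)
}

## small two-group continuous dataset on the three-path graph
gen_three_path_grouped <- function(n = 300, delta = 1, seed = 1) {
  scn <- continuous_scenario(delta = delta, n_per_group = n)
  generate_grouped(scn, seed = seed)
}

## deterministic binary table with one binary covariate, for
## standardization oracles: returns a data frame of (C, A, B) rows
toy_strat_table <- function() {
  ## counts chosen so no cell is empty and effects differ by stratum
  cells <- expand.grid(C = 0:1, A = 0:1, B = 0:1)
  counts <- c(30, 20, 10, 25, 20, 15, 30, 40)
  cells[rep(seq_len(nrow(cells)), counts), ]
}

## brute-force standardized risk difference over strata of C
oracle_strat_rd <- function(d, x1 = 1, x0 = 0) {
  out <- 0
  for (cv in unique(d$C)) {
    pc <- mean(d$C == cv)
    p1 <- mean(d$B[d$A == x1 & d$C == cv])
    p0 <- mean(d$B[d$A == x0 & d$C == cv])
    out <- out + pc * (p1 - p0)
  }
  out
}
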