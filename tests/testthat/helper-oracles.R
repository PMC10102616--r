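# Independent oracles used to cross-check the implementation paths.

# Brute-force OLS by explicit normal equations (X'X)^-1 X'y -- coded
# independently of the QR route inside the fitting code.
ols_normal_equations <- function(X, y) {
  beta <- solve(crossprod(X), crossprod(X, y))
  n <- nrow(X); p <- ncol(X)
  resid <- y - X %*% beta
  sigma2 <- sum(resid^2) / (n - p)
  se <- sqrt(diag(solve(crossprod(X))) * sigma2)
  tval <- as.numeric(beta) / se
  list(beta = as.numeric(beta), se = se,
       p = 2 * pt(-abs(tval), df = n - p))
}

# Exact two-sided Fisher p for a 2x2 table by hypergeometric
# enumeration: sum the probabilities of all tables (with the observed
# margins) no more probable than the observed one.
fisher_2x2_oracle <- function(tab) {
  stopifnot(all(dim(tab) == c(2, 2)))
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact two-sided Mann-Whitney p (no ties) by full enumeration of all
# choose(n1 + n2, n1) rank assignments.
mann_whitney_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  sets <- combn(n1 + n2, n1)
  us <- apply(sets, 2, function(idx) sum(idx) - n1 * (n1 + 1) / 2)
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Small helper: a hand-built cohort-like data frame with an exactly
# linear outcome, for exact-recovery tests.
exact_linear_cohort <- function(n = 24, beta_x = 2, exposure = "hemoglobin") {
  set.seed(42)
  d <- data.frame(
    id = sprintf("E%02d", seq_len(n)),
    group = rep(c("SCD", "control"), length.out = n),
    age = runif(n, 8, 30),
    sex = rep(c("male", "female"), length.out = n),
    hemoglobin = runif(n, 6, 15),
    sao2 = runif(n, 0.9, 1.0),
    icv = runif(n, 1200, 1600),
    total_burden = runif(n, 0.05, 1),
    stringsAsFactors = FALSE
  )
  d$log10_burden <- log10(d$total_burden)
  d$true_gm_cbf <- runif(n, 40, 100)
  x <- switch(exposure,
              hemoglobin = d$hemoglobin,
              scd_status = as.numeric(d$group == "SCD"),
              log10_burden = d$log10_burden)
  male <- as.numeric(d$sex == "male")
  d$gmv <- 600 + beta_x * x - 1.2 * d$age + 10 * male + 0.2 * d$icv
  d$wmv <- 420 + beta_x * x + 0.8 * d$age + 5 * male + 0.15 * d$icv
  d
}
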