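# Independent oracles and fixture builders used across the test files.

# --- fixtures -----------------------------------------------------------

# 10-row response table: 6 complete rows, 2 rows with exactly one missing
# item (item_2, item_7), 1 row with two missing items, 1 row with a
# missing covariate.
make_toy_screen_table <- function() {
  base_row <- function() {
    out <- as.list(c(rep("no", 5), rep("never", 6)))
    names(out) <- paste0("item_", 1:11)
    out$sex <- "female"; out$age_group <- "a30_44"; out$education <- "hs"
    out$income <- "gt50k"; out$insurance <- "insured"; out$race <- "white"
    out$marital <- "married"; out$outcome <- 0L
    out
  }
  rows <- lapply(1:10, function(i) base_row())
  rows[[2]]$item_1 <- "yes"; rows[[2]]$outcome <- 1L
  rows[[7]]$item_2 <- NA                      # one missing yes/no item
  rows[[8]]$item_7 <- NA                      # one missing frequency item
  rows[[9]]$item_3 <- NA; rows[[9]]$item_9 <- NA  # two missing items
  rows[[10]]$income <- NA                     # missing covariate
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

# the worked single-respondent row: items 1-5 = yes,no,no,yes,no and
# items 6-11 = never, once, more_than_once, never, once, never
make_worked_row <- function() {
  d <- data.frame(
    item_1 = "yes", item_2 = "no", item_3 = "no", item_4 = "yes",
    item_5 = "no", item_6 = "never", item_7 = "once",
    item_8 = "more_than_once", item_9 = "never", item_10 = "once",
    item_11 = "never", stringsAsFactors = FALSE
  )
  d
}

# small covariate-free logistic dataset: intercept + (k-1) standard-normal
# columns, outcome from a random true coefficient vector
make_random_logit_data <- function(n, k, seed) {
  set.seed(seed)
  x <- cbind(`(Intercept)` = 1,
             matrix(rnorm(n * (k - 1)), n, k - 1,
                    dimnames = list(NULL, paste0("z", seq_len(k - 1)))))
  beta <- runif(k, -1, 1)
  y <- rbinom(n, 1, plogis(drop(x %*% beta)))
  # guarantee both classes
  if (all(y == y[1])) y[1:2] <- c(0L, 1L)
  list(x = x, y = y, beta = beta)
}

# --- oracles ------------------------------------------------------------

# exhaustive pairwise enumeration of the concordance statistic, ties 1/2
oracle_cstat <- function(pred, y) {
  cases <- pred[y == 1]; controls <- pred[y == 0]
  tot <- 0
  for (a in cases) for (b in controls)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cases) * length(controls))
}

# generic-optimizer logistic MLE, independent of the IRLS/Newton path
oracle_logit_coef <- function(x, y) {
  nll <- function(b) {
    p <- plogis(drop(x %*% b))
    -sum(dbinom(y, 1, p, log = TRUE))
  }
  fit <- optim(rep(0, ncol(x)), nll, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-15))
  fit$par
}

# finite-difference score and Hessian of the Bernoulli log-likelihood
oracle_loglik_i <- function(x, y, beta) {
  dbinom(y, 1, plogis(drop(x %*% beta)), log = TRUE)
}

oracle_score_i <- function(x, y, beta, h = 1e-6) {
  k <- length(beta)
  out <- matrix(0, nrow(x), k)
  for (j in seq_len(k)) {
    bp <- beta; bp[j] <- bp[j] + h
    bm <- beta; bm[j] <- bm[j] - h
    out[, j] <- (oracle_loglik_i(x, y, bp) - oracle_loglik_i(x, y, bm)) / (2 * h)
  }
  out
}

oracle_hessian <- function(x, y, beta, h = 1e-5) {
  k <- length(beta)
  H <- matrix(0, k, k)
  for (j in seq_len(k)) {
    bp <- beta; bp[j] <- bp[j] + h
    bm <- beta; bm[j] <- bm[j] - h
    H[, j] <- (colSums(oracle_score_i(x, y, bp)) -
               colSums(oracle_score_i(x, y, bm))) / (2 * h)
  }
  (H + t(H)) / 2
}

# full two-step Vuong quantities recomputed from numerically-differentiated
# log-likelihoods at optim()-based MLEs; independent of the package path
oracle_vuong <- function(xa, xb, y) {
  ba <- oracle_logit_coef(xa, y)
  bb <- oracle_logit_coef(xb, y)
  m <- oracle_loglik_i(xa, y, ba) - oracle_loglik_i(xb, y, bb)
  n <- length(m)
  omega2 <- mean(m^2) - mean(m)^2
  sa <- oracle_score_i(xa, y, ba); sb <- oracle_score_i(xb, y, bb)
  Aa <- oracle_hessian(xa, y, ba) / n
  Ab <- oracle_hessian(xb, y, bb) / n
  Ba <- crossprod(sa) / n; Bb <- crossprod(sb) / n
  Bab <- crossprod(sa, sb) / n
  W <- rbind(cbind(-Ba %*% solve(Aa), -Bab %*% solve(Ab)),
             cbind(t(Bab) %*% solve(Aa), Bb %*% solve(Ab)))
  list(
    omega2 = omega2,
    omega_stat = n * omega2,
    lambda = sort(Re(eigen(W, only.values = TRUE)$values)),
    z = sum(m) / (sqrt(n) * sqrt(omega2))
  )
}

# convenience: fit a raw-matrix logistic model as an ace_fit
matrix_fit <- function(x, y, label = "m") ace_logit(x, data = y, label = label)

# simulate a pair of single-noise-predictor fits under a null outcome
simulate_null_pair <- function(n, seed) {
  set.seed(seed)
  x1 <- rbinom(n, 1, 0.4)
  x2 <- rbinom(n, 1, 0.4)
  y <- rbinom(n, 1, 0.5)
  list(a = matrix_fit(cbind(1, x1), y, "noise model A"),
       b = matrix_fit(cbind(1, x2), y, "noise model B"))
}
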