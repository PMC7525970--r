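test_that("intercept-only fit reproduces the closed-form log odds", {
  y <- c(rep(1, 30), rep(0, 70))
  fit <- null_logit(y)
  expect_equal(unname(coef(fit)), log(0.3 / 0.7), tolerance = 1e-10)
  expect_true(fit$converged)
})

test_that("the 2x2 slope equals the closed-form log odds ratio", {
  # 20 exposed cases, 10 exposed controls, 10 unexposed cases, 20 unexposed
  # controls: slope = ln((20*20)/(10*10)) = ln 4
  x <- cbind(1, exposed = rep(c(1, 0), each = 30))
  y <- c(rep(1, 20), rep(0, 10), rep(1, 10), rep(0, 20))
  fit <- fit_logistic(x, y)
  expect_equal(unname(fit$coefficients["exposed"]), log(4), tolerance = 1e-6)
})

test_that("degenerate and separated outcomes are hard errors", {
  x <- cbind(1, rnorm(20))
  expect_error(fit_logistic(x, rep(0, 20)), "degenerate")
  expect_error(fit_logistic(x, rep(1, 20)), "degenerate")
  # complete separation: predictor perfectly splits the outcome
  xs <- cbind(1, c(rep(0, 15), rep(1, 15)))
  ys <- c(rep(0, 15), rep(1, 15))
  expect_error(fit_logistic(xs, ys), "separation")
})

test_that("coefficients match a generic numerical optimizer on random data", {
  for (i in 1:20) {
    dat <- make_random_logit_data(n = sample(40:200, 1), k = sample(2:6, 1),
                                  seed = 1000 + i)
    fit <- tryCatch(fit_logistic(dat$x, dat$y), error = function(e) NULL)
    if (is.null(fit)) next  # separation on a tiny draw: legitimately refused
    expect_equal(unname(fit$coefficients),
                 oracle_logit_coef(dat$x, dat$y), tolerance = 1e-6)
  }
})

test_that("per-observation pieces are internally consistent", {
  dat <- make_random_logit_data(n = 300, k = 4, seed = 7)
  fit <- fit_logistic(dat$x, dat$y)
  # log-likelihood contributions sum to the total
  expect_equal(sum(fit$loglik_i), fit$loglik_total, tolerance = 1e-8)
  # score equation: columns of the score sum to ~0; with an intercept the
  # mean fitted probability equals the observed prevalence
  expect_lt(sqrt(sum(colSums(fit$score_i)^2)), 1e-8)
  expect_equal(mean(fit$fitted), mean(dat$y), tolerance = 1e-10)
  # score and Hessian agree with finite differences of the log-likelihood
  expect_equal(fit$score_i,
               oracle_score_i(dat$x, dat$y, fit$coefficients),
               tolerance = 1e-5, ignore_attr = TRUE)
  expect_equal(fit$hessian,
               -oracle_hessian(dat$x, dat$y, fit$coefficients),
               tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("adding a column never decreases the log-likelihood", {
  for (i in 1:10) {
    dat <- make_random_logit_data(n = 150, k = 3, seed = 2000 + i)
    set.seed(3000 + i)
    extra <- cbind(dat$x, new = rnorm(150))
    f_small <- fit_logistic(dat$x, dat$y)
    f_big <- fit_logistic(extra, dat$y)
    expect_gte(f_big$loglik_total, f_small$loglik_total - 1e-10)
  }
})

test_that("fit metrics satisfy their defining identities", {
  dat <- make_random_logit_data(n = 400, k = 4, seed = 11)
  fit <- matrix_fit(dat$x, dat$y)
  nul <- null_logit(dat$y)
  m <- fit_metrics(fit, nul)
  expect_equal(m$aic, -2 * fit$loglik_total + 2 * fit$k, tolerance = 1e-8)
  l0 <- nul$loglik_total; l1 <- fit$loglik_total; n <- fit$n
  expect_equal(m$r2_cox_snell, 1 - exp(2 * (l0 - l1) / n), tolerance = 1e-8)
  expect_equal(m$r2_nagelkerke,
               (1 - exp(2 * (l0 - l1) / n)) / (1 - exp(2 * l0 / n)),
               tolerance = 1e-8)
  expect_gte(m$r2_nagelkerke, 0); expect_lte(m$r2_nagelkerke, 1)
  # a model identical to the null explains nothing
  m0 <- fit_metrics(nul, nul)
  expect_equal(m0$r2_nagelkerke, 0, tolerance = 1e-12)
  # mismatched rows are rejected
  expect_error(fit_metrics(fit, null_logit(dat$y[-1])), "same rows")
})

test_that("the c-statistic matches exhaustive pair enumeration", {
  expect_equal(c_statistic(c(0.9, 0.8, 0.7, 0.4, 0.2), c(1, 1, 0, 1, 0)),
               5 / 6, tolerance = 1e-12)
  expect_equal(c_statistic(rep(0.4, 10), rep(c(0, 1), 5)), 0.5)
  set.seed(42)
  for (i in 1:25) {
    n <- sample(5:30, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    p <- round(runif(n), 2)  # coarse grid to force ties
    expect_equal(c_statistic(p, y), oracle_cstat(p, y), tolerance = 1e-12)
    # invariance under strictly increasing transforms
    expect_equal(c_statistic(qlogis(p / 1.01 + 0.001), y),
                 c_statistic(p, y), tolerance = 1e-12)
  }
})

test_that("the c-statistic agrees with an established AUC implementation", {
  set.seed(99)
  y <- rbinom(200, 1, 0.4)
  p <- plogis(rnorm(200) + y)
  auc <- as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE,
                                        direction = "<")))
  expect_equal(c_statistic(p, y), auc, tolerance = 1e-12)
})

test_that("variance inflation factors match closed forms", {
  y <- rep(c(0, 1, 1, 0), 15)
  # mutually orthogonal, mean-zero columns: VIF = 1
  x <- cbind(1, a = rep(c(1, -1), 30), b = rep(c(1, 1, -1, -1), 15))
  design <- structure(list(
    y = y, x = x, n = 60L, k = 3L, spec = NULL, label = "orthogonal",
    ace_cols = 2:3, score = NULL, outcome = NA_character_,
    covariates = character(0)), class = "ace_design")
  fit <- ace_logit(design)
  expect_equal(unname(vif_ace(fit)), c(1, 1), tolerance = 1e-10)

  # two correlated columns, no covariates: VIF = 1 / (1 - r^2)
  set.seed(5)
  a <- rnorm(200); b <- 0.6 * a + sqrt(1 - 0.36) * rnorm(200)
  x2 <- cbind(1, a = a, b = b)
  y2 <- rbinom(200, 1, 0.5)
  design2 <- design
  design2$y <- y2; design2$x <- x2; design2$n <- 200L
  fit2 <- ace_logit(design2)
  r <- cor(a, b)
  expect_equal(unname(vif_ace(fit2)), rep(1 / (1 - r^2), 2),
               tolerance = 1e-10)

  # a duplicated column is reported as infinite, by name
  fit3 <- fit2
  fit3$x <- cbind(fit2$x, dup_a = fit2$x[, "a"])
  fit3$ace_cols <- 4L
  expect_warning(v <- vif_ace(fit3), "dup_a")
  expect_true(is.infinite(v[["dup_a"]]))
})

test_that("ace_fit methods behave like standard modelling accessors", {
  d <- simulate_ace_data(ace_sim_config(
    n = 1500, seed = 13,
    truth = truth_spec("cr_linear", intercept = -1, score_beta = 0.2)))
  fit <- ace_logit(predictor_spec("CRCn"), data = d)
  expect_s3_class(fit, "ace_fit")
  expect_equal(length(coef(fit)), fit$k)
  expect_equal(dim(vcov(fit)), c(fit$k, fit$k))
  expect_equal(as.numeric(logLik(fit)), fit$loglik_total)
  expect_equal(attr(logLik(fit), "df"), fit$k)
  expect_equal(predict(fit), fit$fitted)
  expect_equal(predict(fit, type = "link"), qlogis(fit$fitted),
               tolerance = 1e-10)
  expect_equal(residuals(fit, "response"), fit$y - fit$fitted)
  expect_equal(sum(residuals(fit, "deviance")^2), -2 * fit$loglik_total,
               tolerance = 1e-8)
  sm <- summary(fit)
  expect_equal(sm$coefficients$or, exp(sm$coefficients$estimate))
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(fit$n, 3))
  expect_true(all(unlist(sims) %in% 0:1))
})
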