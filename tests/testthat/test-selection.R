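test_that("candidate enumeration covers exactly the coding permutations", {
  mir <- enumerate_candidates("MIR")
  crcat <- enumerate_candidates("CRCat")
  crcn <- enumerate_candidates("CRCn")
  expect_length(mir, 4)
  expect_length(crcat, 4)
  expect_length(crcn, 8)
  expect_true(any(vapply(crcn, function(s) s$quadratic, logical(1))))
  key <- function(s) paste(s$family, s$items, s$threshold, s$quadratic)
  for (lst in list(mir, crcat, crcn))
    expect_equal(anyDuplicated(vapply(lst, key, character(1))), 0L)
})

test_that("a single candidate is returned unchanged with an empty trail", {
  dat <- make_random_logit_data(n = 100, k = 2, seed = 3)
  fit <- matrix_fit(dat$x, dat$y, "only")
  sel <- select_within(list(fit))
  expect_identical(sel$best, fit)
  expect_equal(nrow(sel$trail), 0)
  expect_false(sel$by_aic)
})

test_that("with step one forced silent, selection is pure AIC with margin flag", {
  # alpha = 0: the variance test can never reject, so every decision falls
  # through to the AIC rule
  dat <- make_random_logit_data(n = 500, k = 3, seed = 21)
  set.seed(22)
  junk <- matrix(rnorm(500 * 40), 500)
  colnames(junk) <- paste0("junk", 1:40)
  f_lean <- matrix_fit(dat$x, dat$y, "lean")
  f_bloat <- matrix_fit(cbind(dat$x, junk), dat$y, "bloated")
  aic <- function(f) -2 * f$loglik_total + 2 * f$k

  sel <- select_within(list(f_bloat, f_lean), alpha = 0)
  expect_equal(sel$best$label,
               if (aic(f_lean) < aic(f_bloat)) "lean" else "bloated")
  expect_equal(sel$trail$rule, "aic")
  expect_true(sel$by_aic)
  expect_equal(sel$trail$substantial,
               abs(aic(f_lean) - aic(f_bloat)) > 50)
  # identical fits tie on AIC; the tie goes to fewer parameters
  sel_tie <- select_within(list(f_bloat, f_bloat, f_lean), alpha = 0)
  expect_equal(sel_tie$trail$winner[1], "bloated")
  expect_equal(sel_tie$best$label, "lean")
})

test_that("a significant closeness verdict overrides the AIC rule", {
  # alpha = 1: step one always "rejects", step two always decides by sign
  dat <- make_random_logit_data(n = 400, k = 2, seed = 31)
  set.seed(32)
  x_noise <- cbind(dat$x[, 1, drop = FALSE], u = rnorm(400))
  y <- rbinom(400, 1, plogis(dat$x %*% c(-0.3, 1.5)))
  f_true <- matrix_fit(dat$x, y, "true model")
  f_noise <- matrix_fit(x_noise, y, "noise model")
  sel <- select_within(list(f_noise, f_true), alpha = 1)
  expect_equal(sel$trail$rule, "vuong")
  expect_equal(sel$best$label, "true model")
  expect_false(sel$by_aic)
})

test_that("the decision trail is exhaustive over candidates", {
  d <- simulate_ace_data(ace_sim_config(
    n = 2500, seed = 61,
    truth = truth_spec("cr_linear", intercept = -1.2, score_beta = 0.22)))
  fits <- lapply(enumerate_candidates("CRCn"), ace_logit, data = d)
  sel <- select_within(fits, alpha = 0.05)
  labels <- vapply(fits, function(f) f$label, character(1))
  seen <- unique(c(sel$trail$champion, sel$trail$challenger))
  expect_true(all(labels %in% seen))
  expect_true(sel$best$label %in% labels)
})

test_that("the full workflow is reproducible and structurally complete", {
  d <- simulate_ace_data(ace_sim_config(
    n = 3000, seed = 71, missing_rate = 0.01,
    truth = truth_spec("mir", intercept = -1.5,
                       mir_betas = c(1, 0.5, 0, 0.8, 0.2, 0, 0.6,
                                     0.4, 0, 0.7, 0.3))))
  sel1 <- run_ace_selection(d)
  sel2 <- run_ace_selection(d)

  expect_s3_class(sel1, "ace_selection")
  expect_identical(sel1$overall_best, sel2$overall_best)
  expect_equal(sel1$comparison_matrix$aic, sel2$comparison_matrix$aic)
  z1 <- vapply(sel1$comparison_matrix$comparisons, `[[`, numeric(1), "z")
  z2 <- vapply(sel2$comparison_matrix$comparisons, `[[`, numeric(1), "z")
  expect_identical(z1, z2)

  # exactly one best fit per family, with metrics
  expect_named(sel1$best_fits, c("MIR", "CRCat", "CRCn"))
  expect_named(sel1$metrics, c("MIR", "CRCat", "CRCn"))
  # comparison matrix holds all pairs of baseline + three bests
  expect_length(sel1$comparison_matrix$comparisons, 6)
  # screening happened and is logged
  expect_equal(sel1$screen_log$n_retained, sel1$n)
  # the MIR truth is detected on this dataset
  expect_match(sel1$overall_best, "^MIR")
  # baseline is never best while ACE models beat it significantly
  base_cmps <- sel1$comparison_matrix$comparisons[
    grep("vs Baseline$", names(sel1$comparison_matrix$comparisons))]
  expect_true(all(vapply(base_cmps, function(cmp)
    cmp$p_omega < 0.05, logical(1))))
  expect_false(identical(sel1$overall_best, "Baseline (covariates only)"))
})

test_that("MIR odds-ratio table has the reported shape and content", {
  d <- simulate_ace_data(ace_sim_config(
    n = 4000, seed = 81,
    truth = truth_spec("mir", intercept = -1.3,
                       mir_betas = c(1, rep(0, 10)))))
  fit <- ace_logit(predictor_spec("MIR"), data = d)
  tab <- mir_or_table(fit, d)
  expect_equal(nrow(tab), 11)
  expect_equal(tab$item, gsub(" ", "_", ace_item_labels()))
  expect_length(attr(tab, "vif_range"), 2)
  expect_true(all(attr(tab, "vif_range") >= 1))
  # items correlated with the causal one look inflated before adjustment
  expect_gt(tab$unadjusted_or[2], tab$adjusted_or[2])
  # the causal item is significant both ways
  expect_true(tab$adjusted_sig[1] && tab$unadjusted_sig[1])
})

test_that("a one-item MIR fit has identical adjusted and unadjusted ORs", {
  d <- simulate_ace_data(ace_sim_config(
    n = 2000, seed = 82,
    truth = truth_spec("mir", intercept = -1,
                       mir_betas = c(0.8, rep(0, 10)))))
  full <- build_design(predictor_spec("MIR"), d)
  keep <- c(setdiff(seq_len(full$k), full$ace_cols), full$ace_cols[1])
  design1 <- structure(list(
    y = full$y, x = full$x[, keep], n = full$n, k = length(keep),
    spec = predictor_spec("MIR"), label = "MIR, single item",
    ace_cols = length(keep), score = NULL, outcome = full$outcome,
    covariates = full$covariates), class = "ace_design")
  fit1 <- ace_logit(design1)
  tab <- mir_or_table(fit1, d)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$adjusted_or, tab$unadjusted_or, tolerance = 1e-10)
  expect_equal(tab$adjusted_p, tab$unadjusted_p, tolerance = 1e-8)
})

test_that("selection reports are written as delimited text plus JSON", {
  d <- simulate_ace_data(ace_sim_config(
    n = 2000, seed = 91,
    truth = truth_spec("cr_linear", intercept = -1.2, score_beta = 0.2)))
  sel <- run_ace_selection(d)
  dir <- file.path(tempdir(), "aceselect_report")
  paths <- write_selection_report(sel, dir)
  expect_true(all(file.exists(paths)))
  best <- read.delim(paths[1])
  expect_equal(best$family, c("MIR", "CRCat", "CRCn"))
  mat <- read.delim(paths[2])
  expect_equal(nrow(mat), 6)
  mir <- read.delim(paths[3])
  expect_equal(nrow(mir), sel$best_fits$MIR$spec$items)
  trail <- jsonlite::read_json(paths[4])
  expect_equal(trail$overall_best, sel$overall_best)
  unlink(dir, recursive = TRUE)
})
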