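#' Enumerate candidate characterizations within a family
#'
#' All coding permutations considered within a family: exposure threshold
#' ('once' vs 'more than once') crossed with item count (11 vs 9), and --
#' for the continuous score only -- presence of a quadratic term. Hence 4
#' candidates for CRCat and MIR and 8 for CRCn. The enumeration order is
#' also the champion-versus-challenger iteration order used by
#' [select_within()].
#'
#' @param family `"CRCn"`, `"CRCat"` or `"MIR"`.
#' @return List of [predictor_spec()] objects.
#' @export
#' @examples
#' length(enumerate_candidates("CRCn"))  # 8
enumerate_candidates <- function(family = c("CRCn", "CRCat", "MIR")) {
  family <- match.arg(family)
  grid <- expand.grid(
    items = c(11L, 9L), threshold = c("once", "more_than_once"),
    quadratic = if (family == "CRCn") c(FALSE, TRUE) else FALSE,
    stringsAsFactors = FALSE
  )
  lapply(seq_len(nrow(grid)), function(i)
    predictor_spec(family, items = grid$items[i],
                   threshold = grid$threshold[i],
                   quadratic = grid$quadratic[i]))
}

#' Iterative within-category selection with AIC fallback
#'
#' Champion-versus-challenger over the supplied fits (in order): each pair
#' is compared with the two-step Vuong procedure; a significant closeness
#' verdict decides the pair, otherwise the smaller AIC decides, flagged
#' "substantial" when the AIC difference exceeds `aic_margin`; AIC ties
#' within numerical tolerance go to the model with fewer parameters.
#'
#' @param fits List of [ace_logit()] fits on identical rows.
#' @param alpha Significance level for the Vuong steps.
#' @param aic_margin AIC difference treated as substantial support
#'   (default 50).
#' @param method,mc_draws,seed Tail controls passed to [vuong_compare()].
#' @return List with `best` (the winning fit), `trail` (data frame logging
#'   every comparison and the rule that resolved it) and `by_aic` (TRUE
#'   when any decision fell back to AIC).
#' @export
select_within <- function(fits, alpha = 0.05, aic_margin = 50,
                          method = "imhof", mc_draws = 1e6, seed = NULL) {
  stopifnot(length(fits) >= 1)
  aic <- function(f) -2 * f$loglik_total + 2 * f$k
  champ <- fits[[1]]
  trail <- list()
  by_aic <- FALSE
  for (cand in fits[-1]) {
    cmp <- vuong_compare(champ, cand, alpha = alpha, method = method,
                         mc_draws = mc_draws, seed = seed)
    d_aic <- aic(champ) - aic(cand)
    if (cmp$verdict %in% c("a_better", "b_better")) {
      rule <- "vuong"
      winner <- if (cmp$verdict == "a_better") champ else cand
      substantial <- NA
    } else {
      rule <- "aic"
      by_aic <- TRUE
      winner <- if (abs(d_aic) <= 1e-8) {
        if (champ$k <= cand$k) champ else cand   # tie: fewer parameters
      } else if (d_aic > 0) cand else champ
      substantial <- abs(d_aic) > aic_margin
    }
    trail[[length(trail) + 1L]] <- data.frame(
      champion = champ$label, challenger = cand$label,
      verdict = cmp$verdict, p_omega = cmp$p_omega,
      z = cmp$z, p_z = cmp$p_z,
      aic_champion = aic(champ), aic_challenger = aic(cand),
      rule = rule, substantial = substantial,
      winner = winner$label, stringsAsFactors = FALSE
    )
    champ <- winner
  }
  trail <- if (length(trail)) do.call(rbind, trail) else
    data.frame(champion = character(), challenger = character(),
               verdict = character(), p_omega = numeric(), z = numeric(),
               p_z = numeric(), aic_champion = numeric(),
               aic_challenger = numeric(), rule = character(),
               substantial = logical(), winner = character(),
               stringsAsFactors = FALSE)
  list(best = champ, trail = trail, by_aic = by_aic)
}

fit_crcat_with_cell_check <- function(spec, data, outcome, covariates,
                                      min_cell) {
  expo <- code_exposures(data, spec$threshold)
  if (spec$items == 9L) expo <- collapse_to_nine(expo)
  if (is.null(spec$scheme)) {
    rep_cc <- check_cell_counts(expo$score, data[[outcome]],
                                covariates = data[covariates],
                                min_count = min_cell)
    if (nrow(rep_cc$flags) && !is.null(rep_cc$proposed_scheme))
      spec <- predictor_spec("CRCat", items = spec$items,
                             threshold = spec$threshold,
                             scheme = rep_cc$proposed_scheme)
  }
  ace_logit(spec, data = data, outcome = outcome, covariates = covariates)
}

#' Run the full characterization-selection workflow for one outcome
#'
#' Orchestrates the entire analysis for a single binary outcome:
#' screening; a covariate-only baseline fit; enumeration and fitting of all
#' candidate characterizations in each family (with automatic top-category
#' collapse of the categorical score whenever a score-by-outcome or
#' score-by-covariate cell falls below `min_cell`); within-family selection
#' via [select_within()]; a full pairwise comparison matrix of baseline and
#' the three family bests; an overall winner by the same
#' champion-versus-challenger rule; and the MIR odds-ratio table.
#'
#' @param data Response table (screened internally when `screen = TRUE`).
#' @param outcome Outcome column name.
#' @param covariates Covariate column names.
#' @param alpha Significance level for all Vuong steps.
#' @param aic_margin Substantial-AIC rule of thumb (default 50).
#' @param method Weighted-chi-square tail method; the workflow defaults to
#'   the deterministic `"imhof"` inversion (the single-test default is
#'   Monte Carlo).
#' @param mc_draws,seed Tail controls for `method = "mc"`.
#' @param screen Run [screen_responses()] first (default TRUE).
#' @param min_cell Minimum cross-tab cell count (default 20).
#' @return An object of class `"ace_selection"`.
#' @export
#' @examples
#' \donttest{
#' cfg <- ace_sim_config(n = 2000, truth = truth_spec("cr_linear",
#'   intercept = -1.2, score_beta = 0.22), seed = 42)
#' sel <- run_ace_selection(simulate_ace_data(cfg))
#' sel
#' }
run_ace_selection <- function(data, outcome = "outcome",
                              covariates = ace_covariates(), alpha = 0.05,
                              aic_margin = 50, method = "imhof",
                              mc_draws = 1e6, seed = NULL, screen = TRUE,
                              min_cell = 20) {
  screen_log <- NULL
  if (screen) {
    s <- screen_responses(data, covariates = covariates, outcome = outcome)
    data <- s$data
    screen_log <- s$log
  }
  baseline <- ace_logit(NULL, data = data, outcome = outcome,
                        covariates = covariates)
  null_fit <- null_logit(baseline)

  families <- c("MIR", "CRCat", "CRCn")
  best <- list(); trails <- list(); metrics <- list(); by_aic <- list()
  for (fam in families) {
    specs <- enumerate_candidates(fam)
    fits <- lapply(specs, function(sp) {
      if (fam == "CRCat")
        fit_crcat_with_cell_check(sp, data, outcome, covariates, min_cell)
      else
        ace_logit(sp, data = data, outcome = outcome, covariates = covariates)
    })
    sel <- select_within(fits, alpha = alpha, aic_margin = aic_margin,
                         method = method, mc_draws = mc_draws, seed = seed)
    best[[fam]] <- sel$best
    trails[[fam]] <- sel$trail
    by_aic[[fam]] <- sel$by_aic
    metrics[[fam]] <- fit_metrics(sel$best, null_fit)
  }

  # between-category comparison matrix: baseline + three family bests
  mat_fits <- c(list(Baseline = baseline), best)
  labels <- names(mat_fits)
  comparisons <- list()
  nested_warned <- FALSE
  for (i in seq_along(mat_fits)) for (j in seq_len(i - 1L)) {
    # column model j (earlier), row model i (later); positive z favors column
    cmp <- withCallingHandlers(
      vuong_compare(mat_fits[[j]], mat_fits[[i]], alpha = alpha,
                    method = method, mc_draws = mc_draws, seed = seed,
                    nested = (j == 1L)),
      warning = function(w) {
        if (grepl("nested pair", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    comparisons[[paste(labels[i], labels[j], sep = " vs ")]] <- cmp
  }
  matrix_obj <- structure(list(labels = labels,
                               aic = vapply(mat_fits, function(f)
                                 -2 * f$loglik_total + 2 * f$k, numeric(1)),
                               comparisons = comparisons, alpha = alpha),
                          class = "vuong_matrix")

  overall <- select_within(mat_fits, alpha = alpha, aic_margin = aic_margin,
                           method = method, mc_draws = mc_draws, seed = seed)

  mir_table <- mir_or_table(best$MIR, data, outcome = outcome,
                            covariates = covariates, alpha = alpha)

  structure(list(
    outcome = outcome, screen_log = screen_log, n = baseline$n,
    baseline = baseline, best_fits = best, metrics = metrics,
    by_aic = by_aic, within_trails = trails,
    comparison_matrix = matrix_obj,
    overall_best = overall$best$label, overall_trail = overall$trail,
    mir_table = mir_table, alpha = alpha
  ), class = "ace_selection")
}

#' MIR odds-ratio table with per-item unadjusted companions
#'
#' For each ACE item in the best MIR fit: the adjusted odds ratio from the
#' joint fit (each item adjusted for the others and the covariates), and an
#' "unadjusted" odds ratio from a model containing only that item plus the
#' covariates. A VIF range over the ACE columns summarizes
#' multicollinearity.
#'
#' @param mir_fit The selected MIR [ace_logit()] fit.
#' @param data The screened data the fit was estimated on.
#' @param outcome,covariates Column names, as in [run_ace_selection()].
#' @param alpha Significance level for the star annotations.
#' @return Data frame of class `"mir_or_table"` with one row per item and
#'   attribute `vif_range`.
#' @export
mir_or_table <- function(mir_fit, data, outcome = "outcome",
                         covariates = ace_covariates(), alpha = 0.05) {
  stopifnot(inherits(mir_fit, "ace_fit"),
            !is.null(mir_fit$spec), mir_fit$spec$family == "MIR")
  idx <- mir_fit$ace_cols
  labels <- colnames(mir_fit$x)[idx]
  est <- mir_fit$coefficients[idx]
  se <- mir_fit$se[idx]
  p_adj <- 2 * stats::pnorm(-abs(est / se))

  x_cov <- mir_fit$x[, -idx, drop = FALSE]
  un_or <- un_p <- numeric(length(idx))
  for (i in seq_along(idx)) {
    xi <- cbind(x_cov, mir_fit$x[, idx[i], drop = FALSE])
    f1 <- fit_logistic(xi, mir_fit$y)
    b <- f1$coefficients[ncol(xi)]
    un_or[i] <- exp(b)
    un_p[i] <- 2 * stats::pnorm(-abs(b / f1$se[ncol(xi)]))
  }
  out <- data.frame(
    item = sub("^ace_", "", labels),
    adjusted_or = exp(est),
    adjusted_low = exp(est - stats::qnorm(0.975) * se),
    adjusted_high = exp(est + stats::qnorm(0.975) * se),
    adjusted_p = p_adj,
    adjusted_sig = p_adj < alpha,
    unadjusted_or = un_or,
    unadjusted_p = un_p,
    unadjusted_sig = un_p < alpha,
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "vif_range") <- range(vif_ace(mir_fit))
  class(out) <- c("mir_or_table", "data.frame")
  out
}

#' @export
print.mir_or_table <- function(x, digits = 2, ...) {
  df <- as.data.frame(x)
  show <- data.frame(
    item = df$item,
    adjusted = paste0(fmt_num(df$adjusted_or, digits),
                      sig_stars(df$adjusted_p)),
    unadjusted = paste0(fmt_num(df$unadjusted_or, digits),
                        sig_stars(df$unadjusted_p))
  )
  print(show, row.names = FALSE)
  vr <- attr(x, "vif_range")
  cat("VIF range:", fmt_num(vr[1], 2), "-", fmt_num(vr[2], 2), "\n")
  invisible(x)
}

#' @export
print.vuong_matrix <- function(x, ...) {
  k <- length(x$labels)
  cells <- matrix("", k, k, dimnames = list(x$labels, x$labels))
  diag(cells) <- "1"
  for (i in seq_len(k)) for (j in seq_len(i - 1L)) {
    cmp <- x$comparisons[[paste(x$labels[i], x$labels[j], sep = " vs ")]]
    top <- paste0(fmt_num(cmp$omega2, 3), sig_stars(cmp$p_omega))
    bottom <- if (cmp$verdict == "indistinguishable") "--"
      else if (cmp$verdict == "distinguishable_equal_fit") "NDF"
      else paste0(fmt_num(cmp$z, 2), sig_stars(cmp$p_z))
    cells[i, j] <- paste0(top, " | ", bottom)
  }
  cat("Model comparison matrix (per cell: omega2 | z;",
      "positive z favors the column model):\n")
  out <- cbind(AIC = formatC(x$aic, format = "f", digits = 1), cells)
  print(out, quote = FALSE)
  cat("Stars: * p<.05, ** p<.01, *** p<.001. NDF = distinguishable,",
      "non-different fit. -- = indistinguishable.\n")
  invisible(x)
}

#' @export
print.ace_selection <- function(x, ...) {
  cat("ACE characterization selection for outcome '", x$outcome, "' (n = ",
      x$n, ")\n\n", sep = "")
  cat("Best fit within each family:\n")
  for (fam in names(x$best_fits)) {
    m <- x$metrics[[fam]]
    cat(sprintf("  %-6s %-45s R2 = %s  AIC = %s  c = %s%s\n", fam,
                x$best_fits[[fam]]$label, fmt_num(m$r2_nagelkerke),
                formatC(m$aic, format = "f", digits = 1),
                fmt_num(m$c_stat),
                if (isTRUE(x$by_aic[[fam]])) "  (by AIC)" else ""))
  }
  cat("\n")
  print(x$comparison_matrix)
  cat("\nOverall best:", x$overall_best, "\n\n")
  cat("MIR odds ratios (adjusted | unadjusted per item):\n")
  print(x$mir_table)
  invisible(x)
}

#' @export
summary.ace_selection <- function(object, ...) object

#' Write the selection report as delimited tables plus a JSON trail
#'
#' Writes four text artifacts into `dir`: `best_fits.tsv` (per-family best
#' fit and metrics), `comparison_matrix.tsv` (pairwise omega-squared, z and
#' verdicts), `mir_or_table.tsv`, and `decision_trail.json` (every within-
#' and between-family comparison and the rule that resolved it).
#'
#' @param report An [run_ace_selection()] result.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_selection_report <- function(report, dir) {
  stopifnot(inherits(report, "ace_selection"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  best <- do.call(rbind, lapply(names(report$best_fits), function(fam) {
    m <- report$metrics[[fam]]
    data.frame(family = fam, best_fit = report$best_fits[[fam]]$label,
               r2_nagelkerke = m$r2_nagelkerke, aic = m$aic,
               c_stat = m$c_stat, by_aic = isTRUE(report$by_aic[[fam]]),
               stringsAsFactors = FALSE)
  }))
  p1 <- file.path(dir, "best_fits.tsv")
  utils::write.table(best, p1, sep = "\t", row.names = FALSE, quote = FALSE)

  cmps <- report$comparison_matrix$comparisons
  mat <- do.call(rbind, lapply(names(cmps), function(nm) {
    c0 <- cmps[[nm]]
    data.frame(pair = nm, column_model = c0$model_a, row_model = c0$model_b,
               omega2 = c0$omega2, omega_stat = c0$omega_stat,
               p_omega = c0$p_omega, z = c0$z, p_z = c0$p_z,
               verdict = c0$verdict, stringsAsFactors = FALSE)
  }))
  p2 <- file.path(dir, "comparison_matrix.tsv")
  utils::write.table(mat, p2, sep = "\t", row.names = FALSE, quote = FALSE)

  p3 <- file.path(dir, "mir_or_table.tsv")
  mt <- as.data.frame(report$mir_table)
  mt$vif_min <- attr(report$mir_table, "vif_range")[1]
  mt$vif_max <- attr(report$mir_table, "vif_range")[2]
  utils::write.table(mt, p3, sep = "\t", row.names = FALSE, quote = FALSE)

  p4 <- file.path(dir, "decision_trail.json")
  jsonlite::write_json(list(
    outcome = report$outcome, n = report$n,
    screening = report$screen_log,
    within_family = report$within_trails,
    overall = report$overall_trail,
    overall_best = report$overall_best
  ), p4, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")

  invisible(c(p1, p2, p3, p4))
}
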