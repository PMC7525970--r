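#' Generating truth for synthetic outcomes
#'
#' Describes the data-generating adversity-outcome relationship used by
#' [generate_outcomes()]. Exactly one of four modes is declared:
#'
#' * `"null"` -- no adversity effect; the outcome depends only on the
#'   intercept and any covariate effects.
#' * `"mir"` -- each of the 11 binary exposures has its own log odds ratio
#'   (`mir_betas`, length 11, ordered as [ace_item_labels()]).
#' * `"cr_linear"` -- the outcome depends on the exposure count through
#'   `score_beta` (log-OR per additional exposure) and optionally
#'   `score_beta2` (log-OR per squared count unit).
#' * `"cr_categorical"` -- `step_effects[s]` is the log-OR of score `s`
#'   versus score 0; scores beyond `length(step_effects)` receive the last
#'   element.
#'
#' @param mode One of `"null"`, `"mir"`, `"cr_linear"`, `"cr_categorical"`.
#' @param intercept Log-odds of the outcome at reference covariates and no
#'   adversity. Default 0.
#' @param covariate_effects Optional named list; one numeric vector per
#'   covariate giving log-ORs for its non-reference levels (named by level).
#'   Covariates omitted from the list have no effect.
#' @param mir_betas Numeric length 11 (mode `"mir"` only).
#' @param score_beta,score_beta2 Numeric scalars (mode `"cr_linear"` only).
#' @param step_effects Numeric vector, element `s` = log-OR of score `s`
#'   versus 0 (mode `"cr_categorical"` only).
#' @return An object of class `"truth_spec"`.
#' @export
#' @examples
#' truth_spec("cr_linear", intercept = -1, score_beta = 0.2)
truth_spec <- function(mode = c("null", "mir", "cr_linear", "cr_categorical"),
                       intercept = 0, covariate_effects = NULL,
                       mir_betas = NULL, score_beta = NULL, score_beta2 = 0,
                       step_effects = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(intercept), length(intercept) == 1)
  used <- switch(mode,
    null = list(),
    mir = {
      if (is.null(mir_betas) || length(mir_betas) != 11 || anyNA(mir_betas))
        stop("mode 'mir' requires `mir_betas` of length 11", call. = FALSE)
      list(mir_betas = as.numeric(mir_betas))
    },
    cr_linear = {
      if (is.null(score_beta) || !is.numeric(score_beta))
        stop("mode 'cr_linear' requires numeric `score_beta`", call. = FALSE)
      list(score_beta = as.numeric(score_beta),
           score_beta2 = as.numeric(score_beta2))
    },
    cr_categorical = {
      if (is.null(step_effects) || !is.numeric(step_effects) || anyNA(step_effects))
        stop("mode 'cr_categorical' requires numeric `step_effects`", call. = FALSE)
      list(step_effects = as.numeric(step_effects))
    }
  )
  # reject fields that do not belong to the declared mode
  extra <- c(
    if (mode != "mir" && !is.null(mir_betas)) "mir_betas",
    if (mode != "cr_linear" && !is.null(score_beta)) "score_beta",
    if (mode != "cr_categorical" && !is.null(step_effects)) "step_effects"
  )
  if (length(extra))
    stop(sprintf("fields inconsistent with mode '%s': %s",
                 mode, paste(extra, collapse = ", ")), call. = FALSE)
  structure(
    c(list(mode = mode, intercept = as.numeric(intercept),
           covariate_effects = covariate_effects), used),
    class = "truth_spec"
  )
}

#' @export
print.truth_spec <- function(x, ...) {
  cat("Generating truth: mode =", x$mode, " intercept =", x$intercept, "\n")
  if (x$mode == "mir") cat("  mir_betas:", paste(fmt_num(x$mir_betas, 2), collapse = " "), "\n")
  if (x$mode == "cr_linear") cat("  score_beta:", x$score_beta, " score_beta2:", x$score_beta2, "\n")
  if (x$mode == "cr_categorical") cat("  step_effects:", paste(fmt_num(x$step_effects, 2), collapse = " "), "\n")
  invisible(x)
}

#' Default per-item response-level probabilities
#'
#' Package defaults, not estimates from any particular survey: exposure
#' probabilities (at the 'once' threshold) lie between 0.10 and 0.35 across
#' items, mimicking the typical ordering of ACE prevalences (divorce and
#' household alcoholism common; sexual-adversity items rare).
#'
#' @return List of length 11: elements 1-5 are single P(yes) values;
#'   elements 6-11 are length-3 vectors (P(never), P(once), P(more than
#'   once)) summing to 1.
#' @export
default_item_margins <- function() {
  list(
    0.18, 0.25, 0.11, 0.10, 0.28,
    c(0.82, 0.07, 0.11),
    c(0.80, 0.08, 0.12),
    c(0.67, 0.10, 0.23),
    c(0.86, 0.05, 0.09),
    c(0.89, 0.04, 0.07),
    c(0.90, 0.04, 0.06)
  )
}

#' Default covariate level probabilities
#'
#' @return Named list; one named probability vector per covariate. The first
#'   level is the reference cell downstream.
#' @export
default_covariate_margins <- function() {
  list(
    sex = c(female = 0.52, male = 0.48),
    age_group = c(a18_29 = 0.14, a30_44 = 0.22, a45_54 = 0.19,
                  a55_64 = 0.20, a65p = 0.25),
    education = c(lt_hs = 0.10, hs = 0.28, some_college = 0.31,
                  college = 0.31),
    income = c(lt15k = 0.12, i15_25k = 0.18, i25_35k = 0.14,
               i35_50k = 0.17, gt50k = 0.39),
    insurance = c(insured = 0.85, uninsured = 0.15),
    race = c(white = 0.78, black = 0.12, other = 0.10),
    marital = c(married = 0.55, div_widowed = 0.25, never_married = 0.20)
  )
}

#' Configuration of the synthetic survey generator
#'
#' Bundles every knob of the Gaussian-copula generator: item marginals,
#' latent inter-item correlation, covariate marginals, the generating truth,
#' the per-item missingness rate and the seed.
#'
#' @param n Number of respondents (>= 1).
#' @param item_margins As [default_item_margins()].
#' @param rho Either a scalar in `[0, 1)` (exchangeable latent correlation)
#'   or a full 11 x 11 symmetric positive-definite correlation matrix.
#' @param covariate_margins As [default_covariate_margins()].
#' @param truth A [truth_spec()].
#' @param missing_rate Per-item MCAR missingness probability in `[0, 1)`.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   config.
#' @param exposure_threshold Threshold used to define generative exposure
#'   ("once" by default; "more_than_once" available).
#' @param covariate_item_link Scalar in `[0, 1)`; when positive, covariate
#'   levels are drawn by thresholding a latent variable correlated with the
#'   items' standardized latent mean, inducing item-covariate confounding.
#'   0 (default) draws covariates independently of items.
#' @return An object of class `"ace_sim_config"`.
#' @export
ace_sim_config <- function(n, item_margins = default_item_margins(),
                           rho = 0.4,
                           covariate_margins = default_covariate_margins(),
                           truth = truth_spec("null"),
                           missing_rate = 0, seed = 1L,
                           exposure_threshold = "once",
                           covariate_item_link = 0) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("`n` must be a positive integer", call. = FALSE)
  if (!is.list(item_margins) || length(item_margins) != 11)
    stop("`item_margins` must be a list of length 11", call. = FALSE)
  for (j in ACE_YESNO) {
    p <- item_margins[[j]]
    if (length(p) != 1) stop(sprintf("item %d margin must be a single P(yes)", j), call. = FALSE)
    assert_prob(p, sprintf("item %d P(yes)", j))
  }
  for (j in ACE_FREQ) {
    p <- item_margins[[j]]
    if (length(p) != 3 || abs(sum(p) - 1) > 1e-12)
      stop(sprintf("item %d margin must be 3 level probabilities summing to 1", j),
           call. = FALSE)
    assert_prob(p, sprintf("item %d level probabilities", j))
  }
  if (is.matrix(rho)) {
    if (!isTRUE(all.equal(dim(rho), c(11L, 11L))) || max(abs(rho - t(rho))) > 1e-10)
      stop("`rho` matrix must be symmetric 11 x 11", call. = FALSE)
  } else {
    stopifnot(is.numeric(rho), length(rho) == 1)
    if (rho < 0 || rho >= 1) stop("scalar `rho` must lie in [0, 1)", call. = FALSE)
  }
  stopifnot(inherits(truth, "truth_spec"))
  if (missing_rate < 0 || missing_rate >= 1)
    stop("`missing_rate` must lie in [0, 1)", call. = FALSE)
  if (covariate_item_link < 0 || covariate_item_link >= 1)
    stop("`covariate_item_link` must lie in [0, 1)", call. = FALSE)
  for (nm in names(covariate_margins)) {
    p <- covariate_margins[[nm]]
    if (is.null(names(p)) || abs(sum(p) - 1) > 1e-12)
      stop(sprintf("covariate '%s' margins must be named and sum to 1", nm), call. = FALSE)
  }
  structure(list(
    n = n, item_margins = item_margins, rho = rho,
    covariate_margins = covariate_margins, truth = truth,
    missing_rate = missing_rate, seed = as.integer(seed),
    exposure_threshold = match_threshold(exposure_threshold),
    covariate_item_link = covariate_item_link
  ), class = "ace_sim_config")
}

#' @export
print.ace_sim_config <- function(x, ...) {
  cat("Synthetic survey config: n =", x$n,
      " rho =", if (is.matrix(x$rho)) "(matrix)" else x$rho,
      " missing_rate =", x$missing_rate, " seed =", x$seed, "\n")
  print(x$truth)
  invisible(x)
}

latent_correlation <- function(config) {
  if (is.matrix(config$rho)) config$rho
  else {
    R <- matrix(config$rho, 11, 11)
    diag(R) <- 1
    R
  }
}

#' Draw correlated item responses and covariates
#'
#' Items are generated from a Gaussian copula: one latent multivariate
#' normal draw per respondent, thresholded at the quantile cut-points
#' implied by the item marginals (three-level items use two ordered
#' thresholds). Covariates are drawn from their marginals, independently of
#' the items unless `covariate_item_link > 0`.
#'
#' @param config An [ace_sim_config()].
#' @return A data frame with columns `item_1` ... `item_11` (character:
#'   "yes"/"no" for items 1-5, "never"/"once"/"more_than_once" for items
#'   6-11) and one factor column per covariate. Deterministic given
#'   `config$seed`.
#' @export
generate_responses <- function(config) {
  stopifnot(inherits(config, "ace_sim_config"))
  R <- latent_correlation(config)
  L <- tryCatch(chol(R), error = function(e)
    stop("latent correlation matrix is not positive definite: ",
         conditionMessage(e), call. = FALSE))
  with_seed(config$seed, {
    n <- config$n
    Z <- matrix(stats::rnorm(n * 11L), n, 11L) %*% L
    out <- vector("list", 11L)
    for (j in ACE_YESNO) {
      p_yes <- config$item_margins[[j]]
      out[[j]] <- ifelse(Z[, j] > stats::qnorm(1 - p_yes), "yes", "no")
    }
    for (j in ACE_FREQ) {
      p <- config$item_margins[[j]]
      c1 <- stats::qnorm(p[1])            # never | once boundary
      c2 <- stats::qnorm(p[1] + p[2])     # once | more-than-once boundary
      out[[j]] <- ifelse(Z[, j] <= c1, "never",
                   ifelse(Z[, j] <= c2, "once", "more_than_once"))
    }
    names(out) <- ACE_ITEM_COLS
    df <- as.data.frame(out, stringsAsFactors = FALSE)

    link <- config$covariate_item_link
    zbar <- if (link > 0) {
      zm <- rowMeans(Z)
      zm / stats::sd(zm)
    }
    for (nm in names(config$covariate_margins)) {
      p <- config$covariate_margins[[nm]]
      lv <- names(p)
      if (link > 0) {
        u <- link * zbar + sqrt(1 - link^2) * stats::rnorm(n)
        cuts <- stats::qnorm(cumsum(p)[-length(p)])
        df[[nm]] <- factor(lv[findInterval(u, cuts) + 1L], levels = lv)
      } else {
        df[[nm]] <- factor(sample(lv, n, replace = TRUE, prob = p), levels = lv)
      }
    }
    df
  })
}

truth_linear_predictor <- function(responses, truth, threshold = "once",
                                   covariate_margins = default_covariate_margins()) {
  n <- nrow(responses)
  eta <- rep(truth$intercept, n)
  if (!is.null(truth$covariate_effects)) {
    for (nm in names(truth$covariate_effects)) {
      eff <- truth$covariate_effects[[nm]]
      lev <- as.character(responses[[nm]])
      add <- eff[lev]
      add[is.na(add)] <- 0  # reference or unlisted level
      eta <- eta + unname(add)
    }
  }
  if (truth$mode == "null") return(eta)
  expo <- code_exposures(responses, threshold = threshold)
  eta + switch(truth$mode,
    mir = drop(expo$matrix %*% truth$mir_betas),
    cr_linear = truth$score_beta * expo$score +
      truth$score_beta2 * expo$score^2,
    cr_categorical = {
      s <- pmin(expo$score, length(truth$step_effects))
      ifelse(s == 0, 0, truth$step_effects[pmax(s, 1L)])
    }
  )
}

#' Attach a Bernoulli outcome generated under a declared truth
#'
#' The linear predictor is assembled per `truth$mode` from exposures coded
#' at `threshold` (the generator's definition of "exposed"), plus intercept
#' and covariate effects; the outcome is drawn as
#' Bernoulli(plogis(linear predictor)).
#'
#' @param responses Complete response table from [generate_responses()] (no
#'   missing items).
#' @param truth A [truth_spec()].
#' @param seed Integer seed for the Bernoulli draws.
#' @param threshold Exposure threshold used by the generator; default "once".
#' @param outcome Name of the outcome column to create.
#' @return `responses` with an added integer 0/1 outcome column.
#' @export
generate_outcomes <- function(responses, truth, seed,
                              threshold = "once", outcome = "outcome") {
  stopifnot(inherits(truth, "truth_spec"))
  if (anyNA(responses[intersect(ACE_ITEM_COLS, names(responses))]))
    stop("responses must be complete (no missing items) at outcome generation",
         call. = FALSE)
  eta <- truth_linear_predictor(responses, truth, threshold = threshold)
  responses[[outcome]] <- with_seed(seed,
    stats::rbinom(nrow(responses), 1L, stats::plogis(eta)))
  responses
}

#' Knock out item responses completely at random
#'
#' Each of the 11 item cells is independently set to missing (NA) with
#' probability `missing_rate`; covariates and outcomes are untouched.
#'
#' @param responses Response table.
#' @param missing_rate MCAR probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return The table with NAs injected; identical to the input when
#'   `missing_rate = 0`.
#' @export
apply_missingness <- function(responses, missing_rate, seed) {
  if (missing_rate < 0 || missing_rate >= 1)
    stop("`missing_rate` must lie in [0, 1)", call. = FALSE)
  if (missing_rate == 0) return(responses)
  n <- nrow(responses)
  with_seed(seed, {
    for (col in ACE_ITEM_COLS) {
      hit <- stats::runif(n) < missing_rate
      responses[[col]][hit] <- NA
    }
  })
  responses
}

#' Simulate a complete synthetic survey dataset
#'
#' Orchestrates [generate_responses()], [generate_outcomes()] and
#' [apply_missingness()] with seeds derived from `config$seed` (seed,
#' seed + 1, seed + 2), so the whole dataset is reproducible from the
#' config alone.
#'
#' @param config An [ace_sim_config()].
#' @return Data frame of items, covariates and `outcome`, with the config
#'   attached as attribute `"config"`.
#' @export
#' @examples
#' cfg <- ace_sim_config(n = 200, truth = truth_spec("cr_linear",
#'   intercept = -1, score_beta = 0.15), seed = 7)
#' d <- simulate_ace_data(cfg)
#' table(d$outcome)
simulate_ace_data <- function(config) {
  stopifnot(inherits(config, "ace_sim_config"))
  d <- generate_responses(config)
  d <- generate_outcomes(d, config$truth, seed = config$seed + 1L,
                         threshold = config$exposure_threshold)
  d <- apply_missingness(d, config$missing_rate, seed = config$seed + 2L)
  attr(d, "config") <- config
  d
}

#' Write a synthetic dataset as delimited text plus a JSON sidecar
#'
#' The table is written as a comma-separated file with a header row; the
#' generating config (truth, seed, marginals, correlation) is recorded in a
#' JSON sidecar so the dataset is self-describing.
#'
#' @param data Data frame from [simulate_ace_data()].
#' @param path Path of the CSV to write; the sidecar is written next to it
#'   with extension `.json`.
#' @param config The generating [ace_sim_config()]; defaults to the config
#'   attached to `data`.
#' @return Invisibly, the two paths written.
#' @export
write_ace_dataset <- function(data, path, config = attr(data, "config")) {
  utils::write.csv(data, path, row.names = FALSE, na = "")
  side <- sub("\\.[^.]+$", ".json", path)
  if (identical(side, path)) side <- paste0(path, ".json")
  if (!is.null(config)) {
    cfg <- unclass(config)
    cfg$truth <- unclass(cfg$truth)
    jsonlite::write_json(cfg, side, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(c(data = path, sidecar = side))
}

#' Read a respondent-level delimited table
#'
#' Reads a comma-separated survey extract, maps declared missing-data codes
#' (for example "dont_know" or "refused") to NA in the item columns, and
#' sets covariates to factors with the declared reference level first.
#'
#' @param path CSV path with a header row.
#' @param missing_codes Character values (besides empty cells) treated as
#'   missing in item columns.
#' @param covariates Covariate column names to convert to factors.
#' @param references Optional named character vector giving the reference
#'   level per covariate; defaults to each factor's first observed level.
#' @return Data frame ready for [screen_responses()].
#' @export
read_ace_dataset <- function(path, missing_codes = c("dont_know", "refused", "missing"),
                             covariates = ace_covariates(), references = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  for (col in intersect(ACE_ITEM_COLS, names(d))) {
    d[[col]][d[[col]] %in% missing_codes] <- NA
  }
  for (nm in intersect(covariates, names(d))) {
    f <- factor(d[[nm]])
    if (!is.null(references) && nm %in% names(references))
      f <- stats::relevel(f, ref = references[[nm]])
    d[[nm]] <- f
  }
  d
}
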