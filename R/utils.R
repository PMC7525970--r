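# internal helpers shared across modules

match_items <- function(items) {
  items <- as.integer(items)
  if (!items %in% c(11L, 9L)) stop("`items` must be 11 or 9", call. = FALSE)
  items
}

match_threshold <- function(threshold) {
  match.arg(threshold, c("once", "more_than_once"))
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so simulation helpers do not clobber
# user RNG streams. seed = NULL runs under the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sig_stars <- function(p) {
  ifelse(is.na(p), "",
    ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
}

fmt_num <- function(x, digits = 3) formatC(x, digits = digits, format = "f")

assert_prob <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1))
    stop(sprintf("%s must be probabilities in [0, 1]", what), call. = FALSE)
  invisible(x)
}
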