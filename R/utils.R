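## Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

#' Derive a reproducible substream seed
#'
#' Maps a master seed and a stream id to an independent seed, kept strictly
#' below 2^31 - 1 so `set.seed()` always receives a valid integer. Used so
#' every stochastic stage of a study draws from its own stream of one master
#' seed.
#'
#' @param seed master seed.
#' @param id integer stream identifier.
#' @return an integer seed.
#' @export
substream_seed <- function(seed, id) {
  m <- 2147483647
  as.integer(((as.numeric(seed) %% m) * 48271 + id * 1000003) %% m)
}

with_substream <- function(seed, id, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(substream_seed(seed, id))
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

## logit / inverse logit on probabilities strictly inside (0,1)
qlogit <- function(p) log(p / (1 - p))

stop_named <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

## Wald test of a set of coefficients being jointly zero.
wald_joint <- function(coef, vcov, idx) {
  b <- coef[idx]
  V <- vcov[idx, idx, drop = FALSE]
  stat <- tryCatch(drop(t(b) %*% solve(V, b)), error = function(e) NA_real_)
  df <- length(idx)
  list(statistic = stat, df = df,
       p_value = if (is.na(stat)) NA_real_ else stats::pchisq(stat, df, lower.tail = FALSE))
}
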