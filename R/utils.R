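#' Run an expression under a temporary RNG seed
#'
#' Sets the random seed, evaluates `expr`, and restores the caller's RNG
#' state, so library functions can be deterministic without clobbering the
#' session stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a sub-generator seed from a master seed
#'
#' Each sub-generator (species pool, occurrences, polygons, backbones,
#' red list, ...) gets its own stream derived from one master seed, so a
#' stage can be regenerated independently of the others.
#'
#' @param seed master integer seed.
#' @param label character stream label.
#' @return an integer seed below 2^31.
#' @export
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)) * 131L)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

# half-up rounding to `digits` decimals; base round() is round-half-even,
# printed tables use half-up
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  # small epsilon guards exact .5 boundaries against binary representation
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Percentage of a total, rounded half-up to one decimal
#'
#' The bookkeeping convention used in all summary tables: 100 * count / total
#' rounded half-up to one decimal place.
#'
#' @param count numeric numerator(s).
#' @param total numeric denominator.
#' @return numeric percentage(s).
#' @export
pct_of <- function(count, total) {
  if (any(total <= 0)) stop("'total' must be positive")
  round_half_up(100 * count / total, 1)
}

# fold Latin-1 accented characters to ASCII; deterministic, locale-free
fold_accents <- function(x) {
  from <- "áàâãäéèêëíìîïóòôõöúùûüçñÁÀÂÃÄÉÈÊËÍÌÎÏÓÒÔÕÖÚÙÛÜÇÑ"
  to <- "aaaaaeeeeiiiiooooouuuucnAAAAAEEEEIIIIOOOOOUUUUCN"
  chartr(from, to, x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
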