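#' @keywords internal
"_PACKAGE"

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

## Run code with a locally-set RNG seed, restoring .Random.seed afterwards so
## callers' RNG streams are untouched. seed = NULL leaves the stream alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

## Classed error constructors used across modules so callers can test for the
## specific failure mode rather than matching message text.
jf_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "jointfriction_error", "error",
                                     "condition")))
}

## Genotype label -> identifier-safe code ("Prg4+/-" -> "Prg4pm").
genotype_code <- function(g) {
  g <- gsub("\\+", "p", g)
  g <- gsub("-", "m", g)
  gsub("[^[:alnum:]]+", "", g)
}

## Phase-unwrap an angle sequence (radians) so successive values never jump
## by more than pi.
unwrap_angles <- function(a) {
  ok <- !is.na(a)
  x <- a[ok]
  if (length(x) > 1L) {
    d <- diff(x)
    corr <- cumsum(-2 * pi * round(d / (2 * pi)))
    x[-1L] <- x[-1L] + corr
  }
  a[ok] <- x
  a
}

## 2-D rotation matrix (counter-clockwise positive).
rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L, 2L)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    jf_error(sprintf("'%s' must be a single positive finite number", name),
             "config_error")
  invisible(x)
}

check_nonnegative <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
    jf_error(sprintf("'%s' must be a single non-negative finite number", name),
             "config_error")
  invisible(x)
}

## Format reals for delimited output so write/read round trips preserve
## 1e-12 relative accuracy.
fmt_num <- function(x) formatC(x, digits = 17, format = "g")
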