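# Outcome transformations used to satisfy LMEM assumptions: square root,
# log (with a recorded offset when zeros are present), arcsine square root
# for proportions, and the Tukey ladder of powers.

TRANSFORMATIONS <- c("identity", "sqrt", "log", "arcsine_sqrt", "tukey")

#' Apply an outcome transformation
#'
#' Transformations are elementwise:
#' * `identity`: unchanged;
#' * `sqrt`: requires non-negative values;
#' * `log`: requires non-negative values; zeros are shifted by
#'   `offset` = half the smallest positive value (recorded);
#' * `arcsine_sqrt`: `asin(sqrt(p))` on proportions; percentages in
#'   (1, 100] are rescaled by 1/100 first (recorded);
#' * `tukey`: ladder of powers with exponent `lambda` — `x^lambda` for
#'   `lambda > 0`, `log(x)` for `lambda = 0`, `-x^lambda` for
#'   `lambda < 0` (sign flip keeps the transform order-preserving).
#'
#' @param values numeric vector.
#' @param transformation one of `r paste(TRANSFORMATIONS, collapse=", ")`.
#' @param lambda ladder exponent (required for `"tukey"`).
#' @param offset optional explicit zero offset for `log` / non-positive
#'   `lambda`; default half the smallest positive value.
#' @return transformed numeric vector with attribute `record` (a list:
#'   transformation, lambda, offset, rescaled).
#' @export
apply_transformation <- function(values, transformation = "identity",
                                 lambda = NULL, offset = NULL) {
  transformation <- match.arg(transformation, TRANSFORMATIONS)
  v <- as.numeric(values)
  rec <- list(transformation = transformation, lambda = lambda,
              offset = 0, rescaled = FALSE)
  bad_domain <- function(what) {
    off <- which(!is.na(v) & v < 0)
    stop(sprintf("%s transform undefined for negative values (e.g. value %g at position %d)",
                 what, v[off[1]], off[1]), call. = FALSE)
  }
  need_offset <- function() {
    if (!is.null(offset)) return(offset)
    pos <- v[!is.na(v) & v > 0]
    if (!length(pos))
      stop("log-type transform undefined: no positive values", call. = FALSE)
    min(pos) / 2
  }
  out <- switch(transformation,
    identity = v,
    sqrt = { if (any(v < 0, na.rm = TRUE)) bad_domain("sqrt"); sqrt(v) },
    log = {
      if (any(v < 0, na.rm = TRUE)) bad_domain("log")
      if (any(v == 0, na.rm = TRUE)) { rec$offset <- need_offset(); v <- v + rec$offset }
      log(v)
    },
    arcsine_sqrt = {
      if (any(v < 0, na.rm = TRUE)) bad_domain("arcsine_sqrt")
      if (any(v > 1, na.rm = TRUE)) {
        if (any(v > 100, na.rm = TRUE))
          stop("arcsine_sqrt requires proportions in [0,1] or percentages in [0,100]; ",
               "offending value ", max(v, na.rm = TRUE), call. = FALSE)
        v <- v / 100; rec$rescaled <- TRUE
      }
      asin(sqrt(v))
    },
    tukey = {
      if (is.null(lambda)) stop("tukey transform requires lambda", call. = FALSE)
      if (any(v < 0, na.rm = TRUE)) bad_domain("tukey ladder")
      if (lambda <= 0 && any(v == 0, na.rm = TRUE)) {
        rec$offset <- need_offset(); v <- v + rec$offset
      }
      if (lambda > 0) v^lambda else if (lambda == 0) log(v) else -(v^lambda)
    })
  attr(out, "record") <- rec
  out
}
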