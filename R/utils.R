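#' @keywords internal
"_PACKAGE"

# Canonical study channel order used throughout: astrocytes, amyloid-beta,
# presynaptic terminals, microglia.
STUDY_CHANNELS <- c("GFAP", "Abeta4G8", "Synapsin1", "IBA1")

GLIAL_CHANNELS <- c("IBA1", "GFAP")

#' Study channel names
#'
#' The four immunohistochemistry channels the pipeline quantifies:
#' `GFAP` (astrocytes), `Abeta4G8` (amyloid-beta, 4G8 antibody),
#' `Synapsin1` (presynaptic terminals) and `IBA1` (microglia).
#'
#' @return Character vector of length 4 in canonical order.
#' @export
study_channels <- function() STUDY_CHANNELS

# Alias map: variant channel labels seen in practice -> canonical names.
CHANNEL_ALIASES <- c(
  "4G8" = "Abeta4G8", "Abeta" = "Abeta4G8", "AB" = "Abeta4G8",
  "SYN1" = "Synapsin1", "Synapsin-1" = "Synapsin1", "synapsin1" = "Synapsin1",
  "Iba1" = "IBA1", "iba1" = "IBA1", "gfap" = "GFAP"
)

#' Canonicalize channel names
#'
#' Maps variant channel labels (e.g. `"4G8"`, `"SYN1"`) onto the canonical
#' study names via a built-in alias table; unknown names pass through.
#'
#' @param x character vector of channel labels.
#' @return character vector of the same length.
#' @export
canonical_channel <- function(x) {
  hit <- match(x, names(CHANNEL_ALIASES))
  x[!is.na(hit)] <- CHANNEL_ALIASES[hit[!is.na(hit)]]
  x
}

abort_field <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}

check_fraction <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    abort_field(field, "must be a single number in [0, 1]")
  invisible(x)
}

check_positive <- function(x, field, len = 1L, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == len && !anyNA(x) &&
    all(if (strict) x > 0 else x >= 0)
  if (!ok)
    abort_field(field, sprintf("must be %d %s numeric value(s)", len,
                               if (strict) "strictly positive" else "non-negative"))
  invisible(x)
}

# Deterministic child-seed rule: a master seed drives one sample.int() draw
# per child, so cohorts are reproducible and stacks mutually independent.
spawn_seeds <- function(master_seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(as.integer(master_seed))
  sample.int(.Machine$integer.max - 1L, n)
}

# run expr under a local RNG seed, restoring global state afterwards
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
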