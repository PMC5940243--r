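#' @keywords internal
"_PACKAGE"

#' Race/ethnicity classes, in canonical (tie-break) order
#'
#' The four mutually exclusive target classes used throughout the package.
#' The order is also the deterministic tie-break order for class orderings.
#' @export
RE_CLASSES <- c("Other", "White", "Hispanic", "Black")

#' Quinary gender categories
#' @export
GENDER_LEVELS <- c("male", "female", "trans", "other", "unknown")

#' Derive a reproducible sub-seed from a master seed and a stage label
#'
#' All randomness in the package flows from explicit integer seeds. Pipeline
#' stages (cohort generation, fold assignment, masking, per-fold training, ...)
#' each use a seed derived deterministically from the master seed and a string
#' key, so that stages are independent yet reproducible.
#'
#' @param seed master integer seed
#' @param ... stage labels (strings or integers), e.g. `"train"`, `3`
#' @return an integer in [1, 2^31 - 2]
#' @export
derive_seed <- function(seed, ...) {
  key <- paste(c(...), collapse = "/")
  h <- as.numeric(seed) %% 2147483647
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% 2147483647
  as.integer(h) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(..., call. = FALSE)
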