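# Shared low-level helpers: base coding, conditions, seed handling.

BASES <- c("A", "C", "G", "T")

# transition partner of each base code (A<->G, C<->T)
TRANSITION_OF <- c(3L, 4L, 1L, 2L)

# the two transversion partners of each base code
TRANSVERSIONS_OF <- list(c(2L, 4L), c(1L, 3L), c(2L, 4L), c(1L, 3L))

base_to_code <- function(b) {
  code <- match(toupper(b), BASES)
  if (anyNA(code)) {
    ma_error("non-ACGT base encountered", "mutaccum_base_error")
  }
  code
}

code_to_base <- function(code) BASES[code]

#' Signal a classed mutaccum error
#' @noRd
ma_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "mutaccum_error")))
}

#' Check that `x` is a single finite number within [lo, hi]
#' @noRd
check_scalar <- function(x, name, lo = -Inf, hi = Inf,
                         class = "mutaccum_config_error") {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x) || x < lo || x > hi) {
    ma_error(sprintf("'%s' must be a finite number in [%g, %g]", name, lo, hi),
             class)
  }
  invisible(x)
}

#' Recycle a per-regime parameter to length n_regimes
#' @noRd
per_regime <- function(x, n, name, lo = -Inf, hi = Inf,
                       class = "mutaccum_config_error") {
  if (!length(x) %in% c(1L, n)) {
    ma_error(sprintf("'%s' must have length 1 or %d", name, n), class)
  }
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)) ||
      any(x < lo) || any(x > hi)) {
    ma_error(sprintf("'%s' must be finite and in [%g, %g]", name, lo, hi),
             class)
  }
  rep_len(as.numeric(x), n)
}

#' Evaluate an expression with a private RNG stream
#'
#' Saves and restores the global `.Random.seed` so simulation entry points
#' are reproducible from their own `seed` argument without clobbering the
#' caller's stream.
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a parent seed (kept below 2^31)
#' @noRd
child_seed <- function(seed, k) {
  (as.double(seed) * 48271 + 7919 * k) %% 2147483629
}
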