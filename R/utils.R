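#' @keywords internal
"_PACKAGE"

## Shared argument checks. Kept terse: each aborts with the caller-visible
## message the module contracts require.

stop_arg <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, min = -Inf, max = Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_arg(name, " must be a single number")
  if (strict_min && x <= min) stop_arg(name, " must be > ", min)
  if (!strict_min && x < min) stop_arg(name, " must be >= ", min)
  if (x > max) stop_arg(name, " must be <= ", max)
  invisible(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop_arg(name, " must be TRUE or FALSE")
  invisible(x)
}

## Deterministic child RNG streams: runs a block under a seed derived from
## (seed, stream) without clobbering the caller's RNG state.
with_seed <- function(seed, expr, stream = 0L) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed((as.integer(seed) + 1000003L * as.integer(stream)) %% .Machine$integer.max)
  }
  expr
}

#' Amino-acid alphabet used throughout the package
#'
#' The 20 standard residues, in the fixed column order used by
#' [build_profile()] score matrices and the sequence simulator.
#'
#' @return Character vector of 20 one-letter residue codes.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}
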