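#' @keywords internal
"_PACKAGE"

# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Enumerate unordered region pairs
#'
#' Lexicographic enumeration of the \eqn{R(R-1)/2} unordered region pairs
#' (1,2), (1,3), ..., (R-1,R). This ordering is the canonical pair order used
#' by every connectivity matrix in the package.
#'
#' @param n_regions number of regions (>= 2).
#' @return data.frame with integer columns `i` and `j` (`i < j`).
#' @export
#' @examples
#' pair_index(4)
pair_index <- function(n_regions) {
  stopifnot(n_regions >= 2)
  idx <- utils::combn(seq_len(n_regions), 2L)
  data.frame(i = idx[1L, ], j = idx[2L, ])
}

#' Row of the canonical pair table holding pair (i, j)
#'
#' Inverse lookup for [pair_index()]: vectorized over `i`, `j` (`i < j`).
#'
#' @param i,j region indices with `i < j`.
#' @param n_regions number of regions in the enumeration.
#' @return integer row positions into `pair_index(n_regions)`.
#' @export
pair_row <- function(i, j, n_regions) {
  stopifnot(all(i < j), all(j <= n_regions))
  (i - 1L) * n_regions - (i * (i - 1L)) %/% 2L + (j - i)
}

stop_invalid <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
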