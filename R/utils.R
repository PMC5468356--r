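#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All package randomness flows through
# this so that a master seed reproduces every stage bit-for-bit.
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
    set.seed(seed)
  }
  force(expr)
}

# Derive a stream of child seeds from one master seed (all < 2^31).
derive_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Class vocabulary for nuclei
#'
#' Nucleus classes used throughout the pipeline: `"immunopositive"` (Ki-67
#' expressing, DAB brown) and `"immunonegative"` (hematoxylin blue only).
#' The pixel-labeling stage adds `"background"`.
#'
#' @return Character vector of the two nucleus class labels.
#' @export
nucleus_classes <- function() c("immunopositive", "immunonegative")

label_classes <- function() c(nucleus_classes(), "background")

stopifnot_scalar <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max)
    stop(sprintf("`%s` must be a single number in [%s, %s]", name, min, max),
         call. = FALSE)
  invisible(x)
}
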