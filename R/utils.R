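#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded generators do not disturb the
#' caller's RNG stream.
#' @noRd
with_seed_ <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Check a scalar is a positive finite number
#' @noRd
assert_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stopf("'%s' must be a single positive finite number", name)
  invisible(x)
}

## Center-to-center slab widths for sparse axial stacks. Interior slices get
## half the distance between their two neighbours; end slices get the full
## distance to their single neighbour, so a uniform stack of n slices spaced
## s integrates to n*s of anatomy.
slab_widths <- function(z, slice_thickness = NULL) {
  n <- length(z)
  if (n == 0L) return(numeric(0))
  if (n == 1L) {
    if (is.null(slice_thickness))
      stopf("single-slice stack needs a slice_thickness to define a slab width")
    warning("single-slice stack: using slice_thickness as slab width",
            call. = FALSE)
    return(slice_thickness)
  }
  if (any(diff(z) <= 0)) stopf("slice z-positions must be strictly increasing")
  dz <- numeric(n)
  dz[1L] <- z[2L] - z[1L]
  dz[n] <- z[n] - z[n - 1L]
  if (n > 2L) dz[2:(n - 1L)] <- (z[3:n] - z[1:(n - 2L)]) / 2
  dz
}
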