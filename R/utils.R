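# small internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate expr with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  eval.parent(substitute(expr))
}

as_xyz <- function(cloud) {
  if (is.matrix(cloud)) {
    stopifnot(ncol(cloud) >= 3)
    unname(cloud[, 1:3, drop = FALSE])
  } else {
    cbind(cloud$x, cloud$y, cloud$z)
  }
}

xyz_df <- function(m, ...) {
  data.frame(x = m[, 1], y = m[, 2], z = m[, 3], ...)
}
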