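# Internal helpers.

# Evaluate `code` under a temporary RNG seed, restoring (or removing)
# .Random.seed afterwards so no function leaks global RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Uniform-spacing check with relative tolerance (default matches the
# TimeTrace contract).
is_uniform <- function(x, rel_tol = 1e-6) {
  if (length(x) < 2) return(TRUE)
  dx <- diff(x)
  max(abs(dx - dx[1])) <= rel_tol * abs(dx[1])
}

# Trapezoid weights for a uniform grid: integral(f) = sum(w * f).
trapz_weights <- function(x) {
  n <- length(x)
  if (n < 2) return(rep(0, n))
  dx <- x[2] - x[1]
  w <- rep(dx, n)
  w[c(1, n)] <- dx / 2
  w
}

`%||%` <- function(a, b) if (is.null(a)) b else a
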