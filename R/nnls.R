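# Non-negative least squares by the Lawson-Hanson active-set method.
# Solves min ||A x - b||^2 subject to x >= 0.  A must have full column
# rank on every passive set encountered (guaranteed here because the
# Tikhonov systems stack alpha * L under the kernel).
nnls_solve <- function(A, b, max_outer = 10L * ncol(A) + 50L) {
  n <- ncol(A)
  x <- numeric(n)
  passive <- logical(n)
  w <- drop(crossprod(A, b))          # gradient of -0.5||Ax-b||^2 at x = 0
  tol <- 1e-10 * max(abs(w), 1)
  outer <- 0L
  while (any(!passive) && max(w[!passive]) > tol && outer < max_outer) {
    outer <- outer + 1L
    cand <- which(!passive)
    passive[cand[which.max(w[cand])]] <- TRUE
    inner <- 0L
    repeat {
      inner <- inner + 1L
      s <- numeric(n)
      coefs <- qr.coef(qr(A[, passive, drop = FALSE]), b)
      coefs[is.na(coefs)] <- 0
      s[passive] <- coefs
      if (all(s[passive] > 0) || inner > max_outer) {
        x <- s
        break
      }
      neg <- passive & s <= 0
      step <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + step * (s - x)
      hit <- passive & x <= 1e-12
      x[hit] <- 0
      passive[hit] <- FALSE
      if (!any(passive)) { x <- numeric(n); break }
    }
    w <- drop(crossprod(A, b - A %*% x))
  }
  x
}

# Second-difference (discrete curvature) operator, (n-2) x n.
second_diff_matrix <- function(n) {
  stopifnot(n >= 3)
  L <- matrix(0, n - 2, n)
  for (i in seq_len(n - 2)) L[i, i:(i + 2)] <- c(1, -2, 1)
  L
}
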