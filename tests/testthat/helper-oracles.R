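# Independent oracles used to cross-check the package's algorithms.

# Horn's closed-form quaternion solution for the optimal rigid superposition:
# an algorithm independent of the SVD-based Kabsch path it checks.
oracle_quaternion_rmsd <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  M <- crossprod(Pc, Qc)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,        Szx - Sxz,        Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz,  Sxy + Syx,        Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz,  Syz + Szy,
    Sxy - Syx,       Szx + Sxz,        Syz + Szy,       -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lam <- max(eigen(N, symmetric = TRUE)$values)
  msd <- (sum(Pc^2) + sum(Qc^2) - 2 * lam) / nrow(P)
  sqrt(max(msd, 0))
}

# Brute-force change point: exhaustive two-segment SSE minimization.
oracle_change_point <- function(x) {
  n <- length(x)
  sse <- vapply(seq_len(n - 1L), function(k) {
    a <- x[seq_len(k)]; b <- x[seq.int(k + 1L, n)]
    sum((a - mean(a))^2) + sum((b - mean(b))^2)
  }, numeric(1))
  which.min(sse)
}

# Random rotation matrix from a uniform quaternion.
random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
}
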