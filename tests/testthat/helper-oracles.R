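# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths.

# Count states of a viability box by explicit nested enumeration.
enumerate_box_size <- function(lo, hi) {
  count <- 0L
  rec <- function(depth, prefix) {
    if (depth > length(lo)) {
      count <<- count + 1L
      return(invisible())
    }
    for (v in lo[depth]:hi[depth]) rec(depth + 1L, c(prefix, v))
  }
  rec(1L, integer(0))
  count
}

# Dense random Metzler matrix (nonnegative off-diagonal).
random_metzler <- function(n, seed) {
  withr::with_seed(seed, {
    m <- matrix(stats::runif(n * n, 0, 1), n, n) *
      (matrix(stats::runif(n * n), n, n) < 0.3)
    diag(m) <- stats::runif(n, -2, 0.5)
    m
  })
}

# Central-difference discretization of the ploidy diffusion PDE
# dn/dt = (lam - mu) n + beta*lam * d2n/dp2, absorbing at p_min/p_max.
# Returns the dominant eigenvalue of the discretized operator.
continuum_fd_eigenvalue <- function(lam, mu, beta, p_min, p_max, nodes = 200) {
  h <- (p_max - p_min) / (nodes + 1)          # interior nodes only
  D <- beta * lam
  main <- rep((lam - mu) - 2 * D / h^2, nodes)
  off <- rep(D / h^2, nodes - 1)
  A <- diag(main)
  A[cbind(seq_len(nodes - 1), 2:nodes)] <- off
  A[cbind(2:nodes, seq_len(nodes - 1))] <- off
  max(Re(eigen(A, only.values = TRUE)$values))
}
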