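# Independent oracles used across the test files.  These deliberately do
# not reuse the package's dynamic-programming or SVD code paths: alignment
# scores come from explicit enumeration of all monotone traces, the
# minimal superimposition RMSD from the quaternion characteristic-matrix
# method, and two-sphere SASA from the closed-form spherical-cap area.

# -- exhaustive alignment enumeration ---------------------------------------

# all monotone traces aligning code vectors of lengths n1, n2 (global);
# each trace is a 2-column matrix of 0-based indices with -1 gaps
enumerate_traces <- function(n1, n2) {
  out <- list()
  recurse <- function(i, j, cols) {
    if (i == n1 && j == n2) {
      out[[length(out) + 1L]] <<- if (length(cols))
        do.call(rbind, cols) else matrix(integer(0), ncol = 2)
      return(invisible())
    }
    if (i < n1 && j < n2) recurse(i + 1L, j + 1L, c(cols, list(c(i, j))))
    if (i < n1) recurse(i + 1L, j, c(cols, list(c(i, -1L))))
    if (j < n2) recurse(i, j + 1L, c(cols, list(c(-1L, j))))
  }
  recurse(0L, 0L, list())
  out
}

# run-based scoring, written independently of score_of()
score_trace <- function(trace, c1, c2, scores, open, extend) {
  total <- 0
  for (k in 1:2) {
    in_gap <- FALSE
    for (r in seq_len(nrow(trace))) {
      if (trace[r, k] == -1L) {
        total <- total + if (in_gap) extend else open
        in_gap <- TRUE
      } else in_gap <- FALSE
    }
  }
  for (r in seq_len(nrow(trace))) {
    if (trace[r, 1] >= 0L && trace[r, 2] >= 0L)
      total <- total + scores[c1[trace[r, 1] + 1L] + 1L,
                              c2[trace[r, 2] + 1L] + 1L]
  }
  total
}

oracle_global_score <- function(c1, c2, scores, open, extend) {
  traces <- enumerate_traces(length(c1), length(c2))
  max(vapply(traces, score_trace, numeric(1),
             c1 = c1, c2 = c2, scores = scores,
             open = open, extend = extend))
}

oracle_local_score <- function(c1, c2, scores, open, extend) {
  best <- 0
  n1 <- length(c1); n2 <- length(c2)
  for (i1 in seq_len(n1)) for (i2 in i1:n1) {
    for (j1 in seq_len(n2)) for (j2 in j1:n2) {
      s1 <- c1[i1:i2]; s2 <- c2[j1:j2]
      best <- max(best, oracle_global_score(s1, s2, scores, open, extend))
    }
  }
  best
}

# -- quaternion superimposition oracle --------------------------------------

# minimal RMSD over proper rigid motions via the Horn quaternion method
oracle_min_rmsd <- function(P, Q) {
  n <- nrow(P)
  P0 <- sweep(P, 2, colMeans(P))
  Q0 <- sweep(Q, 2, colMeans(Q))
  S <- t(Q0) %*% P0
  Sxx <- S[1, 1]; Sxy <- S[1, 2]; Sxz <- S[1, 3]
  Syx <- S[2, 1]; Syy <- S[2, 2]; Syz <- S[2, 3]
  Szx <- S[3, 1]; Szy <- S[3, 2]; Szz <- S[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,      -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,      -Sxx - Syy + Szz
  ), 4, 4, byrow = TRUE)
  lambda <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  e <- sum(P0^2) + sum(Q0^2) - 2 * lambda
  sqrt(max(0, e) / n)
}

random_rotation <- function() {
  # QR of a random Gaussian matrix, sign-fixed to a proper rotation
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# -- two-sphere SASA oracle --------------------------------------------------

# closed-form exposed area of a probe-inflated sphere (radius ra, centered
# at the origin) partially buried by a neighbour sphere (radius rb, at
# distance d)
oracle_two_sphere_area <- function(ra, rb, d) {
  if (d >= ra + rb) return(4 * pi * ra^2)
  cos_theta <- (d^2 + ra^2 - rb^2) / (2 * d * ra)
  if (cos_theta <= -1) return(0)
  if (cos_theta >= 1) return(4 * pi * ra^2)
  buried_cap <- 2 * pi * ra^2 * (1 - cos_theta)
  4 * pi * ra^2 - buried_cap
}

# lat-long numerical integration of the same quantity (cross-check of the
# closed form, and the spec-style numerical oracle)
numeric_two_sphere_area <- function(ra, rb, d, n_theta = 2000L) {
  theta <- (seq_len(n_theta) - 0.5) * pi / n_theta
  # ring at polar angle theta (measured from the axis towards the
  # neighbour) is buried iff its distance to the neighbour centre < rb
  x <- ra * cos(theta)
  ring_r <- ra * sin(theta)
  dist_sq <- (x - d)^2 + ring_r^2
  exposed <- dist_sq >= rb^2
  ring_area <- 2 * pi * ra^2 * sin(theta) * (pi / n_theta)
  sum(ring_area[exposed])
}

# -- misc helpers ------------------------------------------------------------

random_alphabet <- function(size) {
  alphabet(paste0("s", seq_len(size)))
}

expect_coords_equal <- function(a, b, tol = 5e-4) {
  expect_lt(max(abs(coords(a) - coords(b))), tol)
}

expect_same_annotations <- function(a, b,
    cats = c("chain_id", "res_id", "res_name", "atom_name", "element",
             "hetero")) {
  for (cat in cats) expect_identical(a[[cat]], b[[cat]])
}
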