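# Independent oracles used by the unit and acceptance tests.  Each recomputes
# a quantity from first principles (brute force, finite differences,
# closed form), independently of the implementation path it checks.

# Pearson correlation evaluated literally as cov(X,Y)/(sd(X) sd(Y)) on
# centred values, clamped to [-1, 1].
oracle_pearson <- function(x, y) {
  if (max(x) == min(x) || max(y) == min(y)) return(0)
  cx <- x - sum(x) / length(x)
  cy <- y - sum(y) / length(y)
  min(1, max(-1, sum(cx * cy) / sqrt(sum(cx^2) * sum(cy^2))))
}

# Brute-force double loop over every window placement, recomputing the
# correlation per window, with the same tie rule (smallest i, then j) and
# the zero-variance-window => 0 convention.
oracle_best_segment <- function(a, b, lam, tie_tol = 1e-9) {
  na <- length(a) - lam + 1L
  nb <- length(b) - lam + 1L
  R <- matrix(NA_real_, na, nb)
  for (i in seq_len(na)) {
    wa <- a[i:(i + lam - 1L)]
    for (j in seq_len(nb)) {
      R[i, j] <- oracle_pearson(wa, b[j:(j + lam - 1L)])
    }
  }
  best <- max(abs(R))
  # same tie rule as stated: round-off-level ties resolve to the smallest
  # start in the first curve, then in the second
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    if (abs(R[i, j]) >= best - tie_tol)
      return(list(start_a = i - 1L, start_b = j - 1L, correlation = R[i, j]))
  }
}

# ANM potential V = (gamma/2) * sum over springs (d_ij - d_ij0)^2 evaluated
# at displaced coordinates q (length 3N), and its central-finite-difference
# Hessian at the equilibrium.
oracle_anm_energy <- function(network, q) {
  pos <- network$positions + matrix(q, ncol = 3, byrow = TRUE)
  sp <- network$springs
  d <- sqrt(rowSums((pos[sp[, 1], , drop = FALSE] - pos[sp[, 2], , drop = FALSE])^2))
  0.5 * network$gamma * sum((d - network$spring_length)^2)
}

oracle_anm_fd_hessian <- function(network, h = 1e-4) {
  n3 <- 3 * nrow(network$positions)
  H <- matrix(0, n3, n3)
  e <- function(k) { q <- numeric(n3); q[k] <- h; q }
  V <- function(q) oracle_anm_energy(network, q)
  for (a in seq_len(n3)) {
    H[a, a] <- (V(e(a)) - 2 * V(numeric(n3)) + V(-e(a))) / h^2
    for (b in seq_len(n3)) {
      if (b <= a) next
      H[a, b] <- H[b, a] <-
        (V(e(a) + e(b)) - V(e(a) - e(b)) - V(-e(a) + e(b)) + V(-e(a) - e(b))) /
        (4 * h^2)
    }
  }
  H
}

# Naive triple loop over (m1, m2, n) recounting all nine indexes.
oracle_triple_count <- function(L1, Z1, L2, Z2) {
  M <- nrow(L1); N <- ncol(L1)
  out <- c(s1 = 0, s1_pos = 0, s1_neg = 0, s2 = 0, s2_pos = 0, s2_neg = 0,
           d = 0, d_pos = 0, d_neg = 0)
  for (m1 in 1:M) for (m2 in 1:M) for (n in 1:N) {
    if (L1[m1, n] && !L2[m2, n]) {
      out["s1"] <- out["s1"] + 1
      k <- if (Z1[m1, n]) "s1_pos" else "s1_neg"
      out[k] <- out[k] + 1
    } else if (!L1[m1, n] && L2[m2, n]) {
      out["s2"] <- out["s2"] + 1
      k <- if (Z2[m2, n]) "s2_pos" else "s2_neg"
      out[k] <- out[k] + 1
    } else if (L1[m1, n] && L2[m2, n]) {
      out["d"] <- out["d"] + 1
      k <- if (Z1[m1, n] == Z2[m2, n]) "d_pos" else "d_neg"
      out[k] <- out[k] + 1
    }
  }
  out
}

# Random connected bead network: a random walk with step 3.8 A (consecutive
# nodes always inside a 10 A cutoff, so the network is connected for any
# node count) confined to a protein-density ball so the globule is stiff
# enough that the rigid-body modes are the only near-zero ones.
random_connected_structure <- function(n_nodes, seed) {
  set.seed(seed)
  R <- max(6, 2.1 * n_nodes^(1 / 3))
  pos <- matrix(0, n_nodes, 3)
  for (i in 2:n_nodes) {
    repeat {
      u <- rnorm(3)
      cand <- pos[i - 1, ] + 3.8 * u / sqrt(sum(u^2))
      if (sum(cand^2) <= R^2) break
    }
    pos[i, ] <- cand
  }
  atoms <- data.frame(serial = seq_len(n_nodes), name = "CA", element = "C",
                      chain = "A", resno = seq_len(n_nodes), icode = "",
                      alt = "", resid = "ALA",
                      x = pos[, 1], y = pos[, 2], z = pos[, 3], mass = 12.011,
                      stringsAsFactors = FALSE)
  coopnma:::new_mol_structure(atoms)
}

# per-row cross product: row i of the result is axis x pos[i, ]
# (an infinitesimal rigid rotation displacement field)
cross_all <- function(pos, axis) {
  cbind(axis[2] * pos[, 3] - axis[3] * pos[, 2],
        axis[3] * pos[, 1] - axis[1] * pos[, 3],
        axis[1] * pos[, 2] - axis[2] * pos[, 1])
}

# random logic_pair with given dimensions
random_logic_pair <- function(M = 6, N = 10, p_grid = seq(1, 0.5, by = -0.1)) {
  lp <- list(L = matrix(sample(c(TRUE, FALSE), M * N, replace = TRUE), M, N),
             Z = matrix(sample(c(TRUE, FALSE), M * N, replace = TRUE), M, N),
             p_grid = p_grid)
  class(lp) <- "logic_pair"
  lp
}
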