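# Elastic-network construction, Hessians, mass weighting and modes.

test_that("spring counts match a brute-force pair enumeration", {
  st <- gen_complex(seed = 7, atoms_per_res = 2)
  net <- build_network(st, cutoff = 10)
  pos <- as.matrix(st$atoms[, c("x", "y", "z")])
  n <- nrow(pos)
  cnt <- 0L
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    if (sqrt(sum((pos[i, ] - pos[j, ])^2)) <= 10) cnt <- cnt + 1L
  expect_identical(nrow(net$springs), cnt)
})

test_that("two nodes within/beyond the cutoff give one/no spring", {
  near <- bead_structure(rbind(c(0, 0, 0), c(1, 0, 0)))
  net <- build_network(near, cutoff = 10)
  expect_identical(nrow(net$springs), 1L)
  far <- bead_structure(rbind(c(0, 0, 0), c(12, 0, 0)))
  expect_warning(net2 <- build_network(far, cutoff = 10), "disconnected")
  expect_identical(nrow(net2$springs), 0L)
  expect_false(net2$connected)
})

test_that("the two-node x-bond ANM Hessian is the textbook 6x6 with eigenvalues {0 x5, 2}", {
  st <- bead_structure(rbind(c(0, 0, 0), c(1, 0, 0)))
  H <- build_anm_hessian(build_network(st, cutoff = 10, gamma = 1))$matrix
  expect_equal(dim(H), c(6L, 6L))
  expected <- matrix(0, 6, 6)
  expected[1, 1] <- expected[4, 4] <- 1
  expected[1, 4] <- expected[4, 1] <- -1
  expect_equal(H, expected)
  expect_equal(sort(eigen(H, symmetric = TRUE)$values),
               c(0, 0, 0, 0, 0, 2), tolerance = 1e-12)
})

test_that("nodes beyond the cutoff give a zero ANM Hessian", {
  st <- bead_structure(rbind(c(0, 0, 0), c(12, 0, 0)))
  net <- suppressWarnings(build_network(st, cutoff = 10))
  expect_true(all(build_anm_hessian(net)$matrix == 0))
})

test_that("ANM Hessian matches central finite differences of the network potential", {
  for (seed in 1:3) {
    st <- random_connected_structure(10, seed = seed)
    net <- build_network(st, cutoff = 10, gamma = 1)
    H <- build_anm_hessian(net)$matrix
    Hfd <- oracle_anm_fd_hessian(net)
    expect_lt(max(abs(H - Hfd)), 1e-5)
  }
})

test_that("GNM Kirchhoff equals degree matrix minus adjacency", {
  st <- bead_structure(rbind(c(0, 0, 0), c(3.8, 0, 0)))
  K <- build_gnm_kirchhoff(build_network(st, cutoff = 10, gamma = 2))$matrix
  expect_equal(K, 2 * matrix(c(1, -1, -1, 1), 2))
  expect_equal(eigen(K, symmetric = TRUE)$values, c(4, 0), tolerance = 1e-12)

  # path graph of 3 nodes: ends beyond the cutoff
  st3 <- bead_structure(rbind(c(0, 0, 0), c(8, 0, 0), c(16, 0, 0)))
  K3 <- build_gnm_kirchhoff(build_network(st3, cutoff = 10))$matrix
  expect_equal(K3, matrix(c(1, -1, 0, -1, 2, -1, 0, -1, 1), 3))

  # random network: degree - adjacency by brute force
  st <- random_connected_structure(25, seed = 4)
  net <- build_network(st, cutoff = 10, gamma = 1.5)
  pos <- net$positions
  A <- as.matrix(dist(pos)) <= 10
  diag(A) <- FALSE
  expect_equal(build_gnm_kirchhoff(net)$matrix,
               1.5 * (diag(rowSums(A)) - A), ignore_attr = TRUE)
})

test_that("GNM Kirchhoff zero-eigenvalue multiplicity equals the component count", {
  # two disconnected 3-node clusters
  pos <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0),
               c(50, 0, 0), c(53, 0, 0), c(50, 3, 0))
  net <- suppressWarnings(build_network(bead_structure(pos), cutoff = 10))
  expect_identical(net$n_components, 2L)
  K <- build_gnm_kirchhoff(net)$matrix
  vals <- eigen(K, symmetric = TRUE)$values
  expect_identical(sum(abs(vals) < 1e-10), 2L)
  expect_lt(max(abs(K %*% rep(1, 6))), 1e-12)   # all-ones in the null space
})

test_that("mass weighting reproduces the hand-computed block and preserves symmetry and zero modes", {
  st <- bead_structure(rbind(c(0, 0, 0), c(1, 0, 0)))
  net <- build_network(st, cutoff = 10)
  H <- build_anm_hessian(net)
  Hw <- mass_weight(H, c(4, 1))
  expect_equal(Hw$matrix[c(1, 4), c(1, 4)],
               matrix(c(1 / 4, -1 / 2, -1 / 2, 1), 2))
  expect_lt(min(abs(eigen(Hw$matrix, symmetric = TRUE)$values)), 1e-14)

  # identity for unit masses; symmetry for random masses
  st <- random_connected_structure(12, seed = 9)
  H <- build_anm_hessian(build_network(st, cutoff = 10))
  expect_equal(mass_weight(H, rep(1, 12))$matrix, H$matrix)
  m <- runif(12, 1, 20)
  Hw <- mass_weight(H, m)$matrix
  expect_identical(Hw, t(Hw))
  expect_error(mass_weight(H, c(rep(1, 11), -2)), "positive")
  expect_error(mass_weight(H, rep(1, 5)), "one mass per node")
})

test_that("compute_modes finds exactly 6 trivial modes and matches an independent solver", {
  st <- random_connected_structure(30, seed = 2)
  net <- build_network(st, cutoff = 10)
  H <- build_anm_hessian(net)
  modes <- compute_modes(H, n_essential = 10)
  expect_identical(modes$n_trivial, 6L)
  expect_identical(modes$mode_numbers, 7:16)
  # eigenvalues ascending, >= -tol
  expect_true(all(diff(modes$values) >= -1e-12))
  expect_gt(min(modes$values), -1e-8 * max(modes$values))
  # orthonormal columns
  G <- crossprod(modes$vectors)
  expect_lt(max(abs(G - diag(nrow(G)))), 1e-8)

  # independent check of the essential eigenvalues: smallest Rayleigh
  # quotients from a fresh decomposition of the symmetrised copy
  for (seed in 10:12) {
    st <- random_connected_structure(20, seed = seed)
    H2 <- build_anm_hessian(build_network(st, cutoff = 10))$matrix
    ref <- sort(eigen((H2 + t(H2)) / 2, symmetric = TRUE)$values)
    got <- compute_modes(build_anm_hessian(build_network(st, cutoff = 10)),
                         n_essential = 10)
    expect_equal(got$values, ref, tolerance = 1e-8)
    # residual check ||Hv - lambda v|| for essential modes
    for (k in got$mode_numbers) {
      r <- H2 %*% got$vectors[, k] - got$values[k] * got$vectors[, k]
      expect_lt(max(abs(r)), 1e-8 * max(abs(H2)))
    }
  }
})

test_that("disconnected ANM networks are refused with a component report", {
  pos <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0),
               c(50, 0, 0), c(53, 0, 0), c(50, 3, 0))
  net <- suppressWarnings(build_network(bead_structure(pos), cutoff = 10))
  H <- build_anm_hessian(net)
  expect_error(compute_modes(H, network = net), "disconnected")
})

test_that("mode displacements scale linearly and carry the eigenvector norm", {
  st <- random_connected_structure(15, seed = 3)
  net <- build_network(st, cutoff = 10)
  modes <- compute_modes(build_anm_hessian(net), n_essential = 5)
  d0 <- mode_displacements(modes, net, 7, amplitude = 0)
  expect_true(all(d0 == 0))
  d1 <- mode_displacements(modes, net, 7, amplitude = 1)
  expect_equal(sqrt(sum(d1^2)), 1, tolerance = 1e-12)
  d2 <- mode_displacements(modes, net, 7, amplitude = 2)
  expect_equal(d2, 2 * d1)
  expect_error(mode_displacements(modes, net, 3), "trivial")
  expect_silent(mode_displacements(modes, net, 3, allow_trivial = TRUE))
})

test_that("c-alpha granularity picks one node per residue and scatters to all atoms", {
  st <- gen_complex(seed = 13, atoms_per_res = 3)
  net <- build_network(st, cutoff = 12, granularity = "c-alpha")
  expect_identical(nrow(net$positions), 130L)
  expect_equal(sum(net$masses), sum(st$atoms$mass))
  modes <- compute_modes(build_anm_hessian(net), n_essential = 3)
  disp <- mode_displacements(modes, net, 7)
  expect_identical(nrow(disp), 390L)
  # atoms of one residue share their node displacement
  idx <- which(st$atom_res == 5)
  expect_identical(nrow(unique(disp[idx, , drop = FALSE])), 1L)

  # residue without CA is refused
  st2 <- st
  st2$atoms$name[st2$atoms$name == "CA" & st2$atom_res == 1] <- "CX"
  expect_error(build_network(st2, granularity = "c-alpha"), "without a CA")
})

test_that("modes TSV holds mode number, eigenvalue and 3N components", {
  st <- random_connected_structure(8, seed = 1)
  net <- build_network(st, cutoff = 10)
  modes <- compute_modes(build_anm_hessian(net), n_essential = 4)
  tf <- tempfile(fileext = ".tsv")
  write_modes_tsv(modes, tf)
  tab <- read.delim(tf)
  expect_identical(nrow(tab), 4L)
  expect_identical(ncol(tab), 2L + 24L)
  expect_equal(tab$eigenvalue, modes$values[7:10])
})
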