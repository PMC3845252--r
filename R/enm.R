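# Elastic-network models and normal modes.
#
# The anisotropic network model (ANM) places a harmonic spring of uniform
# stiffness gamma between every pair of nodes closer than a cutoff; the
# potential is V = (gamma/2) * sum_{i<j, connected} (d_ij - d_ij^0)^2.  Its
# Hessian at the equilibrium has the off-diagonal 3x3 super-block
# -gamma * rhat rhat^T for each spring (rhat the unit bond vector) and
# diagonal super-blocks equal to minus the sum of the row's off-diagonal
# blocks, which makes rigid translations and rotations exact zero modes.
# The Gaussian network model (GNM) is the isotropic N x N Kirchhoff variant.

#' Build an elastic network from a structure
#'
#' Nodes are all atoms (`granularity = "all-atom"`) or one CA atom per
#' residue (`"c-alpha"`); springs connect node pairs separated by at most
#' `cutoff` Angstrom.  Under c-alpha granularity a node carries the total
#' mass of its residue.
#'
#' @param structure A `mol_structure`.
#' @param cutoff Spring cutoff distance in Angstrom (> 0). Default 10.
#' @param gamma Uniform spring constant (energy/Angstrom^2, > 0). Default 1.
#' @param granularity `"all-atom"` or `"c-alpha"`.
#' @return An `elastic_network`: node positions (N x 3), masses, springs
#'   (two-column index matrix, i < j), spring lengths, the node-to-atom map,
#'   the number of connected components and a `connected` flag.
#' @export
build_network <- function(structure, cutoff = 10, gamma = 1,
                          granularity = c("all-atom", "c-alpha")) {
  stopifnot(inherits(structure, "mol_structure"), cutoff > 0, gamma > 0)
  granularity <- match.arg(granularity)
  atoms <- structure$atoms
  if (granularity == "all-atom") {
    node_atom <- seq_len(nrow(atoms))
    node_res <- structure$atom_res
    masses <- atoms$mass
  } else {
    is_ca <- atoms$name == "CA"
    node_atom <- integer(n_residues(structure))
    for (r in seq_len(n_residues(structure))) {
      idx <- which(structure$atom_res == r & is_ca)
      node_atom[r] <- if (length(idx)) idx[1] else NA_integer_
    }
    if (anyNA(node_atom)) {
      bad <- structure$residues$key[is.na(node_atom)]
      stop("residues without a CA atom under c-alpha granularity: ",
           paste(bad, collapse = ", "))
    }
    node_res <- seq_len(n_residues(structure))
    masses <- as.numeric(tapply(atoms$mass, structure$atom_res, sum))
  }
  pos <- as.matrix(atoms[node_atom, c("x", "y", "z")])
  dimnames(pos) <- NULL
  n <- nrow(pos)
  if (n < 2L) stop("elastic network needs at least 2 nodes")
  d <- as.matrix(dist(pos))
  adj <- d <= cutoff
  diag(adj) <- FALSE
  springs <- which(adj & upper.tri(adj), arr.ind = TRUE)
  dimnames(springs) <- NULL
  comp <- connected_components(adj)
  net <- structure(list(positions = pos, masses = masses, cutoff = cutoff,
                        gamma = gamma, granularity = granularity,
                        node_atom = node_atom, node_res = node_res,
                        atom_res = structure$atom_res,
                        n_atoms = nrow(atoms),
                        springs = springs,
                        spring_length = d[springs],
                        n_components = max(comp), components = comp,
                        connected = max(comp) == 1L),
                   class = "elastic_network")
  if (!net$connected)
    warning(sprintf("elastic network is disconnected (%d components) at cutoff %.3g",
                    net$n_components, cutoff), call. = FALSE)
  net
}

# component label per node, from a logical adjacency matrix (BFS)
connected_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' @export
print.elastic_network <- function(x, ...) {
  cat(sprintf("elastic_network: %d nodes (%s), %d springs, cutoff %.3g A, gamma %.3g%s\n",
              nrow(x$positions), x$granularity, nrow(x$springs), x$cutoff,
              x$gamma, if (x$connected) "" else sprintf(" [%d components]", x$n_components)))
  invisible(x)
}

new_hessian <- function(kind, mat, gamma) {
  structure(list(kind = kind, matrix = mat, gamma = gamma,
                 n_nodes = if (kind == "anm") nrow(mat) / 3L else nrow(mat)),
            class = "enm_hessian")
}

#' Anisotropic network model Hessian
#'
#' Builds the exact 3N x 3N second-derivative matrix of the ANM potential at
#' the equilibrium geometry.  Symmetry holds exactly by construction, and each
#' diagonal super-block equals minus the sum of its row's off-diagonal
#' super-blocks (translation invariance).
#'
#' @param network An [build_network()] result.
#' @return An `enm_hessian` with `kind = "anm"`.
#' @export
build_anm_hessian <- function(network) {
  stopifnot(inherits(network, "elastic_network"))
  pos <- network$positions
  gamma <- network$gamma
  n <- nrow(pos)
  H <- matrix(0, 3 * n, 3 * n)
  sp <- network$springs
  for (k in seq_len(nrow(sp))) {
    i <- sp[k, 1]; j <- sp[k, 2]
    r <- pos[i, ] - pos[j, ]
    blk <- -gamma * tcrossprod(r) / sum(r * r)
    ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
    H[ii, jj] <- blk
    H[jj, ii] <- blk
    H[ii, ii] <- H[ii, ii] - blk
    H[jj, jj] <- H[jj, jj] - blk
  }
  new_hessian("anm", H, gamma)
}

#' Gaussian network model Kirchhoff matrix
#'
#' N x N connectivity (Laplacian) matrix: -gamma for connected pairs,
#' node degree times gamma on the diagonal; every row sums to zero.
#'
#' @inheritParams build_anm_hessian
#' @return An `enm_hessian` with `kind = "gnm"`.
#' @export
build_gnm_kirchhoff <- function(network) {
  stopifnot(inherits(network, "elastic_network"))
  n <- nrow(network$positions)
  K <- matrix(0, n, n)
  sp <- network$springs
  for (k in seq_len(nrow(sp))) {
    i <- sp[k, 1]; j <- sp[k, 2]
    K[i, j] <- K[i, j] - network$gamma
    K[j, i] <- K[j, i] - network$gamma
    K[i, i] <- K[i, i] + network$gamma
    K[j, j] <- K[j, j] + network$gamma
  }
  new_hessian("gnm", K, network$gamma)
}

#' Mass-weight a Hessian
#'
#' Returns `M^(-1/2) H M^(-1/2)` with `M` the diagonal mass matrix (each node
#' mass repeated for x, y, z in the ANM case).  Symmetry and the zero modes
#' are preserved.
#'
#' @param hessian An `enm_hessian`.
#' @param masses Positive per-node masses, length N.
#' @return The mass-weighted `enm_hessian`.
#' @export
mass_weight <- function(hessian, masses) {
  stopifnot(inherits(hessian, "enm_hessian"))
  if (length(masses) != hessian$n_nodes)
    stop("need one mass per node (", hessian$n_nodes, ")")
  if (!all(is.finite(masses) & masses > 0)) stop("masses must be positive")
  m <- if (hessian$kind == "anm") rep(masses, each = 3L) else masses
  d <- 1 / sqrt(m)
  Hw <- hessian$matrix * tcrossprod(d)
  new_hessian(hessian$kind, Hw, hessian$gamma)
}

#' Diagonalise a Hessian and select the essential modes
#'
#' Full symmetric eigendecomposition in ascending eigenvalue order.  Modes
#' with eigenvalue below `tol_factor` times the largest eigenvalue are
#' trivial (rigid-body for the ANM: exactly six on a connected, non-collinear
#' network); the `n_essential` modes after the trivial block are the
#' essential modes, numbered over the full spectrum (7..16 by default for
#' the ANM).
#'
#' @param hessian An `enm_hessian`.
#' @param n_essential Number of essential (lowest non-trivial) modes to
#'   select; default 10.
#' @param tol_factor Relative zero-eigenvalue tolerance; default `1e-8`.
#' @param network Optional `elastic_network`; used only to name connected
#'   components in the disconnected-network error message.
#' @return A `mode_set`: ascending `values`, orthonormal `vectors` (columns),
#'   `n_trivial`, and `mode_numbers` (full-spectrum indices of the essential
#'   modes).
#' @export
compute_modes <- function(hessian, n_essential = 10, tol_factor = 1e-8,
                          network = NULL) {
  stopifnot(inherits(hessian, "enm_hessian"), n_essential >= 1)
  e <- eigen(hessian$matrix, symmetric = TRUE)
  values <- rev(e$values)
  vectors <- e$vectors[, rev(seq_along(e$values)), drop = FALSE]
  vmax <- max(values)
  if (!(vmax > 0)) stop("Hessian has no positive eigenvalue (empty network?)")
  tol <- tol_factor * vmax
  n_trivial <- sum(values < tol)
  if (hessian$kind == "anm" && n_trivial > 6L) {
    msg <- sprintf("more than 6 near-zero modes (%d): network is disconnected",
                   n_trivial)
    if (!is.null(network)) {
      sizes <- table(network$components)
      msg <- paste0(msg, sprintf(" (%d components of sizes %s)", length(sizes),
                                 paste(sizes, collapse = ", ")))
    }
    stop(msg)
  }
  if (n_trivial + n_essential > length(values))
    stop("not enough modes: requested ", n_essential, " essential modes after ",
         n_trivial, " trivial ones, spectrum has ", length(values))
  structure(list(values = values, vectors = vectors,
                 n_trivial = n_trivial, n_essential = as.integer(n_essential),
                 mode_numbers = seq.int(n_trivial + 1L, n_trivial + n_essential),
                 kind = hessian$kind),
            class = "mode_set")
}

#' @export
print.mode_set <- function(x, ...) {
  cat(sprintf("mode_set (%s): %d modes, %d trivial; essential modes %d..%d\n",
              x$kind, length(x$values), x$n_trivial,
              min(x$mode_numbers), max(x$mode_numbers)))
  cat("essential eigenvalues:",
      paste(signif(x$values[x$mode_numbers], 4), collapse = ", "), "\n")
  invisible(x)
}

#' Per-atom displacement field of one ANM mode
#'
#' Scales the unit-norm eigenvector of `mode_number` by `amplitude` and
#' scatters it back onto atoms.  Under c-alpha granularity every atom of a
#' residue inherits its CA node's displacement.
#'
#' @param modes A `mode_set` from an ANM Hessian.
#' @param network The `elastic_network` the Hessian came from.
#' @param mode_number Full-spectrum mode index; must be an essential mode
#'   unless `allow_trivial`.
#' @param amplitude Scaling in Angstrom applied to the unit eigenvector.
#' @param allow_trivial Permit rigid-body modes (default `FALSE`).
#' @return A (number of atoms) x 3 displacement matrix in Angstrom.
#' @export
mode_displacements <- function(modes, network, mode_number, amplitude = 1,
                               allow_trivial = FALSE) {
  stopifnot(inherits(modes, "mode_set"), inherits(network, "elastic_network"))
  if (modes$kind != "anm") stop("displacements need ANM (3N) eigenvectors")
  if (mode_number < 1 || mode_number > length(modes$values))
    stop("mode_number out of range")
  if (mode_number <= modes$n_trivial && !allow_trivial)
    stop("mode ", mode_number, " is trivial (rigid-body); set allow_trivial = TRUE to use it")
  v <- modes$vectors[, mode_number]
  node_disp <- amplitude * matrix(v, ncol = 3, byrow = TRUE)
  if (network$granularity == "all-atom") {
    disp <- matrix(0, network$n_atoms, 3)
    disp[network$node_atom, ] <- node_disp
  } else {
    # one node per residue; every atom of the residue inherits its node's motion
    node_of_res <- integer(max(network$node_res))
    node_of_res[network$node_res] <- seq_along(network$node_res)
    disp <- node_disp[node_of_res[network$atom_res], , drop = FALSE]
  }
  disp
}

#' Write modes to a tabular text file
#'
#' One row per mode: `mode_number`, `eigenvalue`, then the 3N displacement
#' components (x1, y1, z1, x2, ...) of the unit eigenvector.
#'
#' @param modes A `mode_set`.
#' @param path Output TSV path.
#' @param which_modes Full-spectrum mode indices; defaults to the essential
#'   modes.
#' @return Invisibly, `path`.
#' @export
write_modes_tsv <- function(modes, path, which_modes = modes$mode_numbers) {
  stopifnot(inherits(modes, "mode_set"))
  m <- t(modes$vectors[, which_modes, drop = FALSE])
  out <- data.frame(mode_number = which_modes,
                    eigenvalue = modes$values[which_modes], m)
  names(out) <- c("mode_number", "eigenvalue",
                  paste0("q", seq_len(ncol(m))))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
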