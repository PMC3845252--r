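# Synthetic inputs: bead complexes writable as PDB, curve pairs with a
# planted correlated window, and signed correlation tables with controlled
# structure.  Every generator is a pure function of its parameters and seed
# (no global random state is touched).

#' Planted-window ground truth
#'
#' @param window_a_start,window_b_start 0-based window starts in the two
#'   curves.
#' @param window_length Window length (>= 2).
#' @param target_corr Expected within-window correlation, in (0, 1].
#' @param seed Integer seed of the generator stream.
#' @return A `planted_truth`.
#' @export
planted_truth <- function(window_a_start, window_b_start, window_length,
                          target_corr = 0.95, seed = 1) {
  stopifnot(window_a_start >= 0, window_b_start >= 0, window_length >= 2,
            target_corr > 0, target_corr <= 1)
  structure(list(window_a_start = as.integer(window_a_start),
                 window_b_start = as.integer(window_b_start),
                 window_length = as.integer(window_length),
                 target_corr = target_corr, seed = as.integer(seed)),
            class = "planted_truth")
}

#' Generate a synthetic two-protein/DNA bead complex
#'
#' Lays out three perturbed helical bead chains -- a POU-like protein (chain
#' A, annotated with a POUS/linker/POUHD split), an HMG-like protein (chain
#' B) and a DNA-like chain (C) -- with ~3.8 Angstrom consecutive-bead
#' spacing and inter-chain packing close enough that the default 10 Angstrom
#' cutoff yields one connected elastic network.  The POU linker region is
#' stretched (lower bead density).  Output is deterministic per seed; if a
#' draw produces a disconnected network it is regenerated with a warning
#' (at most 5 attempts).
#'
#' @param n_res Residue counts `c(pou, sox, dna)`, each >= 3.
#'   Default `c(60, 40, 30)`.
#' @param atoms_per_res Atoms per residue (the first is named CA, the rest
#'   are satellites within ~0.8 Angstrom).  Default 1.
#' @param seed Integer seed.
#' @param cutoff Connectivity check cutoff (Angstrom); default 10.
#' @param noise_sd Positional jitter on bead centres (Angstrom); default 0.25.
#' @return A `mol_structure` with attributes `split` (a [subunit_split()]
#'   for chain A) and `chains` (`list(pou = "A", sox = "B", dna = "C")`).
#' @export
gen_complex <- function(n_res = c(pou = 60, sox = 40, dna = 30),
                        atoms_per_res = 1, seed = 1, cutoff = 10,
                        noise_sd = 0.25) {
  stopifnot(length(n_res) == 3L, all(n_res >= 3L), atoms_per_res >= 1L)
  n_res <- as.integer(n_res)
  for (attempt in seq_len(5L)) {
    st <- with_local_seed(seed + (attempt - 1L) * 10007L,
                          gen_complex_once(n_res, atoms_per_res, noise_sd))
    net <- suppressWarnings(build_network(st, cutoff = cutoff))
    if (net$connected) return(st)
    warning(sprintf("attempt %d produced a disconnected complex; regenerating",
                    attempt), call. = FALSE)
  }
  stop("could not generate a connected complex in 5 attempts")
}

gen_complex_once <- function(n_res, atoms_per_res, noise_sd) {
  # compact globular bead chain: a 3.8 A-step random walk confined to a ball
  # whose radius scales like n^(1/3) (protein-like density); a slack in the
  # step length models lower bead density (the POU linker)
  globule <- function(n, centre, steps) {
    R <- max(6, 2.1 * n^(1 / 3))
    pos <- matrix(0, n, 3)
    for (i in seq.int(2L, n)) {
      for (try in 1:50) {
        u <- rnorm(3)
        cand <- pos[i - 1L, ] + steps[i] * u / sqrt(sum(u^2))
        if (sum(cand^2) <= R^2) break
        # fall back: step back toward the centre, always inside the ball
        cand <- pos[i - 1L, ] * max(0, 1 - steps[i] / sqrt(sum(pos[i - 1L, ]^2)))
      }
      pos[i, ] <- cand
    }
    list(pos = sweep(pos, 2, colMeans(pos)) +
           matrix(centre, n, 3, byrow = TRUE), R = R)
  }
  n_pou <- n_res[1]
  s_end <- min(n_pou - 1L, max(2L, as.integer(round(0.4 * n_pou))))
  hd_start <- min(n_pou, s_end + max(1L, as.integer(round(0.08 * n_pou))) + 1L)
  linker <- if (hd_start > s_end + 1L) seq.int(s_end + 1L, hd_start - 1L) else integer(0)
  steps_a <- rep(3.8, n_pou); steps_a[linker] <- 5.2  # low-density linker
  Ra <- max(6, 2.1 * n_pou^(1 / 3)); Rb <- max(6, 2.1 * n_res[2]^(1 / 3))
  Rc <- max(6, 2.1 * n_res[3]^(1 / 3))
  dab <- 0.8 * (Ra + Rb)                    # interpenetrating surfaces: contacts
  dac <- 0.8 * (Ra + Rc)
  h <- sqrt(max(1, dac^2 - (dab / 2)^2))
  centers <- list(A = globule(n_pou, c(0, 0, 0), steps_a),
                  B = globule(n_res[2], c(dab, 0, 0), rep(3.8, n_res[2])),
                  C = globule(n_res[3], c(dab / 2, h, 0), rep(3.8, n_res[3])))
  centers <- lapply(centers, `[[`, "pos")
  rows <- list(); serial <- 0L
  for (ch in names(centers)) {
    P <- centers[[ch]] + matrix(rnorm(3 * nrow(centers[[ch]]), 0, noise_sd),
                                ncol = 3)
    resid <- if (ch == "C") "DA" else "ALA"
    for (r in seq_len(nrow(P))) {
      for (k in seq_len(atoms_per_res)) {
        serial <- serial + 1L
        off <- if (k == 1L) c(0, 0, 0) else {
          u <- rnorm(3); 0.8 * u / sqrt(sum(u^2))
        }
        rows[[serial]] <- data.frame(
          serial = serial,
          name = if (k == 1L) "CA" else paste0("C", k),
          element = "C", chain = ch, resno = r, icode = "", alt = "",
          resid = resid,
          x = P[r, 1] + off[1], y = P[r, 2] + off[2], z = P[r, 3] + off[3],
          mass = 12.011, stringsAsFactors = FALSE)
      }
    }
  }
  st <- new_mol_structure(do.call(rbind, rows))
  attr(st, "split") <- subunit_split("A", c(1, s_end), c(hd_start, n_pou))
  attr(st, "chains") <- list(pou = "A", sox = "B", dna = "C")
  st
}

#' Generate a curve pair with a planted correlated window
#'
#' Outside the planted windows the two curves are independent positive
#' noise; inside, both carry one smooth latent signal plus independent
#' noise whose scale is calibrated so the expected within-window correlation
#' equals `truth$target_corr` when `noise_sd = 1`.  `noise_sd` rescales that
#' calibrated noise: 0 gives perfectly correlated windows.  All values are
#' non-negative (the curves model displacement norms).
#'
#' @param len_a,len_b Curve lengths, `len_a <= len_b`; the windows must fit.
#' @param truth A [planted_truth()].
#' @param noise_sd Multiplier on the calibrated within-window noise;
#'   default 1.
#' @return List with `curve_a`, `curve_b` (numeric) and `truth`.
#' @export
gen_curve_pair <- function(len_a, len_b, truth, noise_sd = 1) {
  stopifnot(inherits(truth, "planted_truth"), len_a <= len_b, noise_sd >= 0)
  lam <- truth$window_length
  if (truth$window_a_start + lam > len_a || truth$window_b_start + lam > len_b)
    stop("planted window does not fit inside the curves")
  with_local_seed(truth$seed, {
    t <- seq_len(lam)
    f <- sample(1:3, 1)
    s <- sin(2 * pi * f * t / lam + runif(1, 0, 2 * pi)) +
      0.4 * sin(2 * pi * (f + 2) * t / lam + runif(1, 0, 2 * pi))
    s <- (s - mean(s)) / sd(s)
    amp <- 0.3
    rho <- truth$target_corr
    sig <- amp * noise_sd * sqrt((1 - rho) / rho)
    a <- runif(len_a, 0.1, 1.1)
    b <- runif(len_b, 0.1, 1.1)
    ia <- truth$window_a_start + t
    ib <- truth$window_b_start + t
    a[ia] <- 0.6 + amp * s + rnorm(lam, 0, sig)
    b[ib] <- 0.6 + amp * s + rnorm(lam, 0, sig)
    if (min(a) < 0) a <- a - min(a)   # constant shifts leave Pearson unchanged
    if (min(b) < 0) b <- b - min(b)
    list(curve_a = a, curve_b = b, truth = truth)
  })
}

#' Generate a signed correlation table with controlled structure
#'
#' Absolute values are drawn uniformly in (0.02, 0.98); with
#' `distinct_rows`, each row's absolute values are pairwise distinct
#' (resampled if needed).  Signs follow `sign_pattern`.
#'
#' @param sign_pattern `"random"`, or a matrix of +1/-1 of the table's
#'   dimensions.
#' @param distinct_rows Enforce pairwise-distinct absolute values per row
#'   (default `TRUE`).
#' @param seed Integer seed.
#' @param p_grid,mode_numbers Table layout; defaults `1.0..0.5` and `7..16`.
#' @param pair_id Stored pair label.
#' @return A `correlation_table` (no segment matches attached).
#' @export
gen_corr_table <- function(sign_pattern = "random", distinct_rows = TRUE,
                           seed = 1, p_grid = seq(1, 0.5, by = -0.1),
                           mode_numbers = 7:16, pair_id = NA) {
  M <- length(p_grid); N <- length(mode_numbers)
  with_local_seed(seed, {
    vals <- matrix(runif(M * N, 0.02, 0.98), M, N)
    if (distinct_rows) {
      for (m in seq_len(M)) {
        while (anyDuplicated(vals[m, ])) vals[m, ] <- runif(N, 0.02, 0.98)
      }
    }
    signs <- if (identical(sign_pattern, "random")) {
      matrix(sample(c(-1, 1), M * N, replace = TRUE), M, N)
    } else {
      sp <- as.matrix(sign_pattern)
      stopifnot(all(dim(sp) == c(M, N)), all(sp %in% c(-1, 1)))
      sp
    }
    new_correlation_table(vals * signs, p_grid, mode_numbers, pair_id = pair_id)
  })
}
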