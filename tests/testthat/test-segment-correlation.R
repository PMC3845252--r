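# Pearson correlation, segment search, table assembly, PCA/Fourier
# condensation.

test_that("pearson_cor reproduces hand-computed values", {
  expect_equal(as.numeric(pearson_cor(c(1, 2, 3), c(2, 4, 6))), 1)
  expect_equal(as.numeric(pearson_cor(c(1, 2, 3), c(-1, -2, -3))), -1)
  # cov-sum 4, variance-sums 5 and 5 -> 4/5
  expect_equal(as.numeric(pearson_cor(c(1, 2, 3, 4), c(1, 3, 2, 4))), 0.8)
  expect_error(pearson_cor(1:3, 1:4), "length")
  r <- pearson_cor(c(2, 2, 2), c(1, 5, 9))
  expect_equal(as.numeric(r), 0)
  expect_true(attr(r, "degenerate"))
})

test_that("pearson_cor is invariant under positive affine maps and flips sign under negative ones", {
  set.seed(41)
  for (i in 1:20) {
    x <- rnorm(15); y <- rnorm(15)
    r <- as.numeric(pearson_cor(x, y))
    expect_equal(as.numeric(pearson_cor(3.2 * x + 7, y)), r, tolerance = 1e-12)
    expect_equal(as.numeric(pearson_cor(x, -0.5 * y + 2)), -r, tolerance = 1e-12)
  }
})

test_that("best_segment_pair finds the identical full-length window", {
  sm <- best_segment_pair(1:5, 1:5, 5)
  expect_identical(c(sm$start_a, sm$start_b), c(0L, 0L))
  expect_equal(sm$correlation, 1)
})

test_that("perfectly correlated windows tie-break to the smallest starts", {
  f1 <- c(0, 0, 1, 2, 3, 0)
  f2 <- c(5, 1, 2, 3, 9, 9, 9)
  sm <- best_segment_pair(f1, f2, 3)
  # |c| = 1 at (1,1) and (2,1); the tie rule keeps (1,1)
  expect_identical(c(sm$start_a, sm$start_b), c(1L, 1L))
  expect_equal(sm$correlation, 1, tolerance = 1e-12)
})

test_that("all-constant windows return the 0 convention at position (0,0)", {
  sm <- best_segment_pair(c(1, 1, 1, 1), c(1, 2, 3, 4), 2)
  expect_identical(c(sm$start_a, sm$start_b), c(0L, 0L))
  expect_equal(sm$correlation, 0)
  expect_true(sm$degenerate)
})

test_that("lambda bounds are enforced", {
  expect_error(best_segment_pair(1:5, 1:8, 1), "lambda")
  expect_error(best_segment_pair(1:5, 1:8, 6), "lambda")
})

test_that("segment search agrees with the brute-force double loop", {
  set.seed(42)
  for (i in 1:60) {
    na <- sample(5:40, 1); nb <- sample(5:40, 1)
    a <- runif(na); b <- runif(nb)
    lam <- sample(2:min(na, nb), 1)
    got <- best_segment_pair(a, b, lam)
    ref <- oracle_best_segment(a, b, lam)
    expect_identical(got$start_a, ref$start_a)
    expect_identical(got$start_b, ref$start_b)
    expect_equal(got$correlation, ref$correlation, tolerance = 1e-12)
  }
})

test_that("lambda_from_p rounds half away from zero and clamps at 2", {
  expect_identical(lambda_from_p(seq(1, 0.5, by = -0.1), 50),
                   c(50L, 45L, 40L, 35L, 30L, 25L))
  expect_identical(lambda_from_p(0.5, 45), 23L)   # 22.5 rounds up
  expect_identical(lambda_from_p(0.1, 10), 2L)    # clamped to the minimum
})

test_that("correlation tables have the published layout and perfect diagonal on identical proteins", {
  set.seed(43)
  curves <- lapply(1:10, function(i) runif(30))
  tab <- correlation_table(curves, curves)
  expect_equal(dim(tab$values), c(6L, 10L))
  expect_identical(tab$mode_numbers, 7:16)
  expect_equal(unname(tab$values), matrix(1, 6, 10), tolerance = 1e-12)
  expect_true(all(abs(tab$values) <= 1))
})

test_that("table serialisation writes the p-by-mode grid and the segment placements", {
  set.seed(44)
  ca <- lapply(1:3, function(i) runif(20))
  cb <- lapply(1:3, function(i) runif(25))
  tab <- correlation_table(ca, cb, p_grid = c(1, 0.5), mode_numbers = 7:9)
  tf <- tempfile(fileext = ".tsv")
  write_correlation_tsv(tab, tf)
  main <- read.delim(tf)
  expect_equal(dim(main), c(2L, 4L))
  seg <- read.delim(paste0(tf, ".segments.tsv"))
  expect_identical(nrow(seg), 6L)
  expect_true(all(seg$lambda %in% tab$lambdas))
})

test_that("pc1 condensation recovers a shared latent curve", {
  g <- sin(seq(0, 3 * pi, length.out = 40)) + 2
  same <- replicate(10, g, simplify = FALSE)
  cond <- pc1_condense(same)
  expect_equal(abs(as.numeric(pearson_cor(cond$values, g))), 1, tolerance = 1e-9)

  # positive multiples of one curve: condensed curve proportional to the
  # centred latent (svd oracle)
  set.seed(45)
  a_n <- runif(10, 0.5, 3)
  curves <- lapply(a_n, function(a) a * g)
  cond <- pc1_condense(curves)
  gc <- g - mean(g)
  expect_equal(abs(as.numeric(pearson_cor(cond$values, gc))), 1, tolerance = 1e-9)
  # sign convention: non-negative correlation with the per-position mean
  expect_gte(as.numeric(pearson_cor(cond$values, rowMeans(do.call(cbind, curves)))), 0)
})

test_that("pc1 scores maximise variance over random competing axes", {
  set.seed(46)
  X <- matrix(rnorm(35 * 10), 35, 10)
  curves <- lapply(seq_len(10), function(j) X[, j])
  cond <- pc1_condense(curves)
  Xc <- sweep(X, 2, colMeans(X))
  v_pc1 <- var(cond$values)
  for (i in 1:100) {
    u <- rnorm(10); u <- u / sqrt(sum(u^2))
    expect_lte(var(Xc %*% u), v_pc1 + 1e-10)
  }
})

test_that("pc1 refuses constant input", {
  expect_error(pc1_condense(replicate(5, rep(2, 10), simplify = FALSE)),
               "variance")
})

test_that("fourier magnitudes: DC line for constants, non-negativity, Parseval", {
  fm <- fourier_magnitude(rep(3, 8))
  expect_equal(fm$values, c(24, rep(0, 7)))
  set.seed(47)
  x <- rnorm(33)
  fm <- fourier_magnitude(x)
  expect_true(all(fm$values >= 0))
  expect_equal(sum(fm$values^2), length(x) * sum(x^2), tolerance = 1e-9)
})

test_that("the restricted shift search scores only aligned windows", {
  a <- c(1, 5, 2, 8, 3)
  b <- c(2, 1, 5, 2, 8, 3, 7)
  all_sm <- best_segment_pair(a, b, 3, search = "all")
  sh_sm <- best_segment_pair(a, b, 3, search = "shift")
  # the all-placement optimum is at least as good
  expect_gte(abs(all_sm$correlation), abs(sh_sm$correlation))
  expect_true(abs(sh_sm$correlation) <= 1)
})
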