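test_that("center_scale_markers standardizes columns and rejects monomorphic ones", {
  X <- matrix(c(0, 1, 1,
                1, 1, 0), nrow = 3)  # 3 x 2: cols (0,1,1), (1,1,0)
  Z <- center_scale_markers(X)
  # hand standardization: means 2/3, sds = sd(c(0,1,1)) = 0.5773503
  expect_equal(colMeans(Z), c(0, 0), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(apply(Z, 2, sd), c(1, 1), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(Z[, 1], (c(0, 1, 1) - 2/3) / sd(c(0, 1, 1)),
               ignore_attr = TRUE)
  # two-value symmetry
  Z2 <- center_scale_markers(matrix(c(0, 0, 1, 1), ncol = 1))
  expect_equal(as.numeric(Z2), c(-.5, -.5, .5, .5) / sd(c(0, 0, 1, 1)))
  # duplicated lines give identical rows
  X3 <- matrix(c(0, 1, 0, 1, 1, 0, 1, 0), nrow = 4)
  Z3 <- center_scale_markers(X3)
  expect_equal(Z3[1, ], Z3[3, ])
  expect_error(center_scale_markers(cbind(X, 1)), "monomorphic")
})

test_that("grm matches the hand-computed ZZ'/p and has zero grand sum", {
  X <- matrix(c(0, 1, 1,
                1, 1, 0), nrow = 3)
  Z <- center_scale_markers(X)
  G <- grm(Z)
  expect_equal(G$K, tcrossprod(Z) / 2, ignore_attr = TRUE)
  expect_equal(sum(G$K), 0, tolerance = 1e-12)
  expect_error(grm(Z, p = 5), "must equal")
  # duplicate lines: equal rows/columns and g_ii = g_ij = g_jj
  X4 <- rbind(c(0, 1, 0, 1), c(0, 1, 0, 1), c(1, 0, 1, 0), c(1, 1, 0, 0))
  G4 <- grm(center_scale_markers(X4))$K
  expect_equal(G4[1, ], G4[2, ], ignore_attr = TRUE)
  expect_equal(G4[1, 1], G4[1, 2])
  expect_equal(G4[1, 1], G4[2, 2])
})

test_that("scaled squared distances are Hamming counts normalized to unit mean", {
  X <- rbind(a = c(0, 1, 0, 1, 1), b = c(0, 1, 1, 0, 1), c = c(1, 0, 1, 0, 1))
  d <- scaled_sq_distances(X)
  # raw d2 between two 0/1 lines = number of mismatching markers
  D2 <- d$d2tilde * d$dbar
  expect_equal(D2["a", "b"], 2, ignore_attr = TRUE)
  expect_equal(D2["a", "c"], 4, ignore_attr = TRUE)
  expect_equal(diag(d$d2tilde), rep(0, 3), ignore_attr = TRUE)
  expect_equal(mean(d$d2tilde), 1, tolerance = 1e-12)
  expect_error(scaled_sq_distances(X[1, , drop = FALSE]), "two lines")
})

test_that("gaussian_kernel applies exp(-theta d2) with unit diagonal", {
  X <- with_seed2(5, matrix(rbinom(60, 1, 0.5), nrow = 6))
  d <- scaled_sq_distances(X)
  for (theta in c(0.2, 1, 5)) {
    K <- gaussian_kernel(d, theta)
    expect_equal(diag(K$K), rep(1, 6), ignore_attr = TRUE)
    expect_equal(K$K[2, 5], exp(-theta * d$d2tilde[2, 5]))
  }
  # unit case and monotonicity in theta at fixed distance
  expect_equal(exp(-1), gaussian_kernel(matrix(c(0, 1, 1, 0), 2), 1)$K[1, 2])
  v <- vapply(c(0.2, 1, 5),
              function(t) exp(-t * 0.8), 0)
  expect_true(all(diff(v) < 0))
  expect_equal(v, c(exp(-0.16), exp(-0.8), exp(-4)))
  expect_error(gaussian_kernel(d, -1), "positive")
})

test_that("gaussian kernels from markers are PSD", {
  for (seed in 1:5) {
    X <- with_seed2(seed, matrix(rbinom(25 * 40, 1, 0.5), nrow = 25))
    K <- gaussian_kernel(scaled_sq_distances(X), 1)$K
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8)
  }
})

test_that("kernel_average uses variance weights and preserves PSD", {
  ids <- c("x", "y")
  k1 <- kernel_matrix(matrix(c(1, .5, .5, 1), 2), ids, "gaussian")
  k2 <- kernel_matrix(matrix(c(1, .2, .2, 1), 2), ids, "gaussian")
  k3 <- kernel_matrix(matrix(c(1, .9, .9, 1), 2), ids, "gaussian")
  # hand-weighted sum with weights (0.5, 0.25, 0.25)
  KA <- kernel_average(list(k1, k2, k3), c(2, 1, 1))
  expect_equal(KA$params$weights, c(.5, .25, .25))
  expect_equal(KA$K[1, 2], .5 * .5 + .25 * .2 + .25 * .9)
  expect_equal(diag(KA$K), c(1, 1), ignore_attr = TRUE)
  # uniform weights -> arithmetic mean; degenerate weights -> single kernel
  expect_equal(kernel_average(list(k1, k2, k3), c(1, 1, 1))$K,
               (k1$K + k2$K + k3$K) / 3)
  expect_equal(kernel_average(list(k1, k2), c(1, 0))$K, k1$K)
  expect_error(kernel_average(list(k1), 1), "two kernels")
  expect_error(kernel_average(list(k1, k2), c(0, 0)), "all be zero")
  k4 <- kernel_matrix(matrix(c(1, 0, 0, 1), 2), c("y", "x"), "gaussian")
  expect_error(kernel_average(list(k1, k4), c(1, 1)), "ordering")
  # PSD preserved under non-negative weights
  X <- with_seed2(9, matrix(rbinom(20 * 30, 1, 0.5), nrow = 20))
  d <- scaled_sq_distances(X)
  ks <- lapply(c(0.2, 1, 5), function(t) gaussian_kernel(d, t))
  KA2 <- kernel_average(ks, c(0.3, 1.2, 0.1))
  expect_gt(min(eigen(KA2$K, symmetric = TRUE,
                      only.values = TRUE)$values), -1e-8)
})

test_that("partition_kernel follows the supplied ID order and reassembles", {
  X <- with_seed2(3, matrix(rbinom(8 * 30, 1, 0.5), nrow = 8))
  X <- X[, apply(X, 2, function(x) length(unique(x)) > 1)]
  rownames(X) <- paste0("L", 1:8)
  G <- grm(center_scale_markers(X))
  tr <- c("L5", "L2", "L7")
  pr <- c("L8", "L1")
  blk <- partition_kernel(G, tr, pr)
  expect_equal(blk$K_TS, G$K[tr, tr])
  expect_equal(blk$K_PS_TS, G$K[pr, tr])
  # shuffled lists give permuted blocks (not K's own order)
  blk2 <- partition_kernel(G, rev(tr), pr)
  expect_equal(blk2$K_TS, blk$K_TS[3:1, 3:1])
  # single prediction row equals that line's similarities
  blk3 <- partition_kernel(G, tr, "L4")
  expect_equal(as.numeric(blk3$K_PS_TS), as.numeric(G$K["L4", tr]))
  # complement partition reassembles the original blocks bit-exactly
  comp <- setdiff(G$ids, tr)
  blk4 <- partition_kernel(G, tr, comp)
  expect_identical(blk4$K_TS, G$K[tr, tr])
  expect_identical(blk4$K_PS_TS, G$K[comp, tr])
  expect_error(partition_kernel(G, tr, c("L2", "L8")), "overlap")
  expect_error(partition_kernel(G, tr, "nope"), "not present")
})
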