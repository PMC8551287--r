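test_that("blup_hat matches the explicit-inverse oracle", {
  inst <- random_ssi_instance(5, seed = 31)
  KP <- with_seed2(32, matrix(rnorm(3 * 5), 3))
  K_TS <- inst$C - 0.5 * diag(5)  # a PSD kernel block
  h <- blup_hat(K_TS, KP, lambda0 = 0.5)
  B_oracle <- KP %*% solve(K_TS + 0.5 * diag(5))
  expect_lt(max(abs(h$B - B_oracle)), 1e-10)
  # unrelated prediction set: zero similarities -> zero predictions
  h0 <- blup_hat(diag(6), matrix(0, 2, 6), lambda0 = 1)
  expect_true(all(h0$B == 0))
  expect_true(all(predict_hat(h0, rnorm(6))$u_hat == 0))
  # duplicate lines concentrate weight on the duplicates
  X <- with_seed2(33, matrix(rbinom(6 * 40, 1, 0.5), 6, 40))
  X <- rbind(X, X[1, ])  # line 7 duplicates line 1
  X <- X[, apply(X, 2, function(x) length(unique(x)) > 1)]
  G <- grm(center_scale_markers(X))
  blk <- partition_kernel(G, paste0("L", 1:6), "L7")
  hd <- blup_hat(blk, lambda0 = 0.3)
  expect_equal(unname(which.max(abs(hd$B[1, ]))), 1L)  # the duplicate
})

test_that("ssi path endpoints: zero at lambda_max, BLUP at lambda = 0", {
  for (seed in 1:5) {
    inst <- random_ssi_instance(30, seed = seed)
    lmax <- max(abs(inst$g))
    p <- ssi_solve_path(inst$g, inst$C, lambda_grid = c(lmax, 0))
    expect_true(all(p$coef[, 1] == 0))
    expect_equal(p$coef[, 2], solve(inst$C, inst$g), tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(p$n_sup[1], 0)
  }
  inst <- random_ssi_instance(20, seed = 9)
  expect_error(ssi_solve_path(inst$g, inst$C, lambda_grid = c(0, 1)),
               "descending")
  expect_error(ssi_solve_path(inst$g[1:3], inst$C), "match")
})

test_that("coordinate descent agrees with the proximal-gradient oracle and KKT", {
  for (seed in 1:10) {
    n <- with_seed2(seed, sample(6:12, 1))
    inst <- random_ssi_instance(n, seed = 40 + seed)
    lmax <- max(abs(inst$g))
    lam <- 0.3 * lmax
    p <- ssi_solve_path(inst$g, inst$C, lambda_grid = c(lmax, lam),
                        tol = 1e-10, maxit = 50000)
    b_cd <- p$coef[, 2]
    b_or <- ista_oracle(inst$C, inst$g, lam)
    expect_lt(abs(ssi_objective(inst$C, inst$g, b_cd, lam) -
                    ssi_objective(inst$C, inst$g, b_or, lam)), 1e-6)
    expect_lt(max(abs(b_cd - b_or)), 1e-6)
    chk <- kkt_check(inst$C, inst$g, b_cd, lam, tol = 1e-6)
    expect_true(chk)
  }
})

test_that("coordinate descent at tiny lambda approaches the BLUP row", {
  inst <- random_ssi_instance(40, seed = 61)
  lmax <- max(abs(inst$g))
  p <- ssi_solve_path(inst$g, inst$C,
                      lambda_grid = c(lmax, 1e-10 * lmax),
                      tol = 1e-10, maxit = 50000)
  expect_lt(max(abs(p$coef[, 2] - solve(inst$C, inst$g))), 1e-6)
})

test_that("objective is non-increasing across coordinate-descent sweeps", {
  for (seed in 1:5) {
    inst <- random_ssi_instance(15, seed = 50 + seed)
    lam <- 0.2 * max(abs(inst$g))
    tr <- ssindex:::cd_solve_trace_cpp(inst$C, inst$g, lam, 1e-10, 5000)
    expect_true(all(diff(tr$objective_trace) <= 1e-12))
  }
})

test_that("ssi_hat stacks independent rows: order and chunking invariance", {
  X <- with_seed2(70, matrix(rbinom(40 * 80, 1, 0.5), 40, 80))
  X <- X[, apply(X, 2, function(x) length(unique(x)) > 1)]
  rownames(X) <- paste0("L", 1:40)
  G <- grm(center_scale_markers(X))
  tr <- paste0("L", 1:20)
  pr <- paste0("L", 21:40)
  blk <- partition_kernel(G, tr, pr)
  lam <- 0.1 * max(abs(blk$K_PS_TS))
  h <- ssi_hat(blk, lambda0 = 0.5, lambda = lam, tol = 1e-8)
  # rows are independent problems: solving subsets/permutations matches
  h_a <- ssi_hat(partition_kernel(G, tr, pr[10:1]), lambda0 = 0.5,
                 lambda = lam, tol = 1e-8)
  h_b <- ssi_hat(partition_kernel(G, tr, pr[11:20]), lambda0 = 0.5,
                 lambda = lam, tol = 1e-8)
  expect_equal(h$B[10:1, ], h_a$B, ignore_attr = TRUE)
  expect_equal(h$B[11:20, ], h_b$B, ignore_attr = TRUE)
  # row-sparsity and KKT per row
  C <- blk$K_TS + 0.5 * diag(20)
  for (i in c(1, 7, 15))
    expect_true(kkt_check(C, blk$K_PS_TS[i, ], h$B[i, ], lam,
                          tol = 1e-6))
  # lambda at/above every row's lambda_max: all-zero Hat matrix
  hz <- ssi_hat(blk, lambda0 = 0.5, lambda = max(abs(blk$K_PS_TS)))
  expect_true(all(hz$B == 0))
  expect_error(ssi_hat(blk, lambda0 = 0.5, lambda = -1), "non-negative")
})

test_that("ssi_hat(lambda = 0) equals blup_hat", {
  for (seed in 1:3) {
    n <- 50
    X <- with_seed2(80 + seed, matrix(rbinom(n * 100, 1, 0.5), n, 100))
    X <- X[, apply(X, 2, function(x) length(unique(x)) > 1)]
    rownames(X) <- paste0("L", 1:n)
    G <- grm(center_scale_markers(X))
    blk <- partition_kernel(G, paste0("L", 1:35), paste0("L", 36:50))
    h0 <- ssi_hat(blk, lambda0 = 0.7, lambda = 0)
    hb <- blup_hat(blk, lambda0 = 0.7)
    expect_lt(max(abs(h0$B - hb$B)), 1e-8)
    expect_equal(h0$kind, "ssi")
  }
})

test_that("solver reports non-convergence with the lambda index", {
  inst <- random_ssi_instance(30, seed = 90)
  lmax <- max(abs(inst$g))
  expect_error(
    ssi_solve_path(inst$g, inst$C, lambda_grid = c(lmax, 0.05 * lmax),
                   tol = 1e-12, maxit = 2),
    "did not converge at lambda index 2")
})

test_that("cross_validate_lambda is deterministic and validates folds", {
  pop <- small_population(seed = 25, n_cycles = 2, families = 4, dh = 15)
  mm <- polymorphic(pop$markers)
  G <- grm(center_scale_markers(mm))
  y <- center_phenotypes(pop$pheno, mm$ids)
  cv1 <- cross_validate_lambda(y, G, lambda0 = 1, n_folds = 5,
                               n_lambda = 8, seed = 3)
  cv2 <- cross_validate_lambda(y, G, lambda0 = 1, n_folds = 5,
                               n_lambda = 8, seed = 3)
  expect_identical(cv1$fold_of, cv2$fold_of)
  expect_identical(cv1$selected_fraction, cv2$selected_fraction)
  expect_true(cv1$selected_fraction %in% cv1$fractions)
  # fold sizes differ by <= 1
  expect_lte(diff(range(table(cv1$fold_of))), 1)
  # pure-noise phenotypes still return a grid member
  yn <- with_seed2(4, rnorm(length(y)))
  names(yn) <- names(y)
  cvn <- cross_validate_lambda(yn, G, lambda0 = 1, n_folds = 5,
                               n_lambda = 8, seed = 5)
  expect_true(cvn$selected_fraction %in% cvn$fractions)
  expect_error(cross_validate_lambda(y[1:4], G$K[1:4, 1:4], 1,
                                     n_folds = 10),
               "smaller than the number of folds")
  expect_error(cross_validate_lambda(y[1:12], G$K[1:12, 1:12], 1,
                                     n_folds = 6),
               "fewer than 3")
})

test_that("predict_hat computes products and sparsity summaries", {
  B <- rbind(c(1, 0, 2, 0), c(0, 0, 0, 0), c(0.5, 0.5, 0.5, 0.5))
  hat <- ssindex:::new_hat_matrix(B, paste0("t", 1:4), paste0("p", 1:3),
                                  lambda = 0.1, lambda0 = 1, kind = "ssi")
  y <- c(t1 = 1, t2 = 2, t3 = 3, t4 = 4)
  pr <- predict_hat(hat, y)
  expect_equal(unname(pr$u_hat), c(1 + 6, 0, 5))
  expect_equal(unname(pr$n_sup), c(2, 0, 4))
  expect_equal(pr$pct_sparsity, 100 * 2 / 4)
  # BLUP: n_sup equals the training-set size for every row
  h <- blup_hat(diag(4) + 0.5, matrix(0.3, 3, 4), lambda0 = 0.5)
  prb <- predict_hat(h, unname(y))
  expect_true(all(prb$n_sup == 4))
  expect_equal(prb$pct_sparsity, 100)
  expect_error(predict_hat(hat, c(a = 1)), "missing")
})
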