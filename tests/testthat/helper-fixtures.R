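# Shared fixtures, generated in code (no stored data files).

# small multi-cycle DH population used across tests
small_population <- function(seed = 42, n_cycles = 3, families = 4,
                             dh = 25, founders = 8, shared = 3,
                             rho_g = 0.5, h2 = 0.5, n_qtl = 30,
                             markers_per_chr = 20, n_chr = 5) {
  map <- genetic_map(n_chr, markers_per_chr)
  plan <- default_crossing_plan(n_cycles, families, dh, founders, shared,
                                seed = seed)
  qtl <- with_seed2(seed + 1,
                    sort(sample.int(map$n_markers,
                                    min(n_qtl, map$n_markers %/% 2))))
  arch <- trait_architecture(qtl, n_cycles, rho_g = rho_g, h2 = h2,
                             seed = seed + 2)
  simulate_population(plan, map, arch, seed = seed + 3)
}

# seed helper that does not rely on the package's internal with_seed
with_seed2 <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# drop monomorphic marker columns (QC-lite for kernel construction)
polymorphic <- function(mm) {
  mm[, apply(mm$X, 2, function(x) length(unique(x)) > 1)]
}

# random PD system for solver tests: C = K + lambda0*I from random markers
random_ssi_instance <- function(n, p = 2 * n, lambda0 = 0.5, seed = 1) {
  X <- with_seed2(seed, matrix(rbinom(n * p, 1, 0.5), n, p))
  keep <- apply(X, 2, function(x) length(unique(x)) > 1)
  Z <- scale(X[, keep])
  K <- tcrossprod(Z) / sum(keep)
  g <- with_seed2(seed + 1000, rnorm(n, sd = 0.3))
  list(C = K + lambda0 * diag(n), g = g)
}

# proximal-gradient (ISTA) oracle for the L1-penalized index problem;
# independent of the coordinate-descent implementation under test
ista_oracle <- function(C, g, lambda, n_iter = 50000) {
  L <- max(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
  b <- numeric(length(g))
  for (i in seq_len(n_iter)) {
    z <- b - (C %*% b - g) / L
    b <- as.numeric(sign(z) * pmax(abs(z) - lambda / L, 0))
  }
  b
}

ssi_objective <- function(C, g, b, lambda) {
  0.5 * sum(b * (C %*% b)) - sum(g * b) + lambda * sum(abs(b))
}
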