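# Simulation of multi-generation doubled-haploid (DH) breeding populations.
#
# The generator emulates the structure of a multi-cycle maize DH program:
# each cycle a set of founder inbreds is crossed in biparental families, one
# recombinant F1 gamete per DH line is sampled along a genetic map (Haldane
# model, no interference) and doubled, so lines are fully homozygous and a
# dominant marker is simply the presence indicator of the band allele.
# Cycles may share founders (which connects generations, as in breeding
# programs that reuse elite parents), and QTL effects may differ between
# cycles with a controllable cross-cycle correlation rho_g -- the marker-
# effect heterogeneity that sparse selection indices exploit.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.null(seed) && abs(seed) >= 2^31) stop("seed must be a 32-bit integer")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# ---- genetic map --------------------------------------------------------

#' Genetic map for the simulator
#'
#' The real marker platform's map is unknown; the default stand-in is 10
#' chromosomes of 1 Morgan each with equally spaced markers.
#'
#' @param n_chr number of chromosomes.
#' @param markers_per_chr markers on each chromosome (scalar or vector).
#' @param length_morgans chromosome length in Morgans (scalar or vector).
#' @return list of class `genetic_map` with `chr` (chromosome index per
#'   marker) and `pos` (position in Morgans, ascending within chromosome).
#' @export
genetic_map <- function(n_chr = 10, markers_per_chr = 50, length_morgans = 1) {
  if (n_chr < 1) stop("need at least one chromosome")
  mpc <- rep_len(markers_per_chr, n_chr)
  len <- rep_len(length_morgans, n_chr)
  if (any(mpc < 1)) stop("each chromosome needs at least one marker")
  chr <- rep(seq_len(n_chr), mpc)
  pos <- unlist(lapply(seq_len(n_chr), function(c) {
    if (mpc[c] == 1) 0 else seq(0, len[c], length.out = mpc[c])
  }))
  structure(list(chr = chr, pos = pos, n_markers = length(chr)),
            class = "genetic_map")
}

validate_map <- function(map) {
  if (!inherits(map, "genetic_map")) stop("'map' must be a genetic_map")
  for (c in unique(map$chr)) {
    p <- map$pos[map$chr == c]
    if (is.unsorted(p)) stop("map positions must be non-decreasing in chr ", c)
  }
  invisible(map)
}

# ---- founders -----------------------------------------------------------

#' Simulate founder inbred lines
#'
#' Founders are independent fully homozygous lines; each marker is present
#' with its specified probability.
#'
#' @param n_founders number of founders (>= 2).
#' @param map a [genetic_map()].
#' @param allele_freq per-marker presence probability in (0, 1); scalar or
#'   vector of length `map$n_markers`.
#' @param seed RNG seed.
#' @return 0/1 integer matrix, founders in rows (`F1`, `F2`, ...).
#' @export
simulate_founders <- function(n_founders, map, allele_freq = 0.5,
                              seed = NULL) {
  validate_map(map)
  if (n_founders < 2) stop("need at least two founders")
  p <- map$n_markers
  f <- rep_len(allele_freq, p)
  if (any(f <= 0 | f >= 1))
    stop("allele frequencies must lie strictly in (0, 1)")
  with_seed(seed, {
    X <- matrix(rbinom(n_founders * p, 1, rep(f, each = n_founders)),
                nrow = n_founders, ncol = p)
    dimnames(X) <- list(paste0("F", seq_len(n_founders)),
                        paste0("M", seq_len(p)))
    X
  })
}

# ---- DH family ----------------------------------------------------------

#' Simulate a doubled-haploid family from two inbred parents
#'
#' Each DH line is a single recombinant F1 gamete, doubled.  Gametes are
#' sampled as a Markov chain along each chromosome: the parental origin of
#' the first marker is uniform, and origin switches between adjacent markers
#' with the Haldane recombination fraction r = (1 - exp(-2d))/2 for map
#' distance d (Morgans).  At markers where the parents agree every DH line
#' carries the shared allele.
#'
#' @param parent_a,parent_b 0/1 vectors of length `map$n_markers`.
#' @param map a [genetic_map()].
#' @param n_dh number of DH lines to generate.
#' @param seed RNG seed.
#' @return 0/1 integer matrix with `n_dh` rows.
#' @export
make_dh_family <- function(parent_a, parent_b, map, n_dh, seed = NULL) {
  validate_map(map)
  p <- map$n_markers
  if (length(parent_a) != p || length(parent_b) != p)
    stop("parents must have one allele per map marker (", p, ")")
  if (n_dh < 1) stop("'n_dh' must be >= 1")
  with_seed(seed, {
    X <- matrix(0L, nrow = n_dh, ncol = p)
    for (c in unique(map$chr)) {
      idx <- which(map$chr == c)
      m <- length(idx)
      init <- matrix(rbinom(n_dh, 1, 0.5), ncol = 1)
      if (m > 1) {
        d <- diff(map$pos[idx])
        r <- 0.5 * (1 - exp(-2 * d))
        S <- matrix(rbinom(n_dh * (m - 1), 1, rep(r, each = n_dh)),
                    nrow = n_dh)
        U <- upper.tri(matrix(0, m - 1, m - 1), diag = TRUE) * 1
        cum <- S %*% U
        P <- (matrix(init, n_dh, m) + cbind(0, cum)) %% 2
      } else {
        P <- init
      }
      pa <- parent_a[idx]; pb <- parent_b[idx]
      X[, idx] <- (1 - P) * matrix(pa, n_dh, m, byrow = TRUE) +
        P * matrix(pb, n_dh, m, byrow = TRUE)
    }
    storage.mode(X) <- "integer"
    colnames(X) <- paste0("M", seq_len(p))
    X
  })
}

# ---- crossing plan ------------------------------------------------------

#' Crossing plan: founder pools and biparental families per cycle
#'
#' @param founders_by_cycle list (one element per cycle) of founder ID
#'   vectors available in that cycle.
#' @param families data.frame with columns `cycle` (integer), `parent_a`,
#'   `parent_b` (founder IDs), `n_dh` (DH lines per family).
#' @return list of class `crossing_plan`.
#' @export
crossing_plan <- function(founders_by_cycle, families) {
  n_cycles <- length(founders_by_cycle)
  if (n_cycles < 1 || nrow(families) == 0)
    stop("a crossing plan needs at least one cycle with one family")
  need <- c("cycle", "parent_a", "parent_b", "n_dh")
  if (!all(need %in% names(families)))
    stop("'families' must have columns ", paste(need, collapse = ", "))
  if (any(families$n_dh < 1)) stop("family sizes must be >= 1")
  for (i in seq_len(nrow(families))) {
    cyc <- families$cycle[i]
    if (cyc < 1 || cyc > n_cycles) stop("family ", i, ": unknown cycle ", cyc)
    pool <- founders_by_cycle[[cyc]]
    if (!all(c(families$parent_a[i], families$parent_b[i]) %in% pool))
      stop("family ", i, ": parents not in cycle ", cyc, " founder pool")
  }
  structure(list(n_cycles = n_cycles,
                 founders_by_cycle = lapply(founders_by_cycle, as.character),
                 families = families),
            class = "crossing_plan")
}

#' Default multi-cycle crossing plan with shared parents
#'
#' Builds a plan in which consecutive cycles share `n_shared` founders (the
#' rest of each pool is new), emulating the reuse of elite parents that
#' connects generations of a breeding program.
#'
#' @param n_cycles number of breeding cycles.
#' @param families_per_cycle biparental families per cycle.
#' @param dh_per_family DH lines per family.
#' @param founders_per_cycle founder pool size per cycle.
#' @param n_shared founders carried over from each cycle to the next
#'   (0 = disconnected cycles; `founders_per_cycle` = one common pool).
#' @param seed RNG seed for the random pairing of parents.
#' @return A [crossing_plan()].
#' @export
default_crossing_plan <- function(n_cycles = 4, families_per_cycle = 10,
                                  dh_per_family = 50, founders_per_cycle = 8,
                                  n_shared = 3, seed = NULL) {
  if (n_shared > founders_per_cycle)
    stop("'n_shared' cannot exceed 'founders_per_cycle'")
  pools <- vector("list", n_cycles)
  next_id <- 1
  for (c in seq_len(n_cycles)) {
    n_new <- if (c == 1) founders_per_cycle else founders_per_cycle - n_shared
    new_ids <- if (n_new > 0)
      paste0("F", seq(next_id, next_id + n_new - 1)) else character(0)
    next_id <- next_id + n_new
    pools[[c]] <- if (c == 1) new_ids else
      c(utils::tail(pools[[c - 1]], n_shared), new_ids)
  }
  fams <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(n_cycles), function(c) {
      pairs <- t(replicate(families_per_cycle,
                           sample(pools[[c]], 2, replace = FALSE)))
      data.frame(cycle = c, parent_a = pairs[, 1], parent_b = pairs[, 2],
                 n_dh = dh_per_family, stringsAsFactors = FALSE)
    }))
  })
  crossing_plan(pools, fams)
}

# ---- trait architecture -------------------------------------------------

#' Trait architecture with cross-cycle effect heterogeneity
#'
#' QTL effects are drawn once per architecture: for each QTL, the vector of
#' per-cycle effects is multivariate normal with unit marginal variance
#' (times `effect_sd^2`) and pairwise correlation `rho_g`.  rho_g = 1 gives
#' identical effects in every cycle (a homogeneous trait); rho_g = 0 gives
#' independent effects per cycle (maximal marker-effect heterogeneity).
#'
#' @param qtl_idx marker column indices that carry effects.
#' @param n_cycles number of cycles.
#' @param rho_g cross-cycle effect correlation in \[0, 1\].
#' @param h2 target narrow-sense heritability of the adjusted phenotype
#'   within each cycle, in (0, 1\].
#' @param effect_sd marginal SD of each QTL effect.
#' @param intercepts per-cycle intercepts (default 0).
#' @param seed RNG seed for the effect draw.
#' @return list of class `trait_architecture` with the effect matrix
#'   (`effects`, QTL x cycles).
#' @export
trait_architecture <- function(qtl_idx, n_cycles, rho_g = 0.5, h2 = 0.5,
                               effect_sd = 1, intercepts = 0, seed = NULL) {
  if (rho_g < 0 || rho_g > 1) stop("'rho_g' must lie in [0, 1]")
  if (h2 <= 0 || h2 > 1) stop("'h2' must lie in (0, 1]")
  if (length(qtl_idx) < 1) stop("need at least one QTL")
  q <- length(qtl_idx)
  eff <- with_seed(seed, {
    common <- rnorm(q)
    sapply(seq_len(n_cycles), function(c)
      effect_sd * (sqrt(rho_g) * common + sqrt(1 - rho_g) * rnorm(q)))
  })
  eff <- matrix(eff, nrow = q, ncol = n_cycles)
  structure(list(qtl_idx = as.integer(qtl_idx), n_cycles = n_cycles,
                 rho_g = rho_g, h2 = h2, effects = eff,
                 intercepts = rep_len(intercepts, n_cycles)),
            class = "trait_architecture")
}

# ---- population ---------------------------------------------------------

#' Simulate a multi-cycle DH population
#'
#' Simulates founders (shared founder IDs are literally the same genotype in
#' every cycle that uses them), generates each biparental DH family along
#' the map, computes true breeding values from the cycle-specific QTL
#' effects, and adds within-cycle Gaussian noise calibrated so that the
#' realized signal share matches the architecture's target heritability:
#' the residual variance in cycle c is var(BV_c) * (1 - h2)/h2.
#'
#' @param plan a [crossing_plan()].
#' @param map a [genetic_map()].
#' @param arch a [trait_architecture()]; QTL indices must be valid columns.
#' @param allele_freq founder presence probability (see
#'   [simulate_founders()]).
#' @param seed RNG seed (controls founders, meiosis and noise).
#' @return list of class `simulated_population`: `markers` (a
#'   [marker_matrix()] with cycle and family labels), `bv` (true breeding
#'   values), `pheno` (adjusted phenotypes), `pedigree` (data.frame).
#' @export
simulate_population <- function(plan, map, arch, allele_freq = 0.5,
                                seed = NULL) {
  if (!inherits(plan, "crossing_plan")) stop("'plan' must be a crossing_plan")
  if (!inherits(arch, "trait_architecture"))
    stop("'arch' must be a trait_architecture")
  validate_map(map)
  if (arch$n_cycles != plan$n_cycles)
    stop("architecture has ", arch$n_cycles, " cycles but plan has ",
         plan$n_cycles)
  if (max(arch$qtl_idx) > map$n_markers || min(arch$qtl_idx) < 1)
    stop("QTL indices out of marker range")
  with_seed(seed, {
    all_f <- unique(unlist(plan$founders_by_cycle))
    Xf <- simulate_founders(length(all_f), map, allele_freq)
    rownames(Xf) <- all_f
    fams <- plan$families
    rows <- vector("list", nrow(fams))
    ids <- cyc <- fam <- vector("list", nrow(fams))
    for (i in seq_len(nrow(fams))) {
      Xi <- make_dh_family(Xf[fams$parent_a[i], ], Xf[fams$parent_b[i], ],
                           map, fams$n_dh[i])
      rows[[i]] <- Xi
      ids[[i]] <- sprintf("C%d_FAM%02d_%03d", fams$cycle[i], i,
                          seq_len(fams$n_dh[i]))
      cyc[[i]] <- rep(fams$cycle[i], fams$n_dh[i])
      fam[[i]] <- rep(sprintf("FAM%02d", i), fams$n_dh[i])
    }
    X <- do.call(rbind, rows)
    ids <- unlist(ids); cycle <- unlist(cyc); family <- unlist(fam)
    mm <- marker_matrix(X, cycle = as.character(cycle), ids = ids,
                        family = family)
    n <- nrow(X)
    bv <- numeric(n)
    pheno <- numeric(n)
    for (c in seq_len(plan$n_cycles)) {
      sel <- which(cycle == c)
      if (!length(sel)) next
      bv[sel] <- arch$intercepts[c] +
        as.numeric(X[sel, arch$qtl_idx, drop = FALSE] %*% arch$effects[, c])
      g <- bv[sel] - mean(bv[sel])
      vg <- var(g)
      if (arch$h2 == 1 || vg == 0) {
        noise <- 0
        if (vg == 0 && arch$h2 < 1)
          warning("cycle ", c, ": zero genetic variance; phenotype is ",
                  "noise-free")
      } else {
        noise <- rnorm(length(sel), 0, sqrt(vg * (1 - arch$h2) / arch$h2))
      }
      pheno[sel] <- g + noise
    }
    pedigree <- data.frame(id = ids, cycle = as.character(cycle),
                           family = family,
                           parent_a = fams$parent_a[match(family,
                             sprintf("FAM%02d", seq_len(nrow(fams))))],
                           parent_b = fams$parent_b[match(family,
                             sprintf("FAM%02d", seq_len(nrow(fams))))],
                           stringsAsFactors = FALSE)
    structure(list(markers = mm, bv = setNames(bv, ids),
                   pheno = setNames(pheno, ids), pedigree = pedigree,
                   arch = arch),
              class = "simulated_population")
  })
}

#' @export
print.simulated_population <- function(x, ...) {
  cat("simulated_population: ", nrow(x$markers$X), " DH lines, ",
      ncol(x$markers$X), " markers, ",
      length(unique(x$markers$cycle)), " cycles\n", sep = "")
  invisible(x)
}

# ---- trial records ------------------------------------------------------

#' Simulate plot-level trial records (alpha-lattice style)
#'
#' Generates one record per line x location x replicate.  Within each
#' replicate the lines are randomized into incomplete blocks of (near)
#' equal size.  value = mu + g_i + L_j + R_k(j) + B_l(kj) + (GxL)_ij + e,
#' with L, R, B, GxL and e independent normal draws at the specified
#' variances; the genotype effect g_i is the line's true breeding value.
#'
#' @param population a [simulate_population()] result.
#' @param n_locations,n_reps,blocks_per_rep design counts (>= 1).
#' @param variance_spec list with elements `sigma2_b` (incomplete block),
#'   `sigma2_e` (residual), `sigma2_gxl`, `sigma2_loc`, `sigma2_rep`;
#'   missing elements default to `sigma2_b = 1, sigma2_e = 1` and 0
#'   otherwise.
#' @param mu overall trial mean.
#' @param seed RNG seed.
#' @return data.frame with columns `line`, `location`, `rep`, `block`,
#'   `value`.  The realized block effects are attached as attribute
#'   `"block_effects"` (named by block ID) for calibration checks.
#' @export
simulate_trial <- function(population, n_locations = 2, n_reps = 2,
                           blocks_per_rep = 5, variance_spec = list(),
                           mu = 0, seed = NULL) {
  if (!inherits(population, "simulated_population"))
    stop("'population' must be a simulated_population")
  if (n_locations < 1 || n_reps < 1 || blocks_per_rep < 1)
    stop("design counts must be >= 1")
  vs <- utils::modifyList(list(sigma2_b = 1, sigma2_e = 1, sigma2_gxl = 0,
                               sigma2_loc = 0, sigma2_rep = 0),
                          variance_spec)
  if (any(unlist(vs) < 0)) stop("variances must be non-negative")
  lines <- population$markers$ids
  g <- population$bv
  n <- length(lines)
  with_seed(seed, {
    loc_eff <- rnorm(n_locations, 0, sqrt(vs$sigma2_loc))
    gxl <- matrix(rnorm(n * n_locations, 0, sqrt(vs$sigma2_gxl)),
                  nrow = n)
    recs <- list()
    block_eff <- c()
    for (j in seq_len(n_locations)) {
      for (k in seq_len(n_reps)) {
        rep_eff <- rnorm(1, 0, sqrt(vs$sigma2_rep))
        ord <- sample.int(n)
        blk <- rep(seq_len(blocks_per_rep), length.out = n)[order(ord)]
        bid <- sprintf("L%d_R%d_B%d", j, k, seq_len(blocks_per_rep))
        be <- setNames(rnorm(blocks_per_rep, 0, sqrt(vs$sigma2_b)), bid)
        block_eff <- c(block_eff, be)
        e <- rnorm(n, 0, sqrt(vs$sigma2_e))
        recs[[length(recs) + 1]] <- data.frame(
          line = lines, location = paste0("LOC", j), rep = paste0("R", k),
          block = bid[blk],
          value = mu + g + loc_eff[j] + rep_eff + be[blk] + gxl[, j] + e,
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, recs)
    rownames(out) <- NULL
    attr(out, "block_effects") <- block_eff
    out
  })
}
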