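# Training/prediction scenarios and repeated-partition evaluation.
#
# A scenario fixes the composition of the training set: one or more past
# cycles in full, optionally augmented with a fraction (5/10/15%) of the
# prediction cycle.  The prediction cycle is split 85-15: the held-out 15%
# remainder is the only pool from which augmentation individuals are drawn,
# so the prediction set is identical across augmentation levels within a
# partition, and augmentation subsets are nested (5% within 10% within
# 15%).  Counts use ceiling(fraction * cycle size), which reproduces the
# published splits (e.g., a 486-line cycle gives 413 predicted and
# 25/49/73 augmentation lines).

#' Build a training/prediction scenario from per-cycle counts
#'
#' @param cycle_sizes named numeric vector of lines per cycle.
#' @param training_cycles names of cycles used in full for training.
#' @param augmentation_fraction fraction of the prediction cycle added to
#'   the training set (0, 0.05, 0.10 or 0.15 by convention; any value up
#'   to `holdout_fraction` is accepted).
#' @param prediction_cycle name of the predicted cycle (not in
#'   `training_cycles`).
#' @param seed partition seed stored with the scenario.
#' @param holdout_fraction share of the prediction cycle withheld from
#'   prediction (default 0.15).
#' @return Object of class `scenario` with realized `n_TS`, `n_PS`,
#'   `n_holdout`, `n_aug`.
#' @export
build_scenario <- function(cycle_sizes, training_cycles,
                           augmentation_fraction = 0, prediction_cycle,
                           seed = NULL, holdout_fraction = 0.15) {
  if (is.null(names(cycle_sizes))) stop("'cycle_sizes' must be named")
  unk <- setdiff(c(training_cycles, prediction_cycle), names(cycle_sizes))
  if (length(unk)) stop("unknown cycle(s): ", paste(unk, collapse = ", "))
  if (prediction_cycle %in% training_cycles)
    stop("the prediction cycle cannot be part of the training cycles")
  if (augmentation_fraction < 0 ||
      augmentation_fraction > holdout_fraction + 1e-12)
    stop("augmentation fraction (", augmentation_fraction,
         ") exceeds the held-out remainder (", holdout_fraction, ")")
  np <- cycle_sizes[[prediction_cycle]]
  n_holdout <- ceiling(holdout_fraction * np)
  n_ps <- np - n_holdout
  n_aug <- ceiling(augmentation_fraction * np)
  n_ts <- sum(cycle_sizes[training_cycles]) + n_aug
  structure(list(training_cycles = training_cycles,
                 prediction_cycle = prediction_cycle,
                 augmentation_fraction = augmentation_fraction,
                 n_TS = as.integer(n_ts), n_PS = as.integer(n_ps),
                 n_holdout = as.integer(n_holdout),
                 n_aug = as.integer(n_aug), seed = seed),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat("scenario: TS = {", paste(x$training_cycles, collapse = ", "),
      "} + ", round(100 * x$augmentation_fraction), "% of ",
      x$prediction_cycle, "  (n_TS = ", x$n_TS, ", n_PS = ", x$n_PS,
      ")\n", sep = "")
  invisible(x)
}

#' Realize a scenario as training/prediction ID sets
#'
#' Permutes the prediction cycle once per partition seed; the first `n_PS`
#' lines form the prediction set and augmentation takes the first `n_aug`
#' of the remainder, so the subsets for increasing fractions are nested.
#'
#' @param scenario a [build_scenario()] result.
#' @param ids,cycles line IDs and their cycle labels (same length).
#' @param seed partition seed (defaults to the scenario's).
#' @return list with `training_ids` and `prediction_ids`.
#' @export
scenario_partition <- function(scenario, ids, cycles, seed = scenario$seed) {
  cycles <- as.character(cycles)
  pred_pool <- ids[cycles == scenario$prediction_cycle]
  if (length(pred_pool) != scenario$n_PS + scenario$n_holdout)
    stop("prediction-cycle size does not match the scenario counts")
  perm <- with_seed(seed, sample(pred_pool))
  ps <- perm[seq_len(scenario$n_PS)]
  remainder <- perm[-seq_len(scenario$n_PS)]
  aug <- if (scenario$n_aug > 0) remainder[seq_len(scenario$n_aug)]
  else character(0)
  ts <- c(ids[cycles %in% scenario$training_cycles], aug)
  list(training_ids = ts, prediction_ids = ps)
}

#' Prediction accuracy rho = cor(y_PS, u_hat)
#'
#' @param y_PS observed (adjusted) phenotypes of the prediction set.
#' @param u_hat predicted breeding values, same order.
#' @return Pearson correlation.
#' @export
accuracy <- function(y_PS, u_hat) {
  if (length(y_PS) != length(u_hat)) stop("length mismatch")
  if (length(y_PS) < 3) stop("need at least 3 pairs for a correlation")
  if (sd(y_PS) == 0 || sd(u_hat) == 0)
    stop("correlation undefined for a constant vector")
  cor(y_PS, u_hat)
}

#' Accuracy gain percentages
#'
#' Gain1 = 100 (KBLUP - GBLUP) / GBLUP compares the non-sparse kernel
#' model with the non-sparse additive model; Gain2 = 100 (SSI - BLUP) /
#' BLUP compares a sparse index with its own non-sparse baseline.
#'
#' @param acc_gblup,acc_kblup,acc_blup,acc_ssi accuracies.
#' @return list with `gain1` and `gain2` (percent; NA when a denominator
#'   is zero or an input is missing).
#' @export
gain_statistics <- function(acc_gblup, acc_kblup = NA_real_,
                            acc_blup = NA_real_, acc_ssi = NA_real_) {
  g1 <- if (is.na(acc_kblup) || is.na(acc_gblup) || acc_gblup == 0)
    NA_real_ else 100 * (acc_kblup - acc_gblup) / acc_gblup
  g2 <- if (is.na(acc_ssi) || is.na(acc_blup) || acc_blup == 0)
    NA_real_ else 100 * (acc_ssi - acc_blup) / acc_blup
  list(gain1 = g1, gain2 = g2)
}

model_kernel_id <- function(model) {
  if (!grepl("^(G|K1|K2|K3|KA)(BLUP|SSI)$", model))
    stop("unknown model '", model, "'; expected e.g. GBLUP, GSSI, K1BLUP, ",
         "KASSI")
  sub("(BLUP|SSI)$", "", model)
}

model_is_sparse <- function(model) grepl("SSI$", model)

#' Run a repeated-partition prediction experiment
#'
#' For each partition seed, the prediction-cycle split is drawn once and
#' every model is evaluated on the same training/prediction sets (paired
#' comparisons).  Variance components (REML) and the cross-validated SSI
#' penalty are estimated on the realized training set only, and cached
#' across partitions that realize an identical training set.
#'
#' @param population a [simulate_population()] result, or a list with
#'   elements `markers` (a [marker_matrix()]) and `pheno` (named numeric).
#' @param models character vector from GBLUP, GSSI, K1BLUP, K1SSI, K2BLUP,
#'   K2SSI, K3BLUP, K3SSI, KABLUP, KASSI.
#' @param training_cycles,prediction_cycle,fractions scenario grid (one
#'   scenario per fraction).
#' @param n_partitions number of random partitions (paper: 100).
#' @param base_seed partition seeds are `base_seed + 0:(n_partitions-1)`.
#' @param theta Gaussian bandwidths for the K kernels.
#' @param n_folds,n_lambda_cv,min_ratio_cv cross-validation controls.
#' @param cv_reuse `"training-set"` re-runs the penalty cross-validation
#'   whenever the realized training set changes (every partition when the
#'   training set is augmented); `"scenario"` tunes the penalty fraction
#'   once per scenario on the first partition's training set and reuses it
#'   (one reported lambda_CV per training-set composition, at a fraction
#'   of the compute).
#' @param tol solver tolerance used for cross-validation and SSI Hat
#'   matrices.
#' @param ka_gibbs list of `n_iter`, `burn_in` for the kernel-averaging
#'   weights (only used by KA models).
#' @return Long-format data.frame: partition, seed, model, fraction,
#'   accuracy, n_sup, pct_sparsity, lambda, lambda_cv_fraction, lambda0,
#'   h2, n_TS, n_PS; failed cells carry NA accuracy and an `error`
#'   message.
#' @export
run_experiment <- function(population, models = c("GBLUP", "GSSI"),
                           training_cycles, prediction_cycle,
                           fractions = 0, n_partitions = 100,
                           base_seed = 1, theta = c(0.2, 1, 5),
                           n_folds = 10, n_lambda_cv = 100,
                           min_ratio_cv = 0.001,
                           cv_reuse = c("training-set", "scenario"),
                           tol = 1e-4,
                           ka_gibbs = list(n_iter = 3000, burn_in = 500)) {
  cv_reuse <- match.arg(cv_reuse)
  if (!length(models) || !length(fractions)) stop("empty models/scenarios")
  mm <- population$markers
  pheno <- population$pheno
  ids <- mm$ids
  cycles <- mm$cycle
  kernel_ids <- unique(vapply(models, model_kernel_id, ""))
  kernels <- list()
  if (any(kernel_ids == "G"))
    kernels$G <- grm(center_scale_markers(mm))
  if (any(kernel_ids != "G")) {
    d2 <- scaled_sq_distances(mm)
    gaussians <- lapply(theta, function(t) gaussian_kernel(d2, t))
    names(gaussians) <- paste0("K", seq_along(theta))
    kernels <- c(kernels, gaussians[intersect(kernel_ids,
                                              names(gaussians))])
    if ("KA" %in% kernel_ids) kernels$.gaussians <- gaussians
  }
  sizes <- table(cycles)
  cycle_sizes <- setNames(as.numeric(sizes), names(sizes))
  # caches keyed by (kernel, realized-training-set) strings; keys can be
  # long, so use match() on a key vector rather than environment names
  new_cache <- function() {
    e <- new.env(parent = emptyenv())
    e$keys <- character(0); e$vals <- list()
    e
  }
  cache_get <- function(cache, key) {
    i <- match(key, cache$keys)
    if (is.na(i)) NULL else cache$vals[[i]]
  }
  cache_set <- function(cache, key, val) {
    cache$keys <- c(cache$keys, key)
    cache$vals[[length(cache$keys)]] <- val
    val
  }
  vc_cache <- new_cache()
  cv_cache <- new_cache()
  ka_cache <- new_cache()
  rows <- list()
  for (p in seq_len(n_partitions)) {
    seed <- base_seed + p - 1
    for (fr in fractions) {
      sc <- build_scenario(cycle_sizes, training_cycles, fr,
                           prediction_cycle, seed = seed)
      part <- scenario_partition(sc, ids, cycles)
      ts_key <- paste(sort(part$training_ids), collapse = "\r")
      y_ts <- center_phenotypes(pheno, part$training_ids)[part$training_ids]
      y_ps <- pheno[part$prediction_ids]
      for (model in models) {
        kid <- model_kernel_id(model)
        row <- data.frame(partition = p, seed = seed, model = model,
                          fraction = fr, accuracy = NA_real_,
                          n_sup = NA_real_, pct_sparsity = NA_real_,
                          lambda = NA_real_,
                          lambda_cv_fraction = NA_real_,
                          lambda0 = NA_real_, h2 = NA_real_,
                          n_TS = sc$n_TS, n_PS = sc$n_PS,
                          error = NA_character_,
                          stringsAsFactors = FALSE)
        res <- tryCatch({
          Kobj <- if (kid == "KA") {
            key <- paste0("KA|", ts_key)
            ka <- cache_get(ka_cache, key)
            if (is.null(ka)) {
              gk <- kernels$.gaussians
              sub <- lapply(gk, function(k)
                kernel_matrix(k$K[part$training_ids, part$training_ids],
                              part$training_ids, "gaussian", k$params))
              vcm <- gibbs_multi_kernel(y_ts, sub,
                                        n_iter = ka_gibbs$n_iter,
                                        burn_in = ka_gibbs$burn_in,
                                        seed = seed)
              ka <- cache_set(ka_cache, key,
                              kernel_average(gk, vcm$sigma2_ak))
            }
            ka
          } else kernels[[kid]]
          blk <- partition_kernel(Kobj, part$training_ids,
                                  part$prediction_ids)
          vkey <- paste0(kid, "|", ts_key)
          vc <- cache_get(vc_cache, vkey)
          if (is.null(vc))
            vc <- cache_set(vc_cache, vkey,
                            reml_single_kernel(y_ts, blk$K_TS))
          l0 <- variance_ratio(vc)
          row$lambda0 <- l0
          row$h2 <- vc$h2
          if (model_is_sparse(model)) {
            ckey <- if (cv_reuse == "scenario")
              paste0(kid, "|scenario|", fr) else vkey
            cv <- cache_get(cv_cache, ckey)
            if (is.null(cv))
              cv <- cache_set(cv_cache, ckey, cross_validate_lambda(
                y_ts, blk$K_TS, l0, n_folds = n_folds,
                n_lambda = n_lambda_cv, min_ratio = min_ratio_cv,
                seed = seed, tol = tol))
            lam <- cv$selected_fraction * max(abs(blk$K_PS_TS))
            hat <- ssi_hat(blk, lambda0 = l0, lambda = lam, tol = tol)
            row$lambda_cv_fraction <- cv$selected_fraction
          } else {
            hat <- blup_hat(blk, lambda0 = l0)
          }
          pr <- predict_hat(hat, y_ts)
          row$lambda <- hat$lambda
          row$n_sup <- pr$n_sup_mean
          row$pct_sparsity <- pr$pct_sparsity
          row$accuracy <- accuracy(y_ps, pr$u_hat[part$prediction_ids])
          row
        }, error = function(e) {
          row$error <- conditionMessage(e)
          row
        })
        rows[[length(rows) + 1]] <- res
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize a run_experiment() table
#'
#' Mean and SD of accuracy by model and fraction, with the gain of each
#' model relative to GBLUP (when present).
#'
#' @param results output of [run_experiment()].
#' @return data.frame with one row per model x fraction.
#' @export
summarize_experiment <- function(results) {
  ok <- !is.na(results$accuracy)
  agg <- aggregate(accuracy ~ model + fraction, data = results[ok, ],
                   FUN = function(a) c(mean = mean(a), sd = sd(a)))
  out <- data.frame(model = agg$model, fraction = agg$fraction,
                    accuracy_mean = agg$accuracy[, "mean"],
                    accuracy_sd = agg$accuracy[, "sd"])
  ns <- aggregate(cbind(n_sup, pct_sparsity, lambda0, h2) ~
                    model + fraction, data = results[ok, ], FUN = mean)
  out <- merge(out, ns, by = c("model", "fraction"), all.x = TRUE)
  base <- out[out$model == "GBLUP", c("fraction", "accuracy_mean")]
  if (nrow(base)) {
    names(base)[2] <- "gblup_mean"
    out <- merge(out, base, by = "fraction", all.x = TRUE)
    out$gain_vs_gblup_pct <- 100 * (out$accuracy_mean - out$gblup_mean) /
      out$gblup_mean
    out$gblup_mean <- NULL
  }
  out[order(out$fraction, out$model), ]
}
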