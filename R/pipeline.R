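#' Pipeline configuration
#'
#' One configuration object driving the full experiment: simulate a labeled
#' cohort, standardize globally, transform each sequence to a daily
#' longitudinal density by GP regression, learn stacked sparse-autoencoder
#' features from 30-day patches, pool per-sequence feature vectors, train
#' the four comparator classifiers, and (optionally) embed the feature
#' spaces in 2-D. All stage seeds derive from `master_seed` via
#' [stage_seed()].
#'
#' @param generator a [generator_config()] (its `seed` is overridden from
#'   `master_seed`).
#' @param warp a [warp_config()].
#' @param kernel `"rq"` (default) or `"se"`.
#' @param grid_padding_days grid padding (default 15).
#' @param patch_window_days patch length (default 30).
#' @param patch_rate patches per 365 days (default 50).
#' @param hidden_units integer vector of 1 or 2 hidden-layer sizes
#'   (default `c(100, 100)`).
#' @param rho,beta,lambda autoencoder sparsity target and penalty weights.
#' @param ae_maxit autoencoder optimizer iteration cap per layer.
#' @param gp_maxit hyperparameter-fit iteration cap.
#' @param gp_fit_max_sequences at most this many training sequences enter the
#'   summed marginal-likelihood fit (a uniform subsample; the objective is a
#'   sum over sequences, so a subsample estimates the same optimum).
#' @param test_fraction held-out fraction (default 0.30).
#' @param en_alpha elastic-net mixing weight (default 0.95).
#' @param cv_folds classifier cross-validation folds (default 5).
#' @param n_boot bootstrap iterations for the test AUC CI (default 30).
#' @param embed if TRUE, also compute t-SNE embeddings (perplexity 20 for
#'   learned spaces, 5 for the engineered space).
#' @param master_seed integer master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            warp = warp_config(),
                            kernel = "rq",
                            grid_padding_days = 15,
                            patch_window_days = 30,
                            patch_rate = 50,
                            hidden_units = c(100L, 100L),
                            rho = 0.05, beta = 3, lambda = 3e-4,
                            ae_maxit = 400L,
                            gp_maxit = 60L,
                            gp_fit_max_sequences = 150L,
                            test_fraction = 0.30,
                            en_alpha = 0.95,
                            cv_folds = 5L,
                            n_boot = 30L,
                            embed = FALSE,
                            master_seed = 1L) {
  check_that(length(hidden_units) %in% 1:2 && all(hidden_units > 0),
             "hidden_units must be 1 or 2 positive counts")
  check_that(test_fraction > 0 && test_fraction < 1,
             "test_fraction must lie in (0,1)")
  check_that(kernel %in% c("rq", "se"), "kernel must be 'rq' or 'se'")
  for (f in c("grid_padding_days", "patch_window_days", "patch_rate"))
    check_that(is_pos_scalar(get(f)), paste(f, "must be positive"))
  structure(list(generator = generator, warp = warp, kernel = kernel,
                 grid_padding_days = grid_padding_days,
                 patch_window_days = patch_window_days,
                 patch_rate = patch_rate,
                 hidden_units = as.integer(hidden_units),
                 rho = rho, beta = beta, lambda = lambda,
                 ae_maxit = ae_maxit, gp_maxit = gp_maxit,
                 gp_fit_max_sequences = gp_fit_max_sequences,
                 test_fraction = test_fraction, en_alpha = en_alpha,
                 cv_folds = cv_folds, n_boot = n_boot, embed = embed,
                 master_seed = master_seed),
            class = "pipeline_config")
}

#' Standardize sequences to zero global mean and unit standard deviation
#'
#' The mean and standard deviation are computed over all pooled training-set
#' values only, then applied unchanged to both sets (no test-set leakage).
#'
#' @param train,test lists of [obs_sequence()]s (`test` may be empty).
#' @return list with standardized `train`, `test`, and the constants `mean`
#'   and `sd`.
#' @export
standardize_global <- function(train, test = list()) {
  check_that(length(train) > 0, "empty training set")
  v <- unlist(lapply(train, `[[`, "values"))
  m <- mean(v)
  s <- stats::sd(v)
  check_that(is.finite(s) && s > 0, "training values have zero variance")
  tf <- function(s_) {
    s_$values <- (s_$values - m) / s
    s_
  }
  list(train = lapply(train, tf), test = lapply(test, tf), mean = m, sd = s)
}

# One sequence -> density -> patches -> activations -> pooled features.
# Returns NULL when the density yields no usable patch (short grid or all
# patches degenerate).
sequence_features <- function(sequence, hp, layers, cfg, seed) {
  dens <- posterior_density(sequence, hp, cfg$kernel, cfg$warp,
                            cfg$grid_padding_days)
  ps <- suppressWarnings(
    extract_patches(dens, cfg$patch_rate, cfg$patch_window_days, seed))
  if (ncol(ps$mu) == 0) return(NULL)
  H1 <- matrix(encode(ps$mu, layers[[1]]), nrow = layers[[1]]$config$n_hidden)
  out <- list(layer1 = pool_sequence_features(H1, ps$patch_sd))
  if (length(layers) > 1) {
    H2 <- matrix(encode(H1, layers[[2]]), nrow = layers[[2]]$config$n_hidden)
    out$layer2 <- pool_sequence_features(H2, ps$patch_sd)
  }
  out
}

# Train/test one classifier and report its AUCs; the second factor level of
# the labels is the positive class. All four comparator classifiers receive
# the same `seed`, so they are identical except for their input features
# (same CV fold assignment, same bootstrap resampling plan).
eval_one_feature_set <- function(name, x_train, y_train, x_test, y_test,
                                 cfg, seed) {
  fit <- train_classifier(x_train, y_train, cfg$en_alpha, cfg$cv_folds, seed)
  auc_tr <- auc_empirical(predict(fit, x_train), y_train)
  sc_te <- predict(fit, x_test)
  auc_te <- auc_empirical(sc_te, y_test)
  ci <- auc_ci_bootstrap(sc_te, y_test, cfg$n_boot, stage_seed(seed, "boot"))
  data.frame(feature_set = name, auc_train = auc_tr, auc_test = auc_te,
             ci_low = ci[1], ci_high = ci[2],
             n_train = length(y_train), n_test = length(y_test),
             selected_regularization = fit$lambda)
}

#' Run the full phenotype-discovery experiment
#'
#' Executes simulate, split, standardize, transform, feature learning,
#' pooling, the four-classifier evaluation (layer-1 pooled, layer-2 pooled,
#' engineered, baseline mean; layer-2 omitted when one hidden layer is
#' configured) and optional embedding, persisting every intermediate
#' artifact under `out_dir` together with a manifest. Re-running with an
#' identical configuration reproduces identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir run directory (created; contents overwritten).
#' @return invisibly, a list with the evaluation `report` (data.frame),
#'   fitted `hp`, trained `layers`, standardization constants, and the run
#'   directory.
#' @export
run_pipeline <- function(config, out_dir) {
  check_that(inherits(config, "pipeline_config"), "config must be a pipeline_config")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ms <- config$master_seed
  log_stage <- function(...) message(sprintf("[phenolearn] %s", sprintf(...)))

  # -- simulate ---------------------------------------------------------
  gen <- config$generator
  gen$seed <- stage_seed(ms, "simulate")
  cohort <- generate_cohort(gen)
  write_sequences(cohort, file.path(out_dir, "sequences.tsv"),
                  file.path(out_dir, "labels.tsv"))
  log_stage("simulated %d sequences", length(cohort))

  # -- split + standardize ---------------------------------------------
  sp <- split_train_test(cohort, config$test_fraction, stage_seed(ms, "split"))
  std <- standardize_global(sp$train, sp$test)
  jsonlite::write_json(list(mean = std$mean, sd = std$sd),
                       file.path(out_dir, "standardization.json"),
                       auto_unbox = TRUE, digits = NA)
  log_stage("split %d train / %d test; global mean %.3f sd %.3f",
            length(std$train), length(std$test), std$mean, std$sd)

  # -- fit GP hyperparameters on (a subsample of) the training set ------
  fit_set <- std$train
  if (length(fit_set) > config$gp_fit_max_sequences) {
    old <- .Random.seed_save(); set.seed(stage_seed(ms, "gp_subsample"))
    fit_set <- fit_set[sort(sample.int(length(fit_set),
                                       config$gp_fit_max_sequences))]
    .Random.seed_restore(old)
  }
  warped <- lapply(fit_set, function(s)
    list(times = warp_times(s$times, config$warp), values = s$values,
         record_id = s$record_id))
  # data-driven init: start the length scale at a few median warped
  # inter-observation intervals so the optimizer starts in the smooth basin
  # (a far-off init can collapse the noise term into the signal)
  med_int <- stats::median(unlist(lapply(warped, function(s) diff(s$times))))
  init_hp <- gp_hyperparameters(1, max(5 * med_int, 1), 1, 0.3)
  hp <- fit_hyperparameters(warped, config$kernel, init_hp, config$gp_maxit)
  jsonlite::write_json(c(unclass(hp), list(kernel = config$kernel,
                                           objective = attr(hp, "objective"),
                                           warp_a = config$warp$a,
                                           warp_b = config$warp$b)),
                       file.path(out_dir, "hyperparameters.json"),
                       auto_unbox = TRUE, digits = NA)
  log_stage("fitted %s kernel on %d sequences (lml %.1f)", config$kernel,
            length(warped), attr(hp, "objective"))

  # -- transform + patch extraction (training set) ----------------------
  densify <- function(s) posterior_density(s, hp, config$kernel, config$warp,
                                           config$grid_padding_days)
  train_dens <- lapply(std$train, densify)
  write_densities(train_dens, file.path(out_dir, "densities_train.tsv"))
  train_patches <- bind_patches(lapply(train_dens, function(d)
    suppressWarnings(extract_patches(d, config$patch_rate,
                                     config$patch_window_days,
                                     stage_seed(ms, paste0("patch_", d$record_id))))))
  log_stage("extracted %d training patches", ncol(train_patches$mu))

  # -- feature learning -------------------------------------------------
  nh <- config$hidden_units
  cfg1 <- layer_config(config$patch_window_days, nh[1], config$rho,
                       config$beta, config$lambda, "normalized_squared_error")
  if (length(nh) > 1) {
    cfg2 <- layer_config(nh[1], nh[2], config$rho, config$beta,
                         config$lambda, "squared_error")
    layers <- stack_layers(train_patches, cfg1, cfg2, config$ae_maxit,
                           c(stage_seed(ms, "ae_layer1"),
                             stage_seed(ms, "ae_layer2")))
    layers <- list(layers$layer1, layers$layer2)
  } else {
    layers <- list(train_layer(train_patches, cfg1, maxit = config$ae_maxit,
                               seed = stage_seed(ms, "ae_layer1")))
  }
  for (i in seq_along(layers))
    write_layer(layers[[i]], file.path(out_dir, sprintf("layer%d", i)))
  log_stage("trained %d autoencoder layer(s)", length(layers))

  # -- pooled + comparator features -------------------------------------
  build_features <- function(seqs) {
    rows1 <- list(); rows2 <- list(); rowse <- list(); rowsb <- list()
    ids <- character(0); labs <- character(0)
    for (s in seqs) {
      f <- sequence_features(s, hp, layers, config,
                             stage_seed(ms, paste0("patch_", s$record_id)))
      if (is.null(f)) next
      ids <- c(ids, s$record_id); labs <- c(labs, s$label)
      rows1[[length(rows1) + 1L]] <- f$layer1
      if (!is.null(f$layer2)) rows2[[length(rows2) + 1L]] <- f$layer2
      rowse[[length(rowse) + 1L]] <- engineered_features(s)
      rowsb[[length(rowsb) + 1L]] <- baseline_feature(s)
    }
    list(record_id = ids, label = labs,
         layer1_pooled = do.call(rbind, rows1),
         layer2_pooled = if (length(rows2)) do.call(rbind, rows2),
         engineered = do.call(rbind, rowse),
         baseline_mean = do.call(rbind, rowsb))
  }
  ftr <- build_features(std$train)
  fte <- build_features(std$test)
  sets <- c("layer1_pooled", if (length(layers) > 1) "layer2_pooled",
            "engineered", "baseline_mean")
  for (nm in sets) {
    write_feature_table(ftr[[nm]], ftr$record_id, ftr$label,
                        file.path(out_dir, sprintf("features_%s_train.tsv", nm)))
    write_feature_table(fte[[nm]], fte$record_id, fte$label,
                        file.path(out_dir, sprintf("features_%s_test.tsv", nm)))
  }
  log_stage("pooled features for %d train / %d test sequences",
            length(ftr$record_id), length(fte$record_id))

  # -- four-classifier evaluation ---------------------------------------
  clf_seed <- stage_seed(ms, "classifier")
  report <- do.call(rbind, lapply(sets, function(nm)
    eval_one_feature_set(nm, ftr[[nm]], ftr$label, fte[[nm]], fte$label,
                         config, clf_seed)))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       dataframe = "rows", digits = NA)
  log_stage("evaluation report written (%d classifiers)", nrow(report))

  # -- optional 2-D embeddings ------------------------------------------
  if (isTRUE(config$embed)) {
    all_lab <- c(ftr$label, fte$label)
    for (nm in setdiff(sets, "baseline_mean")) {
      perp <- if (nm == "engineered") 5 else 20
      xx <- rbind(ftr[[nm]], fte[[nm]])
      if (nrow(xx) > 3 * perp) {
        Y <- embed_2d(xx, perp, stage_seed(ms, paste0("embed_", nm)))
        utils::write.table(
          data.frame(record_id = c(ftr$record_id, fte$record_id),
                     label = all_lab, x = Y[, 1], y = Y[, 2]),
          file.path(out_dir, sprintf("embedding_%s.tsv", nm)),
          sep = "\t", row.names = FALSE, quote = FALSE)
      }
    }
    log_stage("embeddings written")
  }

  # -- manifest ---------------------------------------------------------
  cfg_json <- jsonlite::toJSON(unclass_deep(config), auto_unbox = TRUE,
                               digits = NA)
  manifest <- list(
    package = "phenolearn",
    version = as.character(utils::packageVersion("phenolearn")),
    master_seed = ms,
    config = jsonlite::fromJSON(cfg_json, simplifyVector = TRUE),
    config_hash = fnv1a(cfg_json),
    n_sequences = length(cohort), n_train = length(std$train),
    n_test = length(std$test), n_train_patches = ncol(train_patches$mu),
    stage_seeds = list(simulate = stage_seed(ms, "simulate"),
                       split = stage_seed(ms, "split"),
                       ae_layer1 = stage_seed(ms, "ae_layer1"),
                       ae_layer2 = stage_seed(ms, "ae_layer2")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(report = report, hp = hp, layers = layers,
                 standardization = list(mean = std$mean, sd = std$sd),
                 out_dir = out_dir))
}

# strip S3 classes recursively so jsonlite serializes configs plainly
unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

# cheap rolling hash of a string, hex-encoded (manifest fingerprint only)
fnv1a <- function(s) {
  h <- 5381
  for (c in utf8ToInt(as.character(s))) h <- (h * 33 + c) %% 2147483647
  sprintf("%08x", h)
}
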