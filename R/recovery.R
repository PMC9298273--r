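# Desk-scale recovery experiments: the package's own end-to-end checks that
# the classifier grid attributes a synthetic phenotype to the marker that
# carries it, and that cross-condition transfer ranks conditions by shared
# phenotype direction.

# Effect table where only one compartment carries the mutant phenotype.
single_compartment_effects <- function(compartment = c("nuclear", "neurite")) {
  compartment <- match.arg(compartment)
  eff <- condition_effects()
  eff[eff$condition == "mutant",
      c("nuclear_irregularity", "neurite_fragmentation")] <- 0
  if (compartment == "nuclear")
    eff[eff$condition == "mutant", "nuclear_irregularity"] <- 0.30
  else
    eff[eff$condition == "mutant", "neurite_fragmentation"] <- 0.30
  eff
}

# Recovery-scale phenotype base: denser neurite network so that small
# (256 px) fields still carry several trees, moderate read noise.
recovery_base_params <- function() {
  phenotype_params(neurite_density = 25, noise_sd = 100)
}

# Render a balanced two-class (or multi-condition) field set. Each well is
# one culture: `fields_per_well` fields from one cell line, one experiment,
# one condition. Lines and experiments are cycled across wells.
build_condition_fields <- function(conditions, wells_per_condition, seed,
                                   effects = condition_effects(),
                                   base = recovery_base_params(),
                                   size = 256, n_z = 3, fields_per_well = 2,
                                   lines = list(
                                     control = c("CTRL1", "CTRL2", "CTRL3"),
                                     mutant = c("MUT1", "MUT2", "MUT3", "MUT4")),
                                   experiments = c("EXP1", "EXP2")) {
  fields <- list()
  well_i <- 0
  for (cond in conditions) {
    # stress conditions are applied to control lines, as in the assay design
    pool <- lines[[cond]] %||% lines$control
    for (w in seq_len(wells_per_condition)) {
      well_i <- well_i + 1
      line <- pool[(w - 1) %% length(pool) + 1]
      ex <- experiments[(w - 1) %% length(experiments) + 1]
      spec <- culture_spec(cond, line, ex,
                           seed = derive_seed(seed, "culture", cond, w),
                           base = base, effects = effects)
      for (f in seq_len(fields_per_well)) {
        fields[[length(fields) + 1]] <-
          render_field(spec, size = size, n_z = n_z,
                       well = sprintf("W%03d", well_i), field = f)
      }
    }
  }
  fields
}

# Preprocessing and training settings shared by the recovery experiments:
# 128-px tiles resized to 64, scratch CNN at a from-scratch learning rate.
recovery_pp_config <- function(resize_to = 64)
  preprocess_config(tile_size = 128, resize_to = resize_to)

recovery_clf_config <- function(seed, epochs = 6)
  classifier_config(learning_rate = 0.01, epochs = epochs, seed = seed)

#' Marker-relevance recovery experiment
#'
#' Generates a two-class synthetic dataset in which the disease phenotype
#' lives in exactly one compartment — nuclear-outline irregularity
#' (`"nuclear"`) or neurite fragmentation (`"neurite"`) — and runs the
#' cross-validated grid for the DAPI-only and BIII-only classifiers. If the
#' pipeline works, the classifier trained on the phenotype-bearing marker
#' dominates the AUC distribution of the other and of chance.
#'
#' @param compartment `"nuclear"` or `"neurite"`.
#' @param seed Integer seed.
#' @param wells_per_condition Wells (cultures) per class.
#' @param fields_per_well Field images per well.
#' @param k,n_subsets Cross-validation folds and repeats.
#' @param epochs Training epochs per fold.
#' @return List with `fold_aucs` (the AUC table), `median_auc` (named by
#'   combination), and `mw` (one-sided Mann-Whitney test that the
#'   informative marker's AUCs exceed the other's).
#' @export
marker_relevance_experiment <- function(compartment = c("nuclear", "neurite"),
                                        seed = 1, wells_per_condition = 16,
                                        fields_per_well = 2, k = 10,
                                        n_subsets = 1, epochs = 6) {
  compartment <- match.arg(compartment)
  fields <- build_condition_fields(
    c("control", "mutant"), wells_per_condition, seed,
    effects = single_compartment_effects(compartment),
    fields_per_well = fields_per_well)
  combos <- list(channel_combination("DAPI"), channel_combination("BIII"))
  fold_aucs <- run_cv_grid(
    fields, tests = list(isALS = list(positive = "mutant", negative = "control")),
    combinations = combos, n_subsets = n_subsets, k = k,
    config = recovery_clf_config(seed, epochs),
    pp_config = recovery_pp_config())
  auc_dapi <- fold_aucs$auc[fold_aucs$combination == "DAPI"]
  auc_biii <- fold_aucs$auc[fold_aucs$combination == "BIII"]
  informative <- if (compartment == "nuclear") auc_dapi else auc_biii
  other <- if (compartment == "nuclear") auc_biii else auc_dapi
  list(fold_aucs = fold_aucs,
       median_auc = c(DAPI = stats::median(auc_dapi),
                      BIII = stats::median(auc_biii)),
       mw = mann_whitney_one_sided(other, informative, "b_greater"))
}

#' Cross-condition phenotype transfer experiment
#'
#' Trains disease (mutant-vs-control) classifiers on the DAPI-only and
#' BIII-only channels, then applies them to cultures from stress conditions
#' never seen in training. In the generator's phenotype design heat stress
#' shifts the same parameters as the mutant condition (at reduced
#' magnitude) while osmotic and oxidative stress move orthogonal
#' parameters, so a working pipeline scores heat-stressed cultures higher
#' and clusters heat next to the mutant profile.
#'
#' @param seed Integer seed.
#' @param wells_per_condition Wells per condition.
#' @param fields_per_well Field images per well.
#' @param epochs Training epochs.
#' @return List with `predictions` (per-culture table across conditions for
#'   each classifier), `condition_means` (mean disease probability per
#'   condition per classifier), `effects` (LMM effect of each condition on
#'   each classifier's predictions vs control), `profile` (effect-size
#'   matrix), `clustering` ([ward_cluster()] result) and
#'   `heat_adjacent_to_mutant` (logical).
#' @export
phenotype_transfer_experiment <- function(seed = 1, wells_per_condition = 8,
                                          fields_per_well = 2, epochs = 6) {
  conditions <- c("control", "mutant", "oxidative", "heat", "osmotic")
  fields <- build_condition_fields(conditions, wells_per_condition, seed,
                                   effects = condition_effects(),
                                   fields_per_well = fields_per_well)
  pp <- recovery_pp_config()
  is_train <- vapply(fields, function(fs)
    fs$metadata$spec$condition %in% c("control", "mutant"), logical(1))
  combos <- list(channel_combination("DAPI"), channel_combination("BIII"))
  preds <- list(); effects_rows <- list()
  for (combo in combos) {
    ds <- build_crop_dataset(fields[is_train], combo, pp)
    aug <- augment_crops(ds$crops, as.integer(ds$meta$condition == "mutant"))
    model <- train_classifier(aug$crops, aug$labels,
                              recovery_clf_config(
                                derive_seed(seed, "transfer", combo$label),
                                epochs))
    model$combo <- combo
    pt <- apply_classifier(model, fields, combo, pp)
    cu <- pt$cultures
    cu$classifier <- paste0("ALS|", combo$label)
    preds[[combo$label]] <- cu
    base <- cu[cu$condition == "control", ]
    for (cond in setdiff(conditions, "control")) {
      d <- rbind(base, cu[cu$condition == cond, ])
      d$prediction <- d$prob
      d$condition <- as.integer(d$condition != "control")
      est <- suppressWarnings(fit_random_intercept_lmm(d))
      effects_rows[[length(effects_rows) + 1]] <- data.frame(
        condition = cond, classifier = paste0("ALS|", combo$label),
        beta = est$beta_hat, se = est$se, chi2 = est$chi2, p = est$p,
        stringsAsFactors = FALSE)
    }
  }
  predictions <- do.call(rbind, preds)
  effects <- do.call(rbind, effects_rows)
  cmeans <- aggregate(prob ~ condition + classifier, data = predictions,
                      FUN = mean)
  profile <- matrix(effects$beta,
                    nrow = length(unique(effects$condition)),
                    dimnames = list(unique(effects$condition),
                                    unique(effects$classifier)))
  cl <- ward_cluster(profile)
  list(predictions = predictions, condition_means = cmeans,
       effects = effects, profile = profile, clustering = cl,
       heat_adjacent_to_mutant = leaves_adjacent(cl, "heat", "mutant"))
}
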