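# Channel-ablation classifier grid: combination enumeration, stratified CV,
# ROC-AUC, and crop -> image -> culture probability aggregation.

#' Enumerate the legal channel combinations
#'
#' Single channels (DAPI, BIII, each RBP), the DAPI:BIII pair, and
#' DAPI:BIII:RBP triples — with five RBP markers this yields the 13
#' combinations of the classifier grid.
#'
#' @param rbp_markers Character vector of distinct RBP marker names.
#' @return List of [channel_combination()] objects in deterministic order:
#'   DAPI, BIII, one per RBP, DAPI:BIII, then DAPI:BIII:RBP per RBP.
#' @export
#' @examples
#' length(enumerate_channel_combinations(
#'   c("TDP43", "SFPQ", "FUS", "hnRNPA1", "hnRNPK")))  # 13
enumerate_channel_combinations <- function(rbp_markers = character(0)) {
  if (anyDuplicated(rbp_markers)) stopf("duplicate RBP markers")
  combos <- list(channel_combination("DAPI"), channel_combination("BIII"))
  for (m in rbp_markers)
    combos[[length(combos) + 1]] <- channel_combination(m)
  combos[[length(combos) + 1]] <- channel_combination(c("DAPI", "BIII"))
  for (m in rbp_markers)
    combos[[length(combos) + 1]] <- channel_combination(c("DAPI", "BIII", m))
  combos
}

#' Stratified k-fold assignment
#'
#' Shuffles each class independently and deals its members to folds in
#' round-robin order, so per-fold class counts differ by at most one from
#' `n_class / k` and the folds partition the index set.
#'
#' @param labels Vector of class labels.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed for the shuffles.
#' @return Integer vector in 1..k, same length as `labels`.
#' @export
make_stratified_folds <- function(labels, k = 10, seed = 1) {
  if (k < 2) stopf("'k' must be >= 2")
  fold <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    if (length(idx) < k)
      stopf("class '%s' has %d members, fewer than k = %d folds",
            cls, length(idx), k)
    idx <- with_seed(derive_seed(seed, "fold", as.character(cls)),
                     sample(idx))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Area under the ROC curve
#'
#' The probability that a random positive scores above a random negative,
#' counting ties as one half — computed from midranks, which is exactly the
#' pairwise definition.
#'
#' @param scores_pos,scores_neg Non-empty numeric score vectors.
#' @return AUC in \[0, 1\].
#' @export
#' @examples
#' roc_auc(c(0.8, 0.4), c(0.6, 0.2))  # 0.75
roc_auc <- function(scores_pos, scores_neg) {
  np <- length(scores_pos); nn <- length(scores_neg)
  if (np == 0 || nn == 0) stopf("both score vectors must be non-empty")
  r <- rank(c(scores_pos, scores_neg))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Aggregate crop probabilities up the averaging lineage
#'
#' Image-level probabilities are arithmetic means of their crops' and
#' culture-level probabilities arithmetic means of their images' — the
#' two-level averaging that turns per-crop classifier outputs into one
#' probability per culture.
#'
#' @param crop_probs data.frame with columns `crop`, `image`, `culture`,
#'   `prob` (plus any metadata columns, carried through at culture level
#'   when constant within culture).
#' @return List of class `prediction_table` with data.frames `crops`,
#'   `images`, `cultures` (the latter with an `n_images` column).
#' @export
aggregate_predictions <- function(crop_probs) {
  req <- c("crop", "image", "culture", "prob")
  miss <- setdiff(req, names(crop_probs))
  if (length(miss) > 0) stopf("crop table lacks column '%s'", miss[1])
  orphan <- crop_probs$crop[is.na(crop_probs$image) | is.na(crop_probs$culture)]
  if (length(orphan) > 0)
    stopf("crop '%s' is not linked to an image and culture", orphan[1])
  if (any(crop_probs$prob < 0 | crop_probs$prob > 1))
    stopf("crop probabilities must lie in [0, 1]")

  img <- aggregate(prob ~ image + culture, data = crop_probs, FUN = mean)
  cul <- aggregate(prob ~ culture, data = img, FUN = mean)
  n_img <- aggregate(image ~ culture, data = img, FUN = length)
  names(n_img)[2] <- "n_images"
  cul <- merge(cul, n_img, by = "culture", sort = TRUE)

  meta_cols <- setdiff(names(crop_probs), c(req, "prob"))
  for (mc in meta_cols) {
    u <- unique(crop_probs[, c("culture", mc)])
    if (!anyDuplicated(u$culture))
      cul <- merge(cul, u, by = "culture", sort = TRUE)
  }
  structure(list(crops = crop_probs,
                 images = img[order(img$culture, img$image), ],
                 cultures = cul),
            class = "prediction_table")
}

#' @export
#' @method print prediction_table
print.prediction_table <- function(x, ...) {
  cat(sprintf("<prediction_table> %d crops -> %d images -> %d cultures\n",
              nrow(x$crops), nrow(x$images), nrow(x$cultures)))
  invisible(x)
}

# Preprocess the fields relevant to a combination into one crop dataset.
# Returns crops plus the lineage/metadata table used for folds and AUC.
build_crop_dataset <- function(fields, combo, pp_config) {
  crops_list <- list(); meta <- list()
  for (i in seq_along(fields)) {
    fs <- fields[[i]]
    if (!all(combo$members %in% names(fs$channels))) next
    pp <- preprocess_field(fs, combo, pp_config)
    md <- fs$metadata
    culture <- paste(md$spec$experiment_id, md$well, sep = "_")
    image <- paste(culture, md$field, sep = "_f")
    crops_list[[length(crops_list) + 1]] <- pp$crops
    meta[[length(meta) + 1]] <- data.frame(
      image = image, culture = culture,
      cell_line = md$spec$cell_line_id,
      experiment = md$spec$experiment_id,
      condition = md$spec$condition,
      crop_in_image = seq_len(pp$n_tiles),
      stringsAsFactors = FALSE)
  }
  if (length(crops_list) == 0) return(NULL)
  meta <- do.call(rbind, meta)
  meta$crop <- paste(meta$image, meta$crop_in_image, sep = "_c")
  s <- dim(crops_list[[1]])[1]
  crops <- array(0, dim = c(s, s, 3, nrow(meta)))
  at <- 0
  for (cl in crops_list) {
    n <- dim(cl)[4]
    crops[, , , at + seq_len(n)] <- cl
    at <- at + n
  }
  list(crops = crops, meta = meta)
}

# Augment training crops sixfold, preserving labels.
augment_crops <- function(crops, labels) {
  d <- dim(crops)
  out <- array(0, dim = c(d[1], d[2], d[3], d[4] * 6))
  for (i in seq_len(d[4])) {
    aug <- augment(crops[, , , i])
    for (j in 1:6) out[, , , (i - 1) * 6 + j] <- aug[[j]]
  }
  list(crops = out, labels = rep(labels, each = 6))
}

#' Run the cross-validated classifier grid
#'
#' For every (test, channel combination) cell, repeats stratified k-fold
#' cross-validation in `n_subsets` differently shuffled subsets: the
#' classifier is trained on the augmented training folds and evaluated —
#' never augmented — on the held-out fold, yielding `n_subsets * k` AUC
#' values per cell (50 with the defaults).
#'
#' @param fields List of `field_stack` objects (e.g. from
#'   [generate_plate()]).
#' @param tests Named list; each element has `positive` and `negative`
#'   character vectors of condition labels (positive = disease/stress).
#' @param combinations List of [channel_combination()]s.
#' @param n_subsets Number of repeated CV runs with different shuffles.
#' @param k Folds per run.
#' @param config [classifier_config()].
#' @param pp_config [preprocess_config()].
#' @param split_level `"image"` (default) keeps all 16 crops of a field
#'   image in the same fold, preventing sibling-crop leakage; `"crop"`
#'   shuffles crops independently.
#' @param verbose Print progress.
#' @return data.frame of class `fold_auc_table` with columns `test`,
#'   `combination`, `subset`, `fold`, `auc`.
#' @export
run_cv_grid <- function(fields, tests, combinations, n_subsets = 5, k = 10,
                        config = classifier_config(),
                        pp_config = preprocess_config(),
                        split_level = c("image", "crop"),
                        verbose = FALSE) {
  split_level <- match.arg(split_level)
  rows <- list()
  for (tn in names(tests)) {
    tspec <- tests[[tn]]
    for (combo in combinations) {
      sel <- Filter(function(fs) {
        fs$metadata$spec$condition %in% c(tspec$positive, tspec$negative)
      }, fields)
      ds <- build_crop_dataset(sel, combo, pp_config)
      if (is.null(ds)) {
        warnf("skipping %s | %s: required markers absent", tn, combo$label)
        next
      }
      ds$meta$y <- as.integer(ds$meta$condition %in% tspec$positive)
      unit <- if (split_level == "image") "image" else "crop"
      units <- unique(ds$meta[, c(unit, "y")])
      for (s in seq_len(n_subsets)) {
        fold_of_unit <- make_stratified_folds(
          units$y, k = k, seed = derive_seed(config$seed, tn, combo$label, s))
        fold <- fold_of_unit[match(ds$meta[[unit]], units[[unit]])]
        for (f in seq_len(k)) {
          tr <- fold != f
          aug <- augment_crops(ds$crops[, , , tr, drop = FALSE], ds$meta$y[tr])
          cfg <- config
          cfg$seed <- derive_seed(config$seed, "train", tn, combo$label, s, f)
          model <- train_classifier(aug$crops, aug$labels, cfg)
          te <- which(!tr)
          p <- predict(model, ds$crops[, , , te, drop = FALSE])
          # fold AUC at the split-unit level (crop means per image)
          df <- data.frame(u = ds$meta[[unit]][te], y = ds$meta$y[te], p = p)
          up <- aggregate(p ~ u + y, data = df, FUN = mean)
          auc <- roc_auc(up$p[up$y == 1], up$p[up$y == 0])
          rows[[length(rows) + 1]] <- data.frame(
            test = tn, combination = combo$label, subset = s, fold = f,
            auc = auc, stringsAsFactors = FALSE)
          if (verbose)
            message(sprintf("%s | %-15s subset %d fold %2d: AUC %.3f",
                            tn, combo$label, s, f, auc))
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(out)) class(out) <- c("fold_auc_table", "data.frame")
  out
}

#' Apply a trained classifier to a set of fields
#'
#' Preprocesses every field whose markers cover the model's channel
#' combination, scores all crops and aggregates to per-image and per-culture
#' probabilities — the cross-condition transfer operation.
#'
#' @param model A `scratch_cnn` (its `combo`/`pp_config` attributes are used
#'   when `combo` is `NULL`).
#' @param fields List of `field_stack` objects.
#' @param combo The [channel_combination()] the model was trained on.
#' @param pp_config [preprocess_config()] matching training.
#' @return A `prediction_table` (see [aggregate_predictions()]) whose
#'   culture table carries cell line, experiment and condition metadata.
#' @export
apply_classifier <- function(model, fields, combo = NULL,
                             pp_config = preprocess_config()) {
  combo <- combo %||% model$combo
  if (is.null(combo)) stopf("no channel combination attached to the model")
  have <- vapply(fields, function(fs)
    all(combo$members %in% names(fs$channels)), logical(1))
  if (!any(have))
    stopf("no field carries the markers of combination %s", combo$label)
  ds <- build_crop_dataset(fields[have], combo, pp_config)
  p <- predict(model, ds$crops)
  aggregate_predictions(data.frame(
    crop = ds$meta$crop, image = ds$meta$image, culture = ds$meta$culture,
    cell_line = ds$meta$cell_line, experiment = ds$meta$experiment,
    condition = ds$meta$condition, prob = p, stringsAsFactors = FALSE))
}
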