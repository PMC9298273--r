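# Manifest handling, result writing, and the end-to-end experiment driver.

MANIFEST_COLS <- c("experiment", "plate", "well", "cell_line", "condition",
                   "marker", "field", "z", "path")

#' Read and validate an acquisition manifest
#'
#' A manifest has one row per stored image plane with the nine columns
#' experiment, plate, well, cell_line, condition, marker, field, z, path.
#' A culture is identified by (experiment, plate, well). Validation checks:
#' all columns present; referenced files exist (unless `check_paths =
#' FALSE`); each well carries at most one non-generic (RBP) marker; z
#' indices are contiguous from 0 within each (well, field, marker).
#'
#' @param path CSV file path.
#' @param check_paths Verify that the `path` column points at existing
#'   files.
#' @return Validated data.frame with an added `culture` key column.
#' @export
read_manifest <- function(path, check_paths = TRUE) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(MANIFEST_COLS, names(m))
  if (length(miss) > 0)
    stopf("manifest is missing column '%s'", miss[1])
  if (check_paths && nrow(m) > 0) {
    bad <- which(!is.na(m$path) & !file.exists(m$path))
    if (length(bad) > 0)
      stopf("manifest row %d: file does not exist: %s", bad[1], m$path[bad[1]])
  }
  wells <- split(m$marker, paste(m$plate, m$well))
  for (w in names(wells)) {
    rbp <- setdiff(unique(wells[[w]]), c("DAPI", "BIII"))
    if (length(rbp) > 1)
      stopf("well %s carries %d RBP markers (%s); expected at most one",
            w, length(rbp), paste(rbp, collapse = ", "))
  }
  zgrp <- split(m$z, paste(m$well, m$field, m$marker))
  for (g in names(zgrp)) {
    zs <- sort(unique(zgrp[[g]]))
    if (!identical(zs, seq(0L, max(zs))))
      stopf("z planes not contiguous from 0 for %s", g)
  }
  m$culture <- paste(m$experiment, m$plate, m$well, sep = "_")
  m
}

#' Write a manifest CSV
#'
#' @param manifest data.frame with the nine manifest columns.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  miss <- setdiff(MANIFEST_COLS, names(manifest))
  if (length(miss) > 0) stopf("manifest is missing column '%s'", miss[1])
  write.csv(manifest[, MANIFEST_COLS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

RESULT_SCHEMAS <- list(
  fold_aucs = c("test", "combination", "subset", "fold", "auc"),
  effects = c("condition", "classifier", "beta", "se", "chi2", "p"),
  auc_comparisons = c("test", "pairing", "U", "p", "neg_log10_p")
)

result_schema_for <- function(name) {
  if (startsWith(name, "predictions_"))
    return(c("culture", "cell_line", "experiment", "condition", "marker",
             "n_images", "probability"))
  RESULT_SCHEMAS[[name]]
}

#' Write result tables with fixed schemas
#'
#' Writes each named table as CSV (UTF-8, '.' decimal separator, fixed
#' column order); an element named `linkage` is written as JSON instead.
#' Recognised table names: `fold_aucs`, `predictions_<test>`, `effects`,
#' `auc_comparisons`.
#'
#' @param tables Named list of data.frames (plus optional `linkage` list).
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_results <- function(tables, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    if (nm == "linkage") {
      p <- file.path(out_dir, "linkage.json")
      jsonlite::write_json(tables[[nm]], p, auto_unbox = TRUE, digits = NA)
      paths[nm] <- p
      next
    }
    schema <- result_schema_for(nm)
    if (is.null(schema)) stopf("unknown result table '%s'", nm)
    tb <- as.data.frame(tables[[nm]])
    miss <- setdiff(schema, names(tb))
    if (length(miss) > 0)
      stopf("table '%s' does not match its schema: column '%s' missing",
            nm, miss[1])
    p <- file.path(out_dir, paste0(nm, ".csv"))
    write.csv(tb[, schema, drop = FALSE], p, row.names = FALSE, quote = FALSE)
    paths[nm] <- p
  }
  invisible(paths)
}

default_tests_for <- function(conditions) {
  tests <- list()
  if ("mutant" %in% conditions)
    tests$isALS <- list(positive = "mutant", negative = "control")
  for (cond in intersect(c("oxidative", "heat", "osmotic"), conditions))
    tests[[paste0("is", toupper(cond))]] <-
      list(positive = cond, negative = "control")
  tests
}

run_stage <- function(name, out_dir, expr) {
  tryCatch(expr, error = function(e) {
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      writeLines(sprintf("stage %s failed: %s", name, conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
    }
    stopf("stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run a full simulate -> classify -> attribute -> analyse experiment
#'
#' Drives the whole pipeline from one config: synthetic plate generation,
#' the cross-validated classifier grid, Mann-Whitney AUC comparisons,
#' full-data model fits with cross-condition prediction transfer,
#' mixed-model effect sizes with Ward clustering, and an
#' integrated-gradients overlay gallery. All outputs are CSV/JSON/PNG under
#' `config$out_dir`; a run-metadata JSON records every seed and flag. Any
#' stage failure aborts with the stage name and leaves a `FAILED` marker.
#'
#' @param config Named list (or path to a JSON file): `seed`, `out_dir`,
#'   `layout` (see [generate_plate()]), `size`, `fields_per_well`, `n_z`,
#'   `tests` (default derived from the layout conditions), `combinations`
#'   (default [enumerate_channel_combinations()] over the layout's RBP),
#'   `cv = list(n_subsets, k)`, `classifier` ([classifier_config()]
#'   arguments), `preprocess` ([preprocess_config()] arguments),
#'   `split_level`, `attribution = list(n_images, steps)`.
#' @return List with the result tables, trained models and output paths.
#' @export
run_experiment <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  seed <- config$seed %||% 1
  out_dir <- config$out_dir %||% NULL
  layout <- config$layout %||% stopf("config$layout is required")
  pp <- do.call(preprocess_config, config$preprocess %||% list())
  clf <- do.call(classifier_config,
                 modifyList(config$classifier %||% list(), list(seed = seed)))
  cv <- config$cv %||% list(n_subsets = 5, k = 10)
  rbp <- layout$rbp_marker %||% "FUS"
  combos <- config$combinations %||% enumerate_channel_combinations(rbp)
  tests <- config$tests %||% default_tests_for(layout$conditions)
  if (length(tests) == 0) stopf("no tests derivable from the layout conditions")

  plate <- run_stage("simulate", out_dir, generate_plate(
    layout, seed = seed, size = config$size %||% 540,
    fields_per_well = config$fields_per_well, n_z = config$n_z,
    out_dir = if (!is.null(out_dir)) file.path(out_dir, "images")))

  fold_aucs <- run_stage("cv_grid", out_dir, run_cv_grid(
    plate$fields, tests, combos, n_subsets = cv$n_subsets %||% 5,
    k = cv$k %||% 10, config = clf, pp_config = pp,
    split_level = config$split_level %||% "image"))

  comparisons <- run_stage("auc_comparisons", out_dir, {
    rows <- list()
    for (tn in unique(fold_aucs$test)) {
      sub <- fold_aucs[fold_aucs$test == tn, ]
      labs <- unique(sub$combination)
      if (length(labs) >= 2) {
        prs <- combn(labs, 2)
        for (j in seq_len(ncol(prs))) {
          a <- sub$auc[sub$combination == prs[1, j]]
          b <- sub$auc[sub$combination == prs[2, j]]
          mw <- mann_whitney_one_sided(a, b, "b_greater")
          rows[[length(rows) + 1]] <- data.frame(
            test = tn, pairing = paste(prs[2, j], ">", prs[1, j]),
            U = mw$U, p = mw$p, neg_log10_p = -log10(mw$p),
            stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows) %||% data.frame(test = character(0),
      pairing = character(0), U = numeric(0), p = numeric(0),
      neg_log10_p = numeric(0))
  })

  # full-data models per (test, combination); transfer to every culture
  models <- list(); predictions <- list()
  run_stage("transfer", out_dir, {
    for (tn in names(tests)) {
      tabs <- list()
      for (combo in combos) {
        tsp <- tests[[tn]]
        sel <- Filter(function(fs)
          fs$metadata$spec$condition %in% c(tsp$positive, tsp$negative) &&
            all(combo$members %in% names(fs$channels)), plate$fields)
        if (length(sel) == 0) next
        ds <- build_crop_dataset(sel, combo, pp)
        aug <- augment_crops(ds$crops, as.integer(ds$meta$condition %in% tsp$positive))
        cfg <- clf
        cfg$seed <- derive_seed(seed, "final", tn, combo$label)
        model <- train_classifier(aug$crops, aug$labels, cfg)
        model$combo <- combo
        models[[paste(tn, combo$label, sep = "|")]] <- model
        pt <- apply_classifier(model, plate$fields, combo, pp)
        cu <- pt$cultures
        tabs[[combo$label]] <- data.frame(
          culture = cu$culture, cell_line = cu$cell_line,
          experiment = cu$experiment, condition = cu$condition,
          marker = combo$label, n_images = cu$n_images,
          probability = cu$prob, stringsAsFactors = FALSE)
      }
      predictions[[paste0("predictions_", tn)]] <- do.call(rbind, tabs)
    }
  })

  effects <- run_stage("effects", out_dir, {
    rows <- list()
    for (tn in names(tests)) {
      ptab <- predictions[[paste0("predictions_", tn)]]
      if (is.null(ptab)) next
      base <- ptab[ptab$condition == "control", ]
      for (cond in setdiff(unique(ptab$condition), "control")) {
        for (mk in unique(ptab$marker)) {
          d <- rbind(base[base$marker == mk, ],
                     ptab[ptab$condition == cond & ptab$marker == mk, ])
          if (length(unique(d$condition)) < 2) next
          d$prediction <- d$probability
          d$condition <- as.integer(d$condition != "control")
          est <- suppressWarnings(fit_random_intercept_lmm(d))
          rows[[length(rows) + 1]] <- data.frame(
            condition = cond, classifier = paste(tn, mk, sep = "|"),
            beta = est$beta_hat, se = est$se, chi2 = est$chi2, p = est$p,
            stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows) %||% data.frame(condition = character(0),
      classifier = character(0), beta = numeric(0), se = numeric(0),
      chi2 = numeric(0), p = numeric(0))
  })

  linkage <- run_stage("clustering", out_dir, {
    if (nrow(effects) > 0) {
      prof <- stats::reshape(effects[, c("condition", "classifier", "beta")],
                             idvar = "condition", timevar = "classifier",
                             direction = "wide")
      mat <- as.matrix(prof[, -1, drop = FALSE])
      rownames(mat) <- prof$condition
      if (nrow(mat) >= 2 && !anyNA(mat)) {
        cl <- ward_cluster(mat)
        list(labels = cl$labels, merge = cl$merge, height = cl$height,
             order = cl$order)
      } else NULL
    } else NULL
  })

  gallery <- run_stage("attribution", out_dir, {
    att <- config$attribution %||% list(n_images = 2, steps = 50)
    paths <- character(0)
    if (!is.null(out_dir) && length(models) > 0) {
      m1 <- models[[1]]
      sel <- Filter(function(fs)
        all(m1$combo$members %in% names(fs$channels)), plate$fields)
      ds <- build_crop_dataset(sel, m1$combo, pp)
      p <- predict(m1, ds$crops)
      top <- order(p, decreasing = TRUE)[seq_len(min(att$n_images %||% 2, length(p)))]
      dir.create(file.path(out_dir, "attribution"), showWarnings = FALSE,
                 recursive = TRUE)
      for (i in top) {
        ig <- integrated_gradients(m1, ds$crops[, , , i],
                                   steps = att$steps %||% 50)
        orig <- array(as.integer(pmin(pmax(
          round((ds$crops[, , , i] * rep(pp$constants$std, each = prod(dim(ds$crops)[1:2])) +
                   rep(pp$constants$mean, each = prod(dim(ds$crops)[1:2]))) * 255),
          0), 255)), dim = dim(ds$crops)[1:3])
        fp <- file.path(out_dir, "attribution",
                        sprintf("%s_crop%03d.png", gsub("[|:]", "_", names(models)[1]), i))
        attribution_overlay(ig, orig, path = fp)
        paths <- c(paths, fp)
      }
    }
    paths
  })

  tables <- c(list(fold_aucs = fold_aucs, effects = effects,
                   auc_comparisons = comparisons), predictions)
  if (!is.null(linkage)) tables$linkage <- linkage
  paths <- NULL
  if (!is.null(out_dir)) {
    paths <- run_stage("write_results", out_dir, write_results(tables, out_dir))
    meta <- list(seed = seed,
                 package_version = as.character(utils::packageVersion("neuroscreen")),
                 tests = names(tests),
                 combinations = vapply(combos, function(cb) cb$label, character(1)),
                 cv = cv, split_level = config$split_level %||% "image",
                 classifier = unclass(clf)[c("backbone", "learning_rate",
                                             "batch_size", "epochs")],
                 preprocess = list(tile_size = pp$tile_size,
                                   resize_to = pp$resize_to,
                                   cutoff_percent = pp$cutoff_percent),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(fold_aucs = fold_aucs, predictions = predictions, effects = effects,
       auc_comparisons = comparisons, linkage = linkage, models = models,
       manifest = plate$manifest, gallery = gallery, paths = paths)
}
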