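#' Generate a synthetic plate of fields
#'
#' Expands a layout (experiments x cell lines x conditions x wells) into
#' rendered [render_field()] stacks with the acquisition structure the
#' analysis assumes: 10-12 non-overlapping fields per well and 3-5 z-planes
#' per field. One manifest row is emitted per stored plane per marker, so a
#' field contributes `n_z * 3` rows.
#'
#' @param layout A list with elements `experiments` (character vector or a
#'   count), `cell_lines` (character vector), `conditions` (character
#'   vector), `wells_per_condition` (integer) and optionally `rbp_marker`
#'   (default "FUS").
#' @param seed Master seed; the whole plate is a pure function of
#'   (layout, phenotype_config, seed).
#' @param phenotype_config List with `base` ([phenotype_params()]) and
#'   `effects` ([condition_effects()]).
#' @param size Field size in pixels (>= 256).
#' @param fields_per_well If `NULL`, sampled uniformly in 10-12 per well.
#' @param n_z If `NULL`, sampled uniformly in 3-5 per field.
#' @param out_dir If non-`NULL`, one 16-bit grayscale TIFF is written per
#'   plane, named `{experiment}_{well}_{marker}_{field}_z{k}.tif`, and the
#'   manifest `path` column points at the files; otherwise paths are `NA`
#'   and pixel data stay in memory.
#' @param plate Plate label.
#'
#' @return List with `fields` (list of `field_stack`), `manifest`
#'   (data.frame: experiment, plate, well, cell_line, condition, marker,
#'   field, z, path) and `truths` (list of `ground_truth`, parallel to
#'   `fields`).
#' @export
generate_plate <- function(layout, seed,
                           phenotype_config = list(base = phenotype_params(),
                                                   effects = condition_effects()),
                           size = 540, fields_per_well = NULL, n_z = NULL,
                           out_dir = NULL, plate = "P1") {
  experiments <- layout$experiments %||% 1
  if (is.numeric(experiments)) experiments <- paste0("EXP", seq_len(experiments))
  cell_lines <- layout$cell_lines %||% stopf("layout$cell_lines is required")
  conditions <- layout$conditions %||% stopf("layout$conditions is required")
  wells_per <- layout$wells_per_condition %||% 1
  rbp_marker <- layout$rbp_marker %||% "FUS"
  if (wells_per < 1 || length(cell_lines) < 1 || length(conditions) < 1)
    stopf("all layout counts must be >= 1")
  known <- phenotype_config$effects$condition
  bad <- setdiff(conditions, known)
  if (length(bad) > 0)
    stopf("unknown condition label '%s'", bad[1])
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  fields <- list(); truths <- list(); rows <- list()
  well_i <- 0
  for (ex in experiments) for (cl in cell_lines) for (cond in conditions) {
    for (w in seq_len(wells_per)) {
      well_i <- well_i + 1
      well <- sprintf("W%03d", well_i)
      nf <- fields_per_well %||%
        with_seed(derive_seed(seed, "nf", ex, well), sample(10:12, 1))
      spec <- culture_spec(cond, cl, ex,
                           seed = derive_seed(seed, "culture", ex, cl, cond, w),
                           base = phenotype_config$base,
                           effects = phenotype_config$effects)
      for (f in seq_len(nf)) {
        nz <- n_z %||%
          with_seed(derive_seed(seed, "nz", ex, well, f), sample(3:5, 1))
        fs <- render_field(spec, size = size, n_z = nz,
                           rbp_marker = rbp_marker, well = well, field = f)
        fields[[length(fields) + 1]] <- fs
        truths[[length(truths) + 1]] <- fs$truth
        for (mk in names(fs$channels)) for (k in seq_len(fs$n_z)) {
          path <- NA_character_
          if (!is.null(out_dir)) {
            path <- file.path(out_dir,
                              sprintf("%s_%s_%s_%d_z%d.tif", ex, well, mk, f, k - 1))
            tiff::writeTIFF(fs$channels[[mk]][, , k] / 65535, path,
                            bits.per.sample = 16L, compression = "none")
          }
          rows[[length(rows) + 1]] <- data.frame(
            experiment = ex, plate = plate, well = well, cell_line = cl,
            condition = cond, marker = mk, field = f, z = k - 1L,
            path = path, stringsAsFactors = FALSE)
        }
      }
    }
  }
  manifest <- do.call(rbind, rows)
  list(fields = fields, manifest = manifest, truths = truths)
}

#' Simulate a per-culture prediction table
#'
#' Draws classifier predictions from the random-intercept model the
#' inference layer fits: `y_ij = beta0 + beta1 * condition + u_line +
#' u_experiment + eps`, with Gaussian random intercepts and residuals.
#' Useful as a fixture with known ground truth for effect-recovery and
#' calibration tests.
#'
#' @param beta0 Intercept (baseline prediction of the reference group).
#' @param beta1 Fixed effect of the condition indicator.
#' @param sd_line,sd_exp,sd_resid Standard deviations of the cell-line
#'   intercepts, experiment intercepts and residuals (all >= 0).
#' @param layout List with `n_lines`, `n_experiments`, `cultures_per_cell`
#'   (cultures per line x experiment combination; conditions alternate
#'   0/1 within each cell so the design is balanced).
#' @param seed Integer seed.
#' @param clip If `TRUE`, predictions are clipped to \[0, 1\] (off by
#'   default so that moment checks see the untruncated model).
#'
#' @return data.frame with columns culture, cell_line, experiment,
#'   condition, prediction.
#' @export
#' @examples
#' head(simulate_prediction_table(0.3, 0.4, 0.05, 0.05, 0.1,
#'   layout = list(n_lines = 7, n_experiments = 3, cultures_per_cell = 10),
#'   seed = 1))
simulate_prediction_table <- function(beta0, beta1, sd_line, sd_exp, sd_resid,
                                      layout = list(n_lines = 7,
                                                    n_experiments = 3,
                                                    cultures_per_cell = 10),
                                      seed = 1, clip = FALSE) {
  if (sd_line < 0 || sd_exp < 0 || sd_resid < 0)
    stopf("random-effect and residual standard deviations must be >= 0")
  nl <- layout$n_lines; ne <- layout$n_experiments; nc <- layout$cultures_per_cell
  with_seed(seed, {
    u_line <- rnorm(nl, 0, sd_line)
    u_exp <- rnorm(ne, 0, sd_exp)
    rows <- expand.grid(culture_i = seq_len(nc), experiment = seq_len(ne),
                        line = seq_len(nl))
    cond <- (rows$culture_i - 1) %% 2L
    y <- beta0 + beta1 * cond + u_line[rows$line] + u_exp[rows$experiment] +
      rnorm(nrow(rows), 0, sd_resid)
    if (clip) y <- pmin(pmax(y, 0), 1)
    data.frame(
      culture = sprintf("L%02d_E%02d_C%03d", rows$line, rows$experiment,
                        rows$culture_i),
      cell_line = sprintf("LINE%02d", rows$line),
      experiment = sprintf("EXP%02d", rows$experiment),
      condition = cond,
      prediction = y,
      stringsAsFactors = FALSE)
  })
}
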