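#' Phenotype parameters for the synthetic microscopy generator
#'
#' Bundles the morphological and photometric knobs that the renderer turns
#' into images: nuclear size and boundary roughness, neurite geometry and
#' fragmentation, the nuclear-to-cytoplasmic ratio of the RNA-binding-protein
#' (RBP) channel, and the read-noise level.
#'
#' @param nuclear_radius_px Mean nucleus radius in pixels.
#' @param nuclear_irregularity Standard deviation of the radial boundary
#'   perturbation, as a fraction of the radius (>= 0). 0 gives smooth
#'   ellipses; the perturbation is carried by low-order Fourier modes.
#' @param neurite_width_px Gaussian tube sigma of rendered neurites (pixels).
#' @param neurite_fragmentation Probability in \[0, 1\] that any given neurite
#'   segment is deleted, thinning the network.
#' @param neurite_density Expected number of neurite trees per field.
#' @param rbp_nc_ratio Nuclear-to-cytoplasmic mean-intensity ratio of the RBP
#'   channel (> 0); ALS-relevant RBPs are predominantly nuclear, so the
#'   default is well above 1.
#' @param noise_sd Additive Gaussian read noise sigma in 16-bit counts.
#'   Setting it to 0 disables all rendering noise (shot noise included),
#'   which is useful for geometric ground-truth checks.
#'
#' @return An object of class `phenotype_params` (a validated named list).
#' @export
#' @examples
#' phenotype_params(nuclear_irregularity = 0.2)
phenotype_params <- function(nuclear_radius_px = 25,
                             nuclear_irregularity = 0.05,
                             neurite_width_px = 2,
                             neurite_fragmentation = 0.05,
                             neurite_density = 6,
                             rbp_nc_ratio = 3,
                             noise_sd = 100) {
  p <- list(
    nuclear_radius_px = nuclear_radius_px,
    nuclear_irregularity = nuclear_irregularity,
    neurite_width_px = neurite_width_px,
    neurite_fragmentation = neurite_fragmentation,
    neurite_density = neurite_density,
    rbp_nc_ratio = rbp_nc_ratio,
    noise_sd = noise_sd
  )
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || is.na(p[[nm]]))
      stopf("phenotype parameter '%s' must be a single number", nm)
    if (p[[nm]] < 0) stopf("phenotype parameter '%s' must be nonnegative", nm)
  }
  if (rbp_nc_ratio <= 0) stopf("'rbp_nc_ratio' must be > 0")
  if (neurite_fragmentation > 1)
    stopf("'neurite_fragmentation' must lie in [0, 1]")
  structure(p, class = "phenotype_params")
}

#' Condition effect table
#'
#' One table is the single source of truth for how each culture condition
#' shifts the phenotype parameters, so that recovery tests can compare what
#' was injected with what the classifiers detect. Shifts are additive on the
#' corresponding [phenotype_params()] fields. The defaults encode the
#' generator's phenotype design: the mutant condition perturbs nuclear
#' outlines and fragments neurites; heat stress shifts the same parameters in
#' the same direction at reduced magnitude; oxidative and osmotic stress move
#' orthogonal parameters (RBP relocalisation towards the cytoplasm, nuclear
#' shrinkage).
#'
#' @return A data.frame with a `condition` column plus one column per
#'   phenotype parameter holding the additive shift.
#' @export
condition_effects <- function() {
  eff <- data.frame(
    condition = c("control", "mutant", "oxidative", "heat", "osmotic"),
    nuclear_radius_px = c(0, 0, 0, 0, -6),
    nuclear_irregularity = c(0, 0.30, 0, 0.24, 0),
    neurite_width_px = 0,
    neurite_fragmentation = c(0, 0.30, 0, 0.24, 0),
    neurite_density = 0,
    rbp_nc_ratio = c(0, 0, -1.0, 0, -1.5),
    noise_sd = 0,
    stringsAsFactors = FALSE
  )
  eff
}

# Clamp shifted parameters back into their legal ranges.
clamp_params <- function(p) {
  p$nuclear_radius_px <- max(p$nuclear_radius_px, 5)
  p$nuclear_irregularity <- max(p$nuclear_irregularity, 0)
  p$neurite_width_px <- max(p$neurite_width_px, 0.5)
  p$neurite_fragmentation <- min(max(p$neurite_fragmentation, 0), 1)
  p$neurite_density <- max(p$neurite_density, 0)
  p$rbp_nc_ratio <- max(p$rbp_nc_ratio, 0.2)
  p$noise_sd <- max(p$noise_sd, 0)
  p
}

apply_condition_effect <- function(params, condition, effects, recovery_h = 0) {
  row <- effects[effects$condition == condition, , drop = FALSE]
  if (nrow(row) != 1)
    stopf("unknown condition label '%s'", condition)
  # Stress shifts decay exponentially during recovery (2 h half-life-ish
  # time constant); the mutant genotype does not recover.
  fac <- if (condition %in% c("control", "mutant")) 1 else exp(-recovery_h / 2)
  for (nm in names(params))
    params[[nm]] <- params[[nm]] + fac * row[[nm]]
  clamp_params(params)
}

#' Specify one synthetic culture
#'
#' Combines a base phenotype with the deterministic condition shift from
#' [condition_effects()] and with cell-line and experiment random intercepts
#' on the phenotype parameters. Random effects are drawn from sub-seeds
#' derived from the identifiers, so the same line re-used across wells or
#' experiments always carries the same idiosyncratic offset.
#'
#' @param condition Condition label present in `effects$condition`.
#' @param cell_line_id Cell line identifier (e.g. "CTRL1", "MUT2").
#' @param experiment_id Experiment (differentiation repeat) identifier.
#' @param seed Integer seed; the spec plus seed determine the output exactly.
#' @param base Base [phenotype_params()].
#' @param effects Condition effect table, see [condition_effects()].
#' @param recovery_h Hours of recovery since the stress ended (0 = imaged
#'   at the end of the stress hour).
#' @param line_sd,experiment_sd Named numeric vectors of random-intercept
#'   standard deviations per phenotype parameter.
#'
#' @return An object of class `culture_spec`.
#' @export
culture_spec <- function(condition, cell_line_id, experiment_id, seed,
                         base = phenotype_params(),
                         effects = condition_effects(),
                         recovery_h = 0,
                         line_sd = c(nuclear_radius_px = 1.0,
                                     nuclear_irregularity = 0.01,
                                     neurite_width_px = 0.05,
                                     neurite_fragmentation = 0.01,
                                     neurite_density = 0.3,
                                     rbp_nc_ratio = 0.10,
                                     noise_sd = 0),
                         experiment_sd = c(nuclear_radius_px = 0.5,
                                           nuclear_irregularity = 0.005,
                                           neurite_width_px = 0.02,
                                           neurite_fragmentation = 0.005,
                                           neurite_density = 0.15,
                                           rbp_nc_ratio = 0.05,
                                           noise_sd = 0)) {
  stopifnot(is.character(condition), length(condition) == 1)
  params <- apply_condition_effect(base, condition, effects, recovery_h)
  draw_offsets <- function(sds, tag) {
    with_seed(derive_seed(seed, tag), {
      vapply(names(sds), function(nm) rnorm(1, 0, sds[[nm]]), numeric(1))
    })
  }
  u_line <- draw_offsets(line_sd, paste0("line:", cell_line_id))
  u_exp <- draw_offsets(experiment_sd, paste0("exp:", experiment_id))
  for (nm in names(params))
    params[[nm]] <- params[[nm]] + (u_line[nm] %||% 0) + (u_exp[nm] %||% 0)
  params <- clamp_params(params)
  class(params) <- "phenotype_params"
  structure(list(
    condition = condition,
    cell_line_id = cell_line_id,
    experiment_id = experiment_id,
    recovery_h = recovery_h,
    phenotype = params,
    seed = as.integer(seed)
  ), class = "culture_spec")
}

#' @export
#' @method print culture_spec
print.culture_spec <- function(x, ...) {
  cat(sprintf("<culture_spec> %s | line %s | experiment %s | seed %d\n",
              x$condition, x$cell_line_id, x$experiment_id, x$seed))
  invisible(x)
}

#' @export
#' @method print phenotype_params
print.phenotype_params <- function(x, ...) {
  cat("<phenotype_params>\n")
  for (nm in names(x)) cat(sprintf("  %-22s %.4g\n", nm, x[[nm]]))
  invisible(x)
}
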