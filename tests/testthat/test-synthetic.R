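# Synthetic microscopy generator: determinism, layout bookkeeping,
# phenotype-parameter fidelity of the rendered channels.

quiet_params <- phenotype_params(noise_sd = 0)

test_that("phenotype parameter validation rejects illegal values", {
  expect_error(phenotype_params(rbp_nc_ratio = 0), "rbp_nc_ratio")
  expect_error(phenotype_params(neurite_fragmentation = 1.5), "0, 1")
  expect_error(phenotype_params(nuclear_radius_px = -1), "nonnegative")
  expect_error(culture_spec("frozen", "L", "E", 1), "frozen")
})

test_that("condition effects shift parameters as declared, with clamping", {
  eff <- condition_effects()
  base <- phenotype_params()
  mut <- neuroscreen:::apply_condition_effect(base, "mutant", eff)
  expect_equal(mut$nuclear_irregularity,
               base$nuclear_irregularity +
                 eff$nuclear_irregularity[eff$condition == "mutant"])
  expect_equal(mut$rbp_nc_ratio, base$rbp_nc_ratio)
  osm <- neuroscreen:::apply_condition_effect(base, "osmotic", eff)
  expect_equal(osm$nuclear_radius_px, base$nuclear_radius_px - 6)
  # recovery decays stress shifts but not the genotype
  osm2 <- neuroscreen:::apply_condition_effect(base, "osmotic", eff,
                                               recovery_h = 6)
  expect_lt(abs(osm2$nuclear_radius_px - base$nuclear_radius_px),
            abs(osm$nuclear_radius_px - base$nuclear_radius_px))
  mut2 <- neuroscreen:::apply_condition_effect(base, "mutant", eff,
                                               recovery_h = 6)
  expect_equal(mut2$nuclear_irregularity, mut$nuclear_irregularity)
})

test_that("render_field is a pure function of spec and seed", {
  spec <- fixed_spec(seed = 11)
  a <- render_field(spec, size = 256, n_z = 3)
  b <- render_field(spec, size = 256, n_z = 3)
  expect_identical(a$channels, b$channels)
  expect_identical(a$truth$nucleus_mask, b$truth$nucleus_mask)
  c <- render_field(fixed_spec(seed = 12), size = 256, n_z = 3)
  expect_false(identical(a$channels$DAPI, c$channels$DAPI))
})

test_that("rendered stacks respect the acquisition contract", {
  fs <- render_field(fixed_spec(seed = 2), size = 256)
  expect_true(fs$n_z >= 3 && fs$n_z <= 5)
  expect_setequal(names(fs$channels), c("DAPI", "BIII", "FUS"))
  for (ch in fs$channels) {
    expect_equal(dim(ch), c(256, 256, fs$n_z))
    expect_true(all(ch >= 0 & ch <= 65535))
  }
  # DAPI is brighter inside the nucleus mask than outside
  mip <- max_intensity_projection(fs$channels$DAPI)
  expect_gt(mean(mip[fs$truth$nucleus_mask]), mean(mip[!fs$truth$nucleus_mask]))
  expect_error(render_field(fixed_spec(), size = 100), "at least 256")
  expect_error(render_field(fixed_spec(), size = 256, n_z = 7), "3, 5")
})

test_that("RBP nuclear-to-cytoplasmic ratio is rendered to spec", {
  for (ratio in c(2, 3, 4)) {
    base <- phenotype_params(noise_sd = 0, rbp_nc_ratio = ratio)
    fs <- render_field(fixed_spec(seed = 5, base = base), size = 300, n_z = 3)
    tr <- fs$truth
    rbp <- fs$channels$FUS[, , fs$focus]
    measured <- mean(rbp[tr$nucleus_mask]) / mean(rbp[tr$cytoplasm_mask])
    expect_lt(abs(measured - ratio) / ratio, 0.05)
  }
})

test_that("unperturbed nuclei are smooth; irregularity roughens the boundary", {
  # rasterize single nuclei directly, with eccentricity fixed at 0
  radial_sd <- function(irr) {
    m <- matrix(FALSE, 160, 160)
    m <- neuroscreen:::with_seed(42,
      neuroscreen:::draw_nucleus(m, 80, 80, 30, irr, ecc = 0, psi = 0))
    # boundary pixels: inside the mask but 4-adjacent to outside
    idx <- which(m, arr.ind = TRUE)
    on_edge <- apply(idx, 1, function(p) {
      any(!m[cbind(p[1] + c(-1, 1, 0, 0), p[2] + c(0, 0, -1, 1))])
    })
    b <- idx[on_edge, , drop = FALSE]
    sd(sqrt((b[, 1] - 80)^2 + (b[, 2] - 80)^2))
  }
  expect_lt(radial_sd(0), 1)
  sds <- vapply(c(0, 0.1, 0.3), radial_sd, numeric(1))
  expect_true(all(diff(sds) > 0))
})

test_that("neurite fragmentation strictly shortens the skeleton", {
  skel_len <- function(frag) {
    base <- phenotype_params(noise_sd = 0, neurite_fragmentation = frag,
                             neurite_density = 25)
    sum(render_field(fixed_spec(seed = 9, base = base),
                     size = 256, n_z = 3)$truth$neurite_skeleton)
  }
  l0 <- skel_len(0); l5 <- skel_len(0.5)
  expect_lt(l5, l0)
  expect_gt(l5, 0)
})

test_that("generate_plate obeys the layout product and manifest contract", {
  layout <- list(experiments = 1, cell_lines = c("CTRL1", "MUT1"),
                 conditions = c("control", "mutant"), wells_per_condition = 1)
  pc <- list(base = quiet_params, effects = condition_effects())
  plate <- generate_plate(layout, seed = 4, phenotype_config = pc,
                          size = 256, fields_per_well = 3, n_z = 3)
  # 1 exp x 2 lines x 2 conditions x 1 well x 3 fields
  expect_length(plate$fields, 12)
  # one manifest row per plane per marker
  expect_equal(nrow(plate$manifest), 12 * 3 * 3)
  expect_setequal(names(plate$manifest), neuroscreen:::MANIFEST_COLS)
  expect_error(generate_plate(list(cell_lines = "A", conditions = "sunny",
                                   wells_per_condition = 1),
                              seed = 1, phenotype_config = pc),
               "sunny")
})

test_that("generate_plate is deterministic and samples fields/z in range", {
  layout <- list(experiments = 1, cell_lines = "CTRL1",
                 conditions = "control", wells_per_condition = 3)
  pc <- list(base = quiet_params, effects = condition_effects())
  p1 <- generate_plate(layout, seed = 21, phenotype_config = pc, size = 256)
  p2 <- generate_plate(layout, seed = 21, phenotype_config = pc, size = 256)
  expect_identical(p1$manifest, p2$manifest)
  expect_identical(p1$fields[[1]]$channels, p2$fields[[1]]$channels)
  fields_per_well <- table(unique(p1$manifest[, c("well", "field")])$well)
  expect_true(all(fields_per_well >= 10 & fields_per_well <= 12))
  nz <- aggregate(z ~ well + field, data = p1$manifest, FUN = max)$z + 1
  expect_true(all(nz >= 3 & nz <= 5))
})

test_that("prediction-table simulator matches its generative model", {
  lay <- list(n_lines = 4, n_experiments = 2, cultures_per_cell = 6)
  # no variance anywhere: every prediction equals the group mean
  t0 <- simulate_prediction_table(0.3, 0, 0, 0, 0, layout = lay, seed = 1)
  expect_true(all(t0$prediction == 0.3))
  # determinism
  t1 <- simulate_prediction_table(0.2, 0.4, 0.05, 0.05, 0.1, layout = lay, seed = 7)
  t2 <- simulate_prediction_table(0.2, 0.4, 0.05, 0.05, 0.1, layout = lay, seed = 7)
  expect_identical(t1, t2)
  expect_error(simulate_prediction_table(0, 0, -0.1, 0, 0, layout = lay),
               ">= 0")
  # law of large numbers: condition contrast recovers beta1 at n = 10,000
  big <- simulate_prediction_table(0.2, 0.4, 0.05, 0.05, 0.1,
    layout = list(n_lines = 10, n_experiments = 10, cultures_per_cell = 100),
    seed = 3)
  diff <- mean(big$prediction[big$condition == 1]) -
    mean(big$prediction[big$condition == 0])
  expect_lt(abs(diff - 0.4), 0.02)
})

test_that("variance components are recovered from simulated predictions", {
  # pooled over replicate seeds so sampling error of the variance
  # estimates stays well inside the 20% band
  lay <- list(n_lines = 100, n_experiments = 50, cultures_per_cell = 2)
  vars <- sapply(1:3, function(s) {
    tb <- simulate_prediction_table(0.3, 0.2, 0.10, 0.08, 0.15,
                                    layout = lay, seed = s)
    fit <- fit_random_intercept_lmm(tb)
    fit$varcomp[c("cell_line", "experiment", "residual")]
  })
  est <- rowMeans(vars)
  truth <- c(0.10, 0.08, 0.15)^2
  expect_true(all(abs(est - truth) / truth < 0.2))
})
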