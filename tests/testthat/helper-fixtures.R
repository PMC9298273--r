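# Shared fixtures, all generated in code.

# Phenotype-parameter names, for zeroed random-effect vectors.
param_names <- names(phenotype_params())
zero_sd <- setNames(rep(0, length(param_names)), param_names)

# A culture spec with no cell-line/experiment random effects, so the
# rendered field reflects the base parameters exactly.
fixed_spec <- function(condition = "control", seed = 1,
                       base = phenotype_params(), effects = condition_effects()) {
  culture_spec(condition, "LINE1", "EXP1", seed = seed, base = base,
               effects = effects, line_sd = zero_sd, experiment_sd = zero_sd)
}

# Minimal hand-built field_stack: random 16-bit content whose intensity
# histogram is shaped by `gamma` (pixel = 20000 * u^gamma), a cue that
# survives per-channel autocontrast. Cheap stand-in for rendered fields
# when only bookkeeping or a simple learnable signal is needed.
fake_field <- function(condition, well, field, size = 128, n_z = 2,
                       gamma = 1, seed = 1, markers = c("DAPI", "BIII", "FUS"),
                       cell_line = "LINE1", experiment = "EXP1") {
  with_seed <- neuroscreen:::with_seed
  with_seed(neuroscreen:::derive_seed(seed, "fake", well, field), {
    channels <- lapply(setNames(markers, markers), function(mk) {
      u <- runif(size * size * n_z)
      arr <- array(as.integer(round(20000 * u^gamma)),
                   dim = c(size, size, n_z))
      arr
    })
    structure(list(
      channels = channels, n_z = n_z, focus = 1L,
      metadata = list(spec = list(condition = condition,
                                  cell_line_id = cell_line,
                                  experiment_id = experiment),
                      well = well, field = field, rbp_marker = "FUS"),
      truth = NULL), class = "field_stack")
  })
}

# A balanced set of fake fields where the positive class has a brighter
# intensity distribution (smaller gamma).
fake_two_class_fields <- function(n_per_class, size = 128, gamma_pos = 0.5,
                                  seed = 1) {
  fields <- list()
  for (i in seq_len(n_per_class)) {
    fields[[length(fields) + 1]] <-
      fake_field("control", sprintf("WC%02d", i), 1, size = size, seed = seed)
    fields[[length(fields) + 1]] <-
      fake_field("mutant", sprintf("WM%02d", i), 1, size = size,
                 gamma = gamma_pos, seed = seed + 1000)
  }
  fields
}

# Small preprocessing config for fake-field tests.
tiny_pp <- preprocess_config(tile_size = 64, resize_to = 32)

# Random separable crop set: positive class brighter in one slot.
separable_crops <- function(n_per_class, size = 32, shift = 0.5, seed = 1) {
  neuroscreen:::with_seed(seed, {
    n <- 2 * n_per_class
    x <- array(rnorm(size * size * 3 * n), dim = c(size, size, 3, n))
    y <- rep(0:1, times = n_per_class)
    x[, , 1, y == 1] <- x[, , 1, y == 1] + shift
    list(x = x, y = y)
  })
}
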