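# Preprocessing pipeline: MIP, composition, autocontrast, tiling, resize,
# normalization, augmentation, and the fixed stage order.

test_that("maximum-intensity projection equals the element-wise maximum", {
  one <- array(matrix(1:6, 2, 3), dim = c(2, 3, 1))
  expect_equal(max_intensity_projection(one), matrix(1:6, 2, 3))
  st <- array(0, dim = c(2, 2, 2))
  st[, , 1] <- matrix(c(1, 3, 5, 2), 2, 2, byrow = TRUE)
  st[, , 2] <- matrix(c(4, 2, 0, 9), 2, 2, byrow = TRUE)
  expect_equal(max_intensity_projection(st),
               matrix(c(4, 3, 5, 9), 2, 2, byrow = TRUE))
  expect_error(max_intensity_projection(array(0, dim = c(2, 2, 0))), "n_z")
})

test_that("maximum-intensity projection matches a brute-force loop oracle", {
  st <- neuroscreen:::with_seed(5,
    array(sample.int(65535, 5 * 64 * 64, replace = TRUE), dim = c(64, 64, 5)))
  oracle <- matrix(0, 64, 64)
  for (i in 1:64) for (j in 1:64) {
    m <- st[i, j, 1]
    for (k in 2:5) if (st[i, j, k] > m) m <- st[i, j, k]
    oracle[i, j] <- m
  }
  expect_equal(max_intensity_projection(st), oracle)
})

test_that("RGB composition assigns slots and converts 16->8 bit by floor", {
  ch <- list(DAPI = matrix(65535L, 4, 4), BIII = matrix(255L, 4, 4),
             FUS = matrix(256L, 4, 4))
  img <- compose_rgb(ch, channel_combination(c("DAPI", "BIII", "FUS")))
  expect_equal(img$pixels[1, 1, ], c(0L, 1L, 255L))  # BIII, FUS, DAPI slots
  expect_equal(unname(img$slot_map),
               c("BIII", "FUS", "DAPI"))
  solo <- compose_rgb(ch, channel_combination("DAPI"))
  expect_true(all(solo$pixels[, , 1] == 0))  # red placeholder pitch-black
  expect_true(all(solo$pixels[, , 2] == 0))
  expect_true(all(solo$pixels[, , 3] == 255))
  expect_error(compose_rgb(ch["DAPI"], channel_combination(c("DAPI", "BIII"))),
               "BIII")
})

test_that("channel combinations reject duplicates and two RBPs", {
  expect_error(channel_combination(c("DAPI", "DAPI")), "duplicate")
  expect_error(channel_combination(c("FUS", "TDP43")), "at most one RBP")
})

test_that("autocontrast trims tails and remaps to the full 8-bit range", {
  mk <- function(v, n = length(v)) {
    px <- array(0L, dim = c(1, n, 3))
    px[1, , 1] <- as.integer(v)
    structure(list(pixels = px,
                   slot_map = c(red = "BIII", green = "PLACEHOLDER",
                                blue = "PLACEHOLDER")),
              class = "rgb_image8")
  }
  # constant channel unchanged
  expect_equal(autocontrast(mk(rep(7, 100)))$pixels[1, , 1], rep(7L, 100))
  # cutoff 0: min -> 0, max -> 255
  out <- autocontrast(mk(c(10, 60, 110)), cutoff_percent = 0)$pixels[1, , 1]
  expect_equal(out, c(0L, 128L, 255L))
  # 1000 pixels, one bright outlier, 0.1% cutoff: remap anchored on the
  # trimmed range; independent sorted-quantile oracle
  v <- c(rep(50:100, length.out = 999), 255)
  out <- autocontrast(mk(v), cutoff_percent = 0.1)$pixels[1, , 1]
  cut <- floor(1000 * 0.1 / 100)
  sv <- sort(v)
  lo <- sv[cut + 1]; hi <- sv[1000 - cut]
  oracle <- pmin(pmax(as.integer(round((v - lo) * 255 / (hi - lo))), 0L), 255L)
  expect_equal(out, oracle)
  expect_equal(out[1000], 255L)  # outlier clipped to white
})

test_that("placeholder slots stay pitch-black through contrast and tiling", {
  ch <- list(DAPI = matrix(as.integer(runif(128 * 128, 0, 65535)), 128, 128))
  img <- autocontrast(compose_rgb(ch, channel_combination("DAPI")))
  expect_true(all(img$pixels[, , 1] == 0) && all(img$pixels[, , 2] == 0))
  tiles <- tile_image(img, 64)
  for (tl in tiles) expect_true(all(tl$pixels[, , 1:2] == 0))
  nm <- resize_and_normalize(tiles[[1]], size = 32)
  cst <- normalization_constants()
  expect_true(all(nm[, , 1] == (0 - cst$mean[1]) / cst$std[1]))
})

test_that("tiling produces a row-major partition that reassembles exactly", {
  ch <- list(DAPI = matrix(as.integer(runif(1080 * 1080, 0, 65535)), 1080, 1080))
  img <- compose_rgb(ch, channel_combination("DAPI"))
  tiles <- tile_image(img, 270)
  expect_length(tiles, 16)
  for (tl in tiles) expect_equal(dim(tl$pixels), c(270, 270, 3))
  # tile 1 covers the top-left block
  expect_equal(tiles[[1]]$pixels, img$pixels[1:270, 1:270, , drop = FALSE])
  # reassembly is pixel-exact
  rec <- array(0L, dim = dim(img$pixels))
  i <- 0
  for (r in 1:4) for (c in 1:4) {
    i <- i + 1
    rec[(r - 1) * 270 + 1:270, (c - 1) * 270 + 1:270, ] <- tiles[[i]]$pixels
  }
  expect_identical(rec, img$pixels)
  # generalized grid and the indivisible rejection
  ch5 <- list(DAPI = matrix(0L, 540, 540))
  expect_length(tile_image(compose_rgb(ch5, channel_combination("DAPI")), 270), 4)
  ch6 <- list(DAPI = matrix(0L, 500, 500))
  expect_error(tile_image(compose_rgb(ch6, channel_combination("DAPI")), 270),
               "not divisible")
})

test_that("resize_and_normalize applies the declared constants at 224", {
  px <- array(0L, dim = c(270, 270, 3))
  px[, , 1] <- 255L
  tile <- structure(list(pixels = px,
                         slot_map = c(red = "BIII", green = "PLACEHOLDER",
                                      blue = "PLACEHOLDER")),
                    class = "rgb_image8")
  out <- resize_and_normalize(tile, size = 224)
  expect_equal(dim(out), c(224, 224, 3))
  cst <- normalization_constants()
  expect_true(all(abs(out[, , 1] - (1 - cst$mean[1]) / cst$std[1]) < 1e-12))
  expect_true(all(abs(out[, , 2] - (0 - cst$mean[2]) / cst$std[2]) < 1e-12))
  expect_error(normalization_constants(std = c(0, 1, 1)), "std")
})

test_that("augmentation returns the six symmetries in fixed order", {
  m <- matrix(1:16, 4, 4)
  a <- augment(m)
  expect_length(a, 6)
  expect_identical(a[[1]], m)
  rot90 <- neuroscreen:::rot90_mat
  hm <- neuroscreen:::hmirror_mat
  vm <- neuroscreen:::vmirror_mat
  expect_identical(a[[2]], rot90(m))
  expect_identical(a[[3]], hm(m))
  expect_identical(a[[4]], vm(m))
  expect_identical(a[[5]], rot90(hm(m)))
  expect_identical(a[[6]], rot90(vm(m)))
  # involutions and symmetry degeneracy
  expect_identical(hm(hm(m)), m)
  expect_identical(vm(vm(m)), m)
  const <- matrix(3, 5, 5)
  expect_true(all(vapply(augment(const), identical, logical(1), const)))
  expect_error(augment(matrix(0, 3, 4)), "square")
})

test_that("preprocess_field equals the chained individual stages", {
  fs <- render_field(fixed_spec(seed = 31), size = 256, n_z = 3)
  combo <- channel_combination(c("DAPI", "BIII", "FUS"))
  cfg <- preprocess_config(tile_size = 128, resize_to = 64)
  got <- preprocess_field(fs, combo, cfg)
  # chain the stages by hand
  mips <- lapply(fs$channels[combo$members], max_intensity_projection)
  img <- autocontrast(compose_rgb(mips, combo), cfg$cutoff_percent)
  tiles <- tile_image(img, cfg$tile_size)
  expect_equal(got$n_tiles, 4)
  for (i in seq_along(tiles)) {
    expect_equal(got$crops[, , , i],
                 resize_and_normalize(tiles[[i]], cfg$constants, cfg$resize_to))
  }
})
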