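# Preprocessing: 16-bit z-stacks -> normalized classifier inputs.
# Fixed stage order: MIP -> 8-bit -> RGB composition -> autocontrast ->
# tiling -> resize -> normalization.

PLACEHOLDER <- "PLACEHOLDER"

#' Preprocessing configuration
#'
#' All pipeline constants in one place: 270-px tiles, resize to 224,
#' 0.1 percent autocontrast cutoff, and the ImageNet channel statistics
#' used for normalization.
#'
#' @param tile_size Tile edge in pixels.
#' @param resize_to Classifier input edge in pixels.
#' @param cutoff_percent Percent of pixels trimmed from each histogram tail
#'   before the contrast remap.
#' @param constants [normalization_constants()].
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(tile_size = 270, resize_to = 224,
                              cutoff_percent = 0.1,
                              constants = normalization_constants()) {
  structure(list(tile_size = as.integer(tile_size),
                 resize_to = as.integer(resize_to),
                 cutoff_percent = cutoff_percent,
                 constants = constants),
            class = "preprocess_config")
}

#' Channel normalization constants
#'
#' Mean and standard deviation per colour slot (red, green, blue) applied to
#' unit-scaled intensities, matching the statistics of the natural-image
#' corpus that pretrained backbones expect.
#'
#' @param mean,std Length-3 numeric vectors in slot order red, green, blue.
#' @return List of class `normalization_constants`.
#' @export
normalization_constants <- function(mean = c(0.485, 0.456, 0.406),
                                    std = c(0.229, 0.224, 0.225)) {
  if (any(std <= 0)) stopf("normalization std must be > 0")
  structure(list(mean = mean, std = std), class = "normalization_constants")
}

#' Maximum-intensity projection of a z-stack
#'
#' At each pixel the brightest value across all z-planes is kept.
#'
#' @param zstack H x W x n_z array (n_z >= 1), or H x W matrix.
#' @return H x W matrix of the same storage mode.
#' @export
#' @examples
#' max_intensity_projection(array(1:8, dim = c(2, 2, 2)))
max_intensity_projection <- function(zstack) {
  if (is.matrix(zstack)) return(zstack)
  d <- dim(zstack)
  if (is.null(d) || length(d) != 3 || d[3] < 1)
    stopf("z-stack must be a H x W x n_z array with n_z >= 1")
  out <- zstack[, , 1]
  for (k in seq_len(d[3])[-1]) out <- pmax(out, zstack[, , k])
  out
}

#' Channel combination
#'
#' A subset of the available markers assigned to fixed colour slots: the
#' neurite marker BIII to red, the RBP to green, DAPI to blue. Unused slots
#' are marked `PLACEHOLDER` and rendered pitch-black.
#'
#' @param members Character vector drawn from `"DAPI"`, `"BIII"` and at most
#'   one RBP name.
#' @return List of class `channel_combination` with `members`, `slot_map`
#'   (named red/green/blue) and a `label` like "DAPI:BIII:FUS".
#' @export
channel_combination <- function(members) {
  if (anyDuplicated(members)) stopf("duplicate markers in combination")
  rbp <- setdiff(members, c("DAPI", "BIII"))
  if (length(rbp) > 1)
    stopf("at most one RBP marker per combination (got %s)",
          paste(rbp, collapse = ", "))
  slot_map <- c(red = if ("BIII" %in% members) "BIII" else PLACEHOLDER,
                green = if (length(rbp) == 1) rbp else PLACEHOLDER,
                blue = if ("DAPI" %in% members) "DAPI" else PLACEHOLDER)
  ordered <- c(intersect(c("DAPI", "BIII"), members), rbp)
  structure(list(members = ordered, slot_map = slot_map,
                 label = paste(ordered, collapse = ":")),
            class = "channel_combination")
}

#' @export
#' @method print channel_combination
print.channel_combination <- function(x, ...) {
  cat(sprintf("<channel_combination> %s (R=%s G=%s B=%s)\n", x$label,
              x$slot_map["red"], x$slot_map["green"], x$slot_map["blue"]))
  invisible(x)
}

#' Compose an 8-bit RGB image from 16-bit channels
#'
#' Converts each member channel to 8-bit with the content-independent rule
#' `floor(x / 256)` and places it in its colour slot; placeholder slots are
#' pitch-black.
#'
#' @param channels Named list of H x W 16-bit matrices (markers).
#' @param combo A [channel_combination()].
#' @return Object of class `rgb_image8`: `pixels` (H x W x 3 integer array
#'   in \[0, 255\], slots ordered red, green, blue) and `slot_map`.
#' @export
compose_rgb <- function(channels, combo) {
  stopifnot(inherits(combo, "channel_combination"))
  missing <- setdiff(combo$members, names(channels))
  if (length(missing) > 0)
    stopf("marker '%s' missing from supplied channels", missing[1])
  ref <- channels[[combo$members[1]]]
  H <- nrow(ref); W <- ncol(ref)
  px <- array(0L, dim = c(H, W, 3))
  for (s in 1:3) {
    mk <- combo$slot_map[s]
    if (mk != PLACEHOLDER) {
      ch <- channels[[mk]]
      if (!all(dim(ch) == c(H, W))) stopf("channel '%s' has mismatched size", mk)
      px[, , s] <- as.integer(ch) %/% 256L
    }
  }
  structure(list(pixels = px, slot_map = combo$slot_map), class = "rgb_image8")
}

# Pillow-style per-channel histogram trim: walk `cut` pixels in from each
# end of the 0..255 histogram, then remap [lo, hi] -> [0, 255] linearly.
autocontrast_channel <- function(v, cutoff_percent) {
  if (max(v) == min(v)) return(v)  # constant channel left unchanged
  h <- tabulate(v + 1L, nbins = 256L)
  cut <- floor(length(v) * cutoff_percent / 100)
  lo_cut <- cut; lo <- 0L
  for (i in 0:255) {
    if (h[i + 1] > lo_cut) { lo <- i; break }
    lo_cut <- lo_cut - h[i + 1]
  }
  hi_cut <- cut; hi <- 255L
  for (i in 255:0) {
    if (h[i + 1] > hi_cut) { hi <- i; break }
    hi_cut <- hi_cut - h[i + 1]
  }
  if (hi <= lo) return(v)
  out <- round((v - lo) * 255 / (hi - lo))
  as.integer(pmin(pmax(out, 0), 255))
}

#' Autocontrast an RGB image
#'
#' Per non-placeholder slot, trims `cutoff_percent` of the lightest and
#' darkest pixels from the intensity histogram and linearly remaps the
#' remaining range so its darkest pixel becomes 0 and its lightest 255;
#' trimmed outliers are clipped. Constant slots are left unchanged.
#'
#' @param img An `rgb_image8` from [compose_rgb()].
#' @param cutoff_percent Tail trim per side, in percent of pixels.
#' @return An `rgb_image8`.
#' @export
autocontrast <- function(img, cutoff_percent = 0.1) {
  stopifnot(inherits(img, "rgb_image8"))
  for (s in 1:3) {
    if (img$slot_map[s] == PLACEHOLDER) next
    v <- as.integer(img$pixels[, , s])
    img$pixels[, , s] <- autocontrast_channel(v, cutoff_percent)
  }
  img
}

#' Cut an image into non-overlapping square tiles
#'
#' Row-major grid with the origin at the top-left: a 1080 x 1080 image with
#' the default 270-px tile yields 16 tiles, the first covering rows and
#' columns 1-270. Concatenating the tiles reconstructs the image exactly.
#'
#' @param img An `rgb_image8`.
#' @param tile_size Tile edge; both image dimensions must be divisible by it.
#' @return List of `rgb_image8` tiles with attribute `grid = c(rows, cols)`.
#' @export
tile_image <- function(img, tile_size = 270) {
  stopifnot(inherits(img, "rgb_image8"))
  H <- dim(img$pixels)[1]; W <- dim(img$pixels)[2]
  if (H %% tile_size != 0 || W %% tile_size != 0)
    stopf("image size %d x %d is not divisible by tile size %d", H, W, tile_size)
  nr <- H %/% tile_size; nc <- W %/% tile_size
  tiles <- vector("list", nr * nc)
  i <- 0
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    i <- i + 1
    rows <- ((r - 1) * tile_size + 1):(r * tile_size)
    cols <- ((c - 1) * tile_size + 1):(c * tile_size)
    tiles[[i]] <- structure(list(pixels = img$pixels[rows, cols, , drop = FALSE],
                                 slot_map = img$slot_map), class = "rgb_image8")
  }
  attr(tiles, "grid") <- c(nr, nc)
  tiles
}

#' Resize a tile and normalize for the classifier
#'
#' Bilinear resize to `size` x `size`, intensity scaling to \[0, 1\], then
#' per-slot standardization with the supplied constants.
#'
#' @param tile An `rgb_image8`.
#' @param constants [normalization_constants()].
#' @param size Output edge in pixels.
#' @return `size` x `size` x 3 numeric array.
#' @export
resize_and_normalize <- function(tile, constants = normalization_constants(),
                                 size = 224) {
  stopifnot(inherits(tile, "rgb_image8"),
            inherits(constants, "normalization_constants"))
  out <- array(0, dim = c(size, size, 3))
  in_size <- dim(tile$pixels)[1:2]
  for (s in 1:3) {
    m <- tile$pixels[, , s] / 255
    if (!all(in_size == size)) {
      if (max(m) == min(m)) {
        m <- matrix(m[1, 1], size, size)  # constant slot: exact, no resample
      } else {
        m <- as.matrix(EBImage::resize(m, w = size, h = size,
                                       filter = "bilinear"))
      }
    }
    out[, , s] <- (m - constants$mean[s]) / constants$std[s]
  }
  out
}

# --- augmentation -----------------------------------------------------

rot90_mat <- function(m) t(m)[ncol(m):1, , drop = FALSE]
hmirror_mat <- function(m) m[, ncol(m):1, drop = FALSE]
vmirror_mat <- function(m) m[nrow(m):1, , drop = FALSE]

apply_slotwise <- function(x, f) {
  if (is.matrix(x)) return(f(x))
  d <- dim(x)
  out <- array(x[1], dim = c(dim(f(x[, , 1])), d[3]))
  for (s in seq_len(d[3])) out[, , s] <- f(x[, , s])
  out
}

#' Sixfold geometric augmentation
#'
#' Returns the training-time augmentation family in fixed order: the
#' original, a 90-degree rotation, horizontal and vertical mirrors, and the
#' 90-degree rotations of the two mirrors.
#'
#' @param img A square matrix, H x W x C array, or `rgb_image8`.
#' @return List of 6 objects of the same type as the input, in the order
#'   original, rot90, hmirror, vmirror, rot90(hmirror), rot90(vmirror).
#' @export
augment <- function(img) {
  raw <- if (inherits(img, "rgb_image8")) img$pixels else img
  d <- dim(raw)
  if (d[1] != d[2]) stopf("augmentation requires a square image")
  ops <- list(identity, function(m) rot90_mat(m), hmirror_mat, vmirror_mat,
              function(m) rot90_mat(hmirror_mat(m)),
              function(m) rot90_mat(vmirror_mat(m)))
  lapply(ops, function(f) {
    out <- apply_slotwise(raw, f)
    if (inherits(img, "rgb_image8"))
      structure(list(pixels = out, slot_map = img$slot_map), class = "rgb_image8")
    else out
  })
}

#' Preprocess one field into classifier-ready crops
#'
#' Chains the fixed pipeline: per-marker maximum-intensity projection, 8-bit
#' conversion and RGB composition for the requested channel combination,
#' autocontrast, tiling, bilinear resize and normalization.
#'
#' @param field A `field_stack` (or a named list of H x W x n_z arrays).
#' @param combo A [channel_combination()].
#' @param config A [preprocess_config()].
#' @return List with `crops` (size x size x 3 x n_tiles array) and `n_tiles`.
#' @export
preprocess_field <- function(field, combo, config = preprocess_config()) {
  channels <- if (inherits(field, "field_stack")) field$channels else field
  mips <- lapply(channels[combo$members], max_intensity_projection)
  img <- compose_rgb(mips, combo)
  img <- autocontrast(img, config$cutoff_percent)
  tiles <- tile_image(img, config$tile_size)
  n <- length(tiles)
  crops <- array(0, dim = c(config$resize_to, config$resize_to, 3, n))
  for (i in seq_len(n))
    crops[, , , i] <- resize_and_normalize(tiles[[i]], config$constants,
                                           config$resize_to)
  list(crops = crops, n_tiles = n)
}
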