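# Field renderer: turns a culture_spec into three 16-bit z-stacks
# (DAPI nuclei, BIII neurite network + somata, RBP nuclear/cytoplasmic
# mixture) plus ground-truth masks.

# Signals are scaled so that bright structures sit near this many counts,
# leaving 16-bit headroom and making autocontrast a real operation.
RENDER_GAIN <- 20000
N_FOURIER_MODES <- 6

gblur_mat <- function(m, sigma) {
  if (sigma <= 0) return(m)
  as.matrix(EBImage::gblur(m, sigma = sigma))
}

# Rasterize one nucleus: ellipse whose boundary radius is modulated by
# N_FOURIER_MODES Fourier modes with fixed amplitude and random phases, so
# the radial perturbation has standard deviation ~= irregularity * radius.
draw_nucleus <- function(mask, cx, cy, radius, irregularity,
                         ecc = NULL, psi = NULL, phases = NULL) {
  H <- nrow(mask); W <- ncol(mask)
  ecc <- ecc %||% runif(1, 0, 0.3)
  a <- radius * (1 + ecc); b <- radius / (1 + ecc)
  psi <- psi %||% runif(1, 0, pi)
  phases <- phases %||% runif(N_FOURIER_MODES, 0, 2 * pi)
  amp <- irregularity * sqrt(2 / N_FOURIER_MODES)

  ext <- ceiling(a * (1 + 3 * max(irregularity, 0.05)) + 2)
  rows <- max(1, floor(cy - ext)):min(H, ceiling(cy + ext))
  cols <- max(1, floor(cx - ext)):min(W, ceiling(cx + ext))
  dy <- rows - cy
  dx <- cols - cx
  DX <- matrix(rep(dx, each = length(dy)), nrow = length(dy))
  DY <- matrix(rep(dy, times = length(dx)), nrow = length(dy))
  xr <- DX * cos(psi) + DY * sin(psi)
  yr <- -DX * sin(psi) + DY * cos(psi)
  theta <- atan2(yr, xr)
  r_ell <- a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
  delta <- 0
  for (k in seq_len(N_FOURIER_MODES))
    delta <- delta + amp * cos(k * theta + phases[k])
  # divide by sqrt(E[(1+delta)^2]) so the perturbation preserves expected
  # area: the phenotype is the outline, not the size
  inside <- sqrt(xr^2 + yr^2) <=
    r_ell * (1 + delta) / sqrt(1 + irregularity^2)
  mask[rows, cols] <- mask[rows, cols] | inside
  mask
}

# Branching random walk returning per-step segments, grouped into deletable
# chunks. Step length 2 px, bounded heading noise, branch prob 0.1 per step.
grow_tree <- function(x0, y0, H, W, max_steps = 300, step_len = 2,
                      heading_sd = 0.15, branch_prob = 0.1, chunk_len = 8) {
  segs <- matrix(numeric(0), ncol = 4)
  chunk <- integer(0)
  stack <- list(list(x = x0, y = y0, h = runif(1, 0, 2 * pi)))
  steps <- 0; chunk_id <- 0
  while (length(stack) > 0 && steps < max_steps) {
    st <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    chunk_id <- chunk_id + 1
    in_chunk <- 0
    while (steps < max_steps) {
      st$h <- st$h + rnorm(1, 0, heading_sd)
      nx <- st$x + step_len * cos(st$h)
      ny <- st$y + step_len * sin(st$h)
      if (nx < 2 || nx > W - 1 || ny < 2 || ny > H - 1) break
      segs <- rbind(segs, c(st$x, st$y, nx, ny))
      if (in_chunk >= chunk_len) { chunk_id <- chunk_id + 1; in_chunk <- 0 }
      chunk <- c(chunk, chunk_id)
      in_chunk <- in_chunk + 1
      st$x <- nx; st$y <- ny
      steps <- steps + 1
      if (runif(1) < branch_prob)
        stack[[length(stack) + 1]] <-
          list(x = st$x, y = st$y, h = st$h + sample(c(-1, 1), 1) * runif(1, 0.6, 1.2))
    }
  }
  list(segments = segs, chunk = chunk)
}

# Mark the pixels of a 2-px segment (endpoints + midpoints) in a mask.
stamp_segments <- function(mask, segs) {
  if (nrow(segs) == 0) return(mask)
  ts <- c(0, 0.34, 0.67, 1)
  for (t in ts) {
    xs <- round(segs[, 1] + t * (segs[, 3] - segs[, 1]))
    ys <- round(segs[, 2] + t * (segs[, 4] - segs[, 2]))
    ok <- xs >= 1 & xs <= ncol(mask) & ys >= 1 & ys <= nrow(mask)
    mask[cbind(ys[ok], xs[ok])] <- TRUE
  }
  mask
}

disk_mask <- function(mask, cx, cy, r) {
  H <- nrow(mask); W <- ncol(mask)
  rows <- max(1, floor(cy - r)):min(H, ceiling(cy + r))
  cols <- max(1, floor(cx - r)):min(W, ceiling(cx + r))
  DY <- matrix(rep(rows - cy, times = length(cols)), nrow = length(rows))
  DX <- matrix(rep(cols - cx, each = length(rows)), nrow = length(rows))
  mask[rows, cols] <- mask[rows, cols] | (DX^2 + DY^2 <= r^2)
  mask
}

#' Render one synthetic field of view
#'
#' Produces the three-marker z-stack a real well would yield: a DAPI channel
#' of radially perturbed elliptical nuclei, a beta-III-tubulin channel of
#' branching neurite trees rendered as Gaussian tubes plus somata, and one
#' RBP channel mixing nuclear and cytoplasmic signal at the spec's
#' nuclear-to-cytoplasmic ratio. Out-of-focus planes are obtained by blurring
#' the in-focus render with a sigma proportional to the distance from the
#' focus plane; Poisson shot noise and Gaussian read noise are added unless
#' `noise_sd` is 0. Ground-truth masks (nuclei, neurite skeleton, somata) are
#' returned alongside for property tests.
#'
#' @param spec A [culture_spec()].
#' @param size Height/width in pixels (scalar or length-2; >= 256).
#' @param n_z Number of z planes (3-5); sampled uniformly when `NULL`.
#' @param rbp_marker Name of the RBP channel (e.g. "FUS").
#' @param well,field Metadata labels stored with the stack.
#' @return A list of class `field_stack` with elements `channels` (named list
#'   of H x W x n_z integer arrays in \[0, 65535\]), `n_z`, `focus`,
#'   `metadata`, and `truth` (class `ground_truth`: `nucleus_mask`,
#'   `neurite_skeleton`, `soma_mask`, `params_used`).
#' @export
#' @examples
#' spec <- culture_spec("control", "CTRL1", "EXP1", seed = 7)
#' fs <- render_field(spec, size = 256)
#' dim(fs$channels$DAPI)
render_field <- function(spec, size = 540, n_z = NULL,
                         rbp_marker = "FUS", well = "W01", field = 1L) {
  stopifnot(inherits(spec, "culture_spec"))
  if (length(size) == 1) size <- c(size, size)
  if (any(size < 256)) stopf("field size must be at least 256 x 256")
  H <- as.integer(size[1]); W <- as.integer(size[2])
  p <- spec$phenotype

  with_seed(derive_seed(spec$seed, "field", well, field), {
    area_ratio <- (H * W) / (540^2)

    ## --- nuclei -------------------------------------------------------
    n_nuclei <- max(3, rpois(1, 30 * area_ratio))
    margin <- p$nuclear_radius_px + 5
    centers <- matrix(numeric(0), ncol = 2)
    tries <- 0
    while (nrow(centers) < n_nuclei && tries < 500) {
      tries <- tries + 1
      cx <- runif(1, margin, W - margin)
      cy <- runif(1, margin, H - margin)
      if (nrow(centers) == 0 ||
          min((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2) >
            (2.2 * p$nuclear_radius_px)^2)
        centers <- rbind(centers, c(cx, cy))
    }
    nucleus_mask <- matrix(FALSE, H, W)
    radii <- numeric(nrow(centers))
    for (i in seq_len(nrow(centers))) {
      radii[i] <- p$nuclear_radius_px * rnorm(1, 1, 0.1)
      nucleus_mask <- draw_nucleus(nucleus_mask, centers[i, 1], centers[i, 2],
                                   radii[i], p$nuclear_irregularity)
    }

    ## --- somata and neurites -----------------------------------------
    soma_mask <- matrix(FALSE, H, W)
    for (i in seq_len(nrow(centers)))
      soma_mask <- disk_mask(soma_mask, centers[i, 1], centers[i, 2],
                             radii[i] * 1.3)
    skeleton <- matrix(FALSE, H, W)
    n_trees <- rpois(1, p$neurite_density * area_ratio)
    for (t in seq_len(n_trees)) {
      root <- centers[sample.int(nrow(centers), 1), ]
      tr <- grow_tree(root[1], root[2], H, W)
      if (nrow(tr$segments) == 0) next
      keep_chunk <- runif(max(tr$chunk)) >= p$neurite_fragmentation
      keep <- keep_chunk[tr$chunk]
      skeleton <- stamp_segments(skeleton, tr$segments[keep, , drop = FALSE])
    }

    ## --- in-focus renders (unit scale) --------------------------------
    texture <- gblur_mat(matrix(runif(H * W, -1, 1), H, W), 3)
    dapi <- nucleus_mask * (1 + 0.2 * texture)

    tube <- gblur_mat(skeleton * 1.0, p$neurite_width_px) *
      sqrt(2 * pi) * p$neurite_width_px
    tube <- pmin(tube, 1.2)
    biii <- pmax(tube * 0.9, soma_mask * 0.5)

    cyto_mask <- (soma_mask | skeleton) & !nucleus_mask
    rbp <- nucleus_mask * 1.0 + cyto_mask * (1 / p$rbp_nc_ratio)

    in_focus <- list(DAPI = dapi, BIII = biii, rbp)
    names(in_focus)[3] <- rbp_marker

    ## --- z-stack assembly ---------------------------------------------
    if (is.null(n_z)) n_z <- sample(3:5, 1)
    if (n_z < 3 || n_z > 5) stopf("n_z must lie in [3, 5]")
    focus <- sample.int(n_z, 1)
    sigma0 <- 2
    channels <- lapply(in_focus, function(img) {
      st <- array(0L, dim = c(H, W, n_z))
      for (k in seq_len(n_z)) {
        plane <- gblur_mat(img, sigma0 * abs(k - focus)) * RENDER_GAIN
        if (p$noise_sd > 0) {
          plane <- matrix(rpois(H * W, pmax(plane, 0)), H, W) +
            rnorm(H * W, 0, p$noise_sd)
        }
        st[, , k] <- as.integer(pmin(pmax(round(plane), 0), 65535))
      }
      st
    })

    truth <- structure(list(
      nucleus_mask = nucleus_mask,
      neurite_skeleton = skeleton,
      soma_mask = soma_mask,
      cytoplasm_mask = cyto_mask,
      params_used = p
    ), class = "ground_truth")

    structure(list(
      channels = channels,
      n_z = as.integer(n_z),
      focus = as.integer(focus),
      metadata = list(spec = spec, well = well, field = as.integer(field),
                      rbp_marker = rbp_marker),
      truth = truth
    ), class = "field_stack")
  })
}

#' @export
#' @method print field_stack
print.field_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<field_stack> %d x %d, %d z-planes, markers: %s\n",
              d[1], d[2], x$n_z, paste(names(x$channels), collapse = ", ")))
  invisible(x)
}
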