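# Integrated-gradients attribution and overlay rendering.

#' Integrated gradients attribution
#'
#' Approximates the path integral of the model's score gradient along the
#' straight line from a baseline image to the input, so that each pixel's
#' attribution is `(x - x') * mean_m dF(x' + (m/steps)(x - x'))/dx`
#' (right-endpoint Riemann sum, m = 1..steps). By the completeness axiom the
#' attributions sum to `F(x) - F(x')` as `steps` grows; for a linear scorer
#' the sum is exact at any number of steps. The attribution target is the
#' pre-softmax score of the selected (by default the predicted) class.
#'
#' @param model A model with a [score_gradient()] method.
#' @param image Input array (e.g. `h x w x 3` normalized crop).
#' @param baseline Reference image of the same shape; default all-zero.
#' @param steps Path resolution (>= 1).
#' @param target 1-based class index; default: class with the highest score
#'   at the input.
#' @param batch_size Interpolated images evaluated per backward pass.
#' @return Object of class `attribution_map`: `values` (signed, same shape
#'   as the input), `magnitude` (per-pixel L1 over slots, max-normalized to
#'   \[0, 1\]; all-zero map if every attribution is zero), `baseline`,
#'   `steps`, `target`, `score` and `baseline_score`.
#' @export
integrated_gradients <- function(model, image, baseline = NULL, steps = 50,
                                 target = NULL, batch_size = 25) {
  if (steps < 1) stopf("'steps' must be >= 1")
  baseline <- baseline %||% array(0, dim = dim(image))
  if (!identical(dim(baseline), dim(image)))
    stopf("baseline and image shapes differ")
  if (is.null(target)) {
    sc <- score_gradient(model, image, class = 1L)$scores
    target <- which.max(sc[, 1])
  }
  d <- dim(image)
  diff <- image - baseline
  grad_sum <- array(0, dim = d)
  alphas <- seq_len(steps) / steps
  for (start in seq(1, steps, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, steps)
    xb <- array(0, dim = c(d, length(idx)))
    for (j in seq_along(idx))
      xb[, , , j] <- baseline + alphas[idx[j]] * diff
    g <- score_gradient(model, xb, class = target)$grad
    grad_sum <- grad_sum + apply(g, 1:3, sum)
  }
  values <- diff * grad_sum / steps
  mag <- apply(abs(values), c(1, 2), sum)
  mx <- max(mag)
  if (mx > 0) mag <- mag / mx
  f_x <- score_gradient(model, image, class = target)$scores[target, 1]
  f_b <- score_gradient(model, baseline, class = target)$scores[target, 1]
  structure(list(values = values, magnitude = mag, baseline = baseline,
                 steps = as.integer(steps), target = as.integer(target),
                 score = f_x, baseline_score = f_b),
            class = "attribution_map")
}

#' @export
#' @method print attribution_map
print.attribution_map <- function(x, ...) {
  cat(sprintf(
    "<attribution_map> %s, %d steps, class %d, sum(values) = %.4f, F(x)-F(x') = %.4f\n",
    paste(dim(x$values), collapse = " x "), x$steps, x$target,
    sum(x$values), x$score - x$baseline_score))
  invisible(x)
}

#' Overlay an attribution map on the original image
#'
#' Renders the 0-1 attribution magnitude as a white-to-blue ramp
#' alpha-blended over the original 8-bit image: pixels with no contribution
#' show the original, the strongest contribution saturates to blue.
#'
#' @param map An `attribution_map`.
#' @param original An `rgb_image8` (or H x W x 3 array in 0-255) matching
#'   the map's spatial shape.
#' @param alpha Maximum blend weight of the ramp.
#' @param path Optional PNG output path.
#' @return H x W x 3 integer array in \[0, 255\] (invisibly when written).
#' @export
attribution_overlay <- function(map, original, alpha = 0.7, path = NULL) {
  stopifnot(inherits(map, "attribution_map"))
  orig <- if (inherits(original, "rgb_image8")) original$pixels else original
  if (!all(dim(orig)[1:2] == dim(map$magnitude)))
    stopf("attribution map and image shapes differ")
  mag <- map$magnitude
  ramp <- array(0, dim = dim(orig))
  ramp[, , 1] <- 255 * (1 - mag)
  ramp[, , 2] <- 255 * (1 - mag)
  ramp[, , 3] <- 255
  w <- array(rep(alpha * mag, 3), dim = dim(orig))
  out <- (1 - w) * orig + w * ramp
  out <- array(as.integer(pmin(pmax(round(out), 0), 255)), dim = dim(orig))
  if (!is.null(path)) {
    png::writePNG(out / 255, path)
    return(invisible(out))
  }
  out
}
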