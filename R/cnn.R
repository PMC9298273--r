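# Small scratch CNN: 4 stride-2 conv/ReLU blocks, global average pooling,
# 2-way linear head. Forward/backward are exact (no dropout/batchnorm), so
# training is deterministic given the seed and integrated gradients can be
# computed from the same backward machinery.

#' Classifier configuration
#'
#' Training hyperparameters of the binary image classifiers: stochastic
#' gradient descent with learning rate 0.001, batch size 32, cross-entropy
#' loss, 10 epochs.
#'
#' @param backbone `"scratch_small_cnn"` (default; trained from random
#'   initialisation) or `"pretrained_mobilenet_v2"` (requires externally
#'   supplied weights; not bundled).
#' @param learning_rate SGD learning rate (> 0). The default matches the
#'   fine-tuning setting; networks trained from scratch typically need a
#'   larger rate (see `scratch_learning_rate` in the cross-validation
#'   helpers).
#' @param momentum SGD momentum coefficient in \[0, 1).
#' @param batch_size Minibatch size.
#' @param epochs Number of passes over the training set (>= 1).
#' @param conv_channels Filters per conv block of the scratch backbone.
#' @param seed Integer seed expanded deterministically into weight-init and
#'   batch-order sub-seeds.
#' @return List of class `classifier_config`.
#' @export
classifier_config <- function(backbone = c("scratch_small_cnn",
                                           "pretrained_mobilenet_v2"),
                              learning_rate = 0.001, momentum = 0.9,
                              batch_size = 32,
                              epochs = 10, conv_channels = c(8, 16, 32, 64),
                              seed = 1) {
  backbone <- match.arg(backbone)
  if (learning_rate <= 0) stopf("'learning_rate' must be > 0")
  if (momentum < 0 || momentum >= 1) stopf("'momentum' must lie in [0, 1)")
  if (epochs < 1) stopf("'epochs' must be >= 1")
  structure(list(backbone = backbone, learning_rate = learning_rate,
                 momentum = momentum,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 conv_channels = conv_channels, n_classes = 2L,
                 seed = as.integer(seed)),
            class = "classifier_config")
}

scratch_cnn_init <- function(input_channels = 3, conv_channels = c(8, 16, 32, 64),
                             seed = 1) {
  with_seed(derive_seed(seed, "init"), {
    cin <- input_channels
    conv <- list()
    for (f in conv_channels) {
      sdw <- sqrt(2 / (3 * 3 * cin))
      conv[[length(conv) + 1]] <- list(
        w = array(rnorm(3 * 3 * cin * f, 0, sdw), dim = c(3, 3, cin, f)),
        b = numeric(f))
      cin <- f
    }
    fc_w <- matrix(rnorm(2 * cin, 0, sqrt(1 / cin)), 2, cin)
    list(conv = conv, fc_w = fc_w, fc_b = numeric(2))
  })
}

cnn_forward <- function(weights, x, keep_cache = FALSE) {
  acts <- list(x)
  pre <- list()
  a <- x
  for (l in seq_along(weights$conv)) {
    z <- .conv_forward(a, weights$conv[[l]]$w, weights$conv[[l]]$b, 2L, 1L)
    a <- pmax(z, 0)
    if (keep_cache) { pre[[l]] <- z; acts[[l + 1]] <- a }
  }
  d <- dim(a)
  hw <- d[1] * d[2]
  feats <- matrix(colMeans(matrix(a, nrow = hw)), nrow = d[3])  # F x N
  logits <- weights$fc_w %*% feats + weights$fc_b               # 2 x N
  out <- list(logits = logits, feats = feats, out_dim = d)
  if (keep_cache) { out$acts <- acts; out$pre <- pre }
  out
}

cnn_backward <- function(weights, fwd, dlogits, need_input_grad = FALSE,
                         need_wgrads = TRUE) {
  grads <- list(conv = vector("list", length(weights$conv)))
  if (need_wgrads) {
    grads$fc_w <- dlogits %*% t(fwd$feats)
    grads$fc_b <- rowSums(dlogits)
  }
  dfeats <- t(weights$fc_w) %*% dlogits                 # F x N
  d <- fwd$out_dim
  hw <- d[1] * d[2]
  da <- array(rep(as.numeric(dfeats) / hw, each = hw), dim = d)
  for (l in rev(seq_along(weights$conv))) {
    dz <- da * (fwd$pre[[l]] > 0)
    need_dx <- l > 1 || need_input_grad
    bk <- .conv_backward(fwd$acts[[l]], weights$conv[[l]]$w, dz, 2L, 1L,
                         need_dx, need_wgrads)
    if (need_wgrads)
      grads$conv[[l]] <- list(w = bk$dw, b = bk$db)
    if (need_dx) da <- bk$dx
  }
  if (need_input_grad) grads$dx <- da
  grads
}

softmax_cols <- function(logits) {
  z <- sweep(logits, 2, apply(logits, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

#' Train a binary image classifier
#'
#' Minimises cross-entropy by minibatch stochastic gradient descent on the
#' scratch CNN backbone. Inputs are expected preprocessed (resized and
#' normalized); augmentation is the caller's responsibility so that
#' evaluation images are never augmented.
#'
#' @param x `h x w x 3 x N` array of normalized crops.
#' @param labels Integer/logical vector of length N with both classes
#'   present; class 1 is the positive class (disease / stress).
#' @param config A [classifier_config()].
#' @param verbose Print per-epoch loss.
#' @return Object of class `scratch_cnn` with the trained weights and the
#'   config; use [predict.scratch_cnn()] for probabilities.
#' @export
train_classifier <- function(x, labels, config = classifier_config(),
                             verbose = FALSE) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stopf("training set contains a single class; need both classes")
  if (config$backbone == "pretrained_mobilenet_v2")
    stopf(paste("pretrained_mobilenet_v2 requires externally supplied",
                "weights; use backbone = 'scratch_small_cnn'"))
  n <- dim(x)[4]
  stopifnot(length(labels) == n)
  weights <- scratch_cnn_init(dim(x)[3], config$conv_channels, config$seed)
  lr <- config$learning_rate
  mom <- config$momentum %||% 0
  vel <- list(conv = lapply(weights$conv, function(l)
    list(w = array(0, dim = dim(l$w)), b = numeric(length(l$b)))),
    fc_w = matrix(0, nrow(weights$fc_w), ncol(weights$fc_w)),
    fc_b = numeric(2))
  for (epoch in seq_len(config$epochs)) {
    ord <- with_seed(derive_seed(config$seed, "epoch", epoch), sample.int(n))
    total_loss <- 0
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1, n)]
      xb <- x[, , , idx, drop = FALSE]
      yb <- labels[idx]
      fwd <- cnn_forward(weights, xb, keep_cache = TRUE)
      p <- softmax_cols(fwd$logits)
      eps <- 1e-12
      total_loss <- total_loss -
        sum(log(pmax(p[cbind(yb + 1L, seq_along(idx))], eps)))
      dlogits <- p
      dlogits[cbind(yb + 1L, seq_along(idx))] <-
        dlogits[cbind(yb + 1L, seq_along(idx))] - 1
      dlogits <- dlogits / length(idx)
      g <- cnn_backward(weights, fwd, dlogits)
      for (l in seq_along(weights$conv)) {
        vel$conv[[l]]$w <- mom * vel$conv[[l]]$w - lr * g$conv[[l]]$w
        vel$conv[[l]]$b <- mom * vel$conv[[l]]$b - lr * g$conv[[l]]$b
        weights$conv[[l]]$w <- weights$conv[[l]]$w + vel$conv[[l]]$w
        weights$conv[[l]]$b <- weights$conv[[l]]$b + vel$conv[[l]]$b
      }
      vel$fc_w <- mom * vel$fc_w - lr * g$fc_w
      vel$fc_b <- mom * vel$fc_b - lr * g$fc_b
      weights$fc_w <- weights$fc_w + vel$fc_w
      weights$fc_b <- weights$fc_b + vel$fc_b
    }
    if (verbose)
      message(sprintf("epoch %d/%d: loss %.4f", epoch, config$epochs,
                      total_loss / n))
  }
  structure(list(weights = weights, config = config,
                 input_dim = dim(x)[1:3]),
            class = "scratch_cnn")
}

#' Predict class probabilities with a trained classifier
#'
#' @param object A `scratch_cnn` from [train_classifier()].
#' @param newdata `h x w x 3 x N` array (or a single `h x w x 3` image).
#' @param type `"prob"` for positive-class probabilities, `"logit"` for the
#'   raw 2 x N class scores.
#' @param batch_size Evaluation minibatch size.
#' @param ... Unused.
#' @return Numeric vector of length N (`"prob"`) or a 2 x N matrix.
#' @export
predict.scratch_cnn <- function(object, newdata, type = c("prob", "logit"),
                                batch_size = 64, ...) {
  type <- match.arg(type)
  if (length(dim(newdata)) == 3)
    dim(newdata) <- c(dim(newdata), 1)
  n <- dim(newdata)[4]
  logits <- matrix(0, 2, n)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    logits[, idx] <- cnn_forward(object$weights,
                                 newdata[, , , idx, drop = FALSE])$logits
  }
  if (type == "logit") return(logits)
  softmax_cols(logits)[2, ]
}

#' Model score and input gradient
#'
#' Generic used by [integrated_gradients()]: for a batch of inputs, return
#' the per-class scores and the gradient of the selected class's score with
#' respect to every input pixel.
#'
#' @param model A differentiable model object.
#' @param x Input batch `h x w x c x N` (or single `h x w x c`).
#' @param class 1-based index of the class whose score is differentiated.
#' @return List with `scores` (n_classes x N matrix) and `grad`
#'   (same shape as `x`).
#' @export
score_gradient <- function(model, x, class = 1L) UseMethod("score_gradient")

#' @rdname score_gradient
#' @export
score_gradient.scratch_cnn <- function(model, x, class = 1L) {
  single <- length(dim(x)) == 3
  if (single) dim(x) <- c(dim(x), 1)
  n <- dim(x)[4]
  fwd <- cnn_forward(model$weights, x, keep_cache = TRUE)
  dlogits <- matrix(0, nrow(fwd$logits), n)
  dlogits[class, ] <- 1
  g <- cnn_backward(model$weights, fwd, dlogits, need_input_grad = TRUE,
                    need_wgrads = FALSE)
  grad <- g$dx
  if (single) { dim(grad) <- dim(grad)[1:3] }
  list(scores = fwd$logits, grad = grad)
}

#' Linear image scorer
#'
#' A differentiable toy model `F(x) = sum(w * x) + b` whose integrated
#' gradients have the closed form `w * x` for a zero baseline; mainly useful
#' to validate attribution code.
#'
#' @param w Weight array (same shape as the images to score).
#' @param b Scalar offset.
#' @return Object of class `linear_scorer`.
#' @export
linear_scorer <- function(w, b = 0) {
  structure(list(w = w, b = b), class = "linear_scorer")
}

#' @rdname score_gradient
#' @export
score_gradient.linear_scorer <- function(model, x, class = 1L) {
  single <- length(dim(x)) == length(dim(model$w))
  if (single) dim(x) <- c(dim(x), 1)
  n <- dim(x)[length(dim(x))]
  scores <- matrix(0, 1, n)
  xm <- matrix(x, ncol = n)
  scores[1, ] <- colSums(xm * as.numeric(model$w)) + model$b
  grad <- array(rep(as.numeric(model$w), n), dim = dim(x))
  if (single) dim(grad) <- dim(model$w)
  list(scores = scores, grad = grad)
}
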