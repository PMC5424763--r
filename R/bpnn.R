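# Three-layer sigmoid back-propagation classifier: the modelling core of
# the package. `bpnn()` is the fitting function (formula or x/y interface)
# returning a classed object with the usual methods. The per-sample
# gradient-descent loop lives in compiled code; reference implementations
# of the forward pass, loss and analytic gradient are kept here in R and
# back the finite-difference gradient check.

#' Hidden-layer size rule
#'
#' The number of hidden nodes is half the sum of input and output nodes,
#' rounded up: nh = ceil((ni + no) / 2). Ceiling is forced by the
#' reference architectures (10 inputs -> 6 hidden, 9 inputs -> 6 hidden).
#'
#' @param ni number of input nodes (>= 1).
#' @param no number of output nodes (>= 1), default 2 (good/NG).
#' @return integer hidden-node count.
#' @export
hidden_nodes <- function(ni, no = 2L) {
  stopifnot(ni >= 1, no >= 1)
  as.integer(ceiling(0.5 * (ni + no)))
}

#' Min-max normalization bounds
#'
#' Fits per-feature (column) minima and maxima on a training matrix;
#' [normalize_apply()] maps features linearly onto \[0, 1\] and clips
#' out-of-range values (e.g. validation rows beyond the training range).
#'
#' @param x numeric matrix or data frame of training features.
#' @return list with numeric vectors `min` and `max` (named by column).
#' @export
normalize_fit <- function(x) {
  x <- as.matrix(x)
  mins <- apply(x, 2, min)
  maxs <- apply(x, 2, max)
  flat <- maxs - mins <= 0
  if (any(flat))
    stop("constant feature(s): ", paste(colnames(x)[flat], collapse = ", "))
  list(min = mins, max = maxs)
}

#' @rdname normalize_fit
#' @param bounds bounds from [normalize_fit()].
#' @export
normalize_apply <- function(bounds, x) {
  x <- as.matrix(x)
  sc <- sweep(sweep(x, 2, bounds$min, "-"), 2, bounds$max - bounds$min, "/")
  sc[sc < 0] <- 0
  sc[sc > 1] <- 1
  sc
}

#' Training configuration for a back-propagation network
#'
#' @param learning_rate online gradient-descent step size (> 0).
#' @param mse_tolerance stop when the epoch-mean squared error (over
#'   samples and output units) falls below this (> 0).
#' @param max_epochs epoch budget; hitting it flags the fit non-converged.
#' @param rng_seed integer seed driving weight initialization and the
#'   per-epoch sample shuffle.
#' @return list of class `"train_config"`.
#' @export
train_config <- function(learning_rate = 0.01, mse_tolerance = 0.01,
                         max_epochs = 10000L, rng_seed = 1L) {
  stopifnot(learning_rate > 0, mse_tolerance > 0, max_epochs >= 1)
  structure(list(learning_rate = learning_rate,
                 mse_tolerance = mse_tolerance,
                 max_epochs = as.integer(max_epochs),
                 rng_seed = as.integer(rng_seed)),
            class = "train_config")
}

#' Fit a back-propagation neural network classifier
#'
#' Fits a three-layer network (logistic sigmoid in hidden and output
#' layers) for two-class problems by online back-propagation: weights are
#' initialized uniformly in \[-0.5, 0.5\] from `cfg$rng_seed`, samples are
#' reshuffled every epoch, and training stops when the epoch-mean squared
#' error against one-hot targets drops below `cfg$mse_tolerance` (or at
#' `cfg$max_epochs`, with a warning). The hidden layer is sized by
#' [hidden_nodes()]; inputs are min-max normalized to \[0, 1\] with bounds
#' kept in the model.
#'
#' @param x numeric feature matrix (rows = samples), or a formula.
#' @param y factor (or vector coercible to factor) with exactly two
#'   levels; by convention `good`/`ng`.
#' @param cfg a [train_config()].
#' @param data data frame holding the formula variables.
#' @param ... passed between methods.
#' @return an object of class `"bpnn"`: layer sizes, weight matrices `W1`
#'   (hidden x input) and `W2` (output x hidden), biases `b1`, `b2`,
#'   normalization `bounds`, class `levels`, `final_mse`, `mse_history`,
#'   `epochs`, `converged`, and the configuration.
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(60, 0.2, 0.05), ncol = 2),
#'            matrix(rnorm(60, 0.8, 0.05), ncol = 2))
#' y <- rep(c("good", "ng"), each = 30)
#' fit <- bpnn(x, y, cfg = train_config(max_epochs = 2000))
#' table(predict(fit, x)$label, y)
#' @export
bpnn <- function(x, ...) UseMethod("bpnn")

#' @rdname bpnn
#' @export
bpnn.formula <- function(x, data, cfg = train_config(), ...) {
  mf <- stats::model.frame(x, data)
  y <- stats::model.response(mf)
  xm <- stats::model.matrix(attr(mf, "terms"), mf)
  xm <- xm[, colnames(xm) != "(Intercept)", drop = FALSE]
  bpnn.default(xm, y, cfg = cfg, ...)
}

#' @rdname bpnn
#' @export
bpnn.default <- function(x, y, cfg = train_config(), ...) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (anyNA(x)) stop("NaN/NA in training inputs")
  y <- factor(y)
  if (nlevels(y) != 2L) stop("y must have exactly two classes")
  if (any(table(y) < 1L)) stop("each class needs at least one sample")
  if (length(y) != nrow(x)) stop("x/y length mismatch")

  bounds <- normalize_fit(x)
  xn <- normalize_apply(bounds, x)
  targets <- cbind(as.numeric(y == levels(y)[1]),
                   as.numeric(y == levels(y)[2]))
  ni <- ncol(x); no <- 2L
  nh <- hidden_nodes(ni, no)
  fit <- bpnn_train_cpp(xn, targets, nh, cfg$learning_rate,
                        cfg$mse_tolerance, cfg$max_epochs,
                        as.double(cfg$rng_seed))
  if (!fit$converged)
    warning(sprintf("bpnn did not reach MSE < %g in %d epochs (final MSE %.4g)",
                    cfg$mse_tolerance, cfg$max_epochs, fit$final_mse))
  structure(list(
    n_input = ni, n_hidden = nh, n_output = no,
    W1 = fit$W1, b1 = fit$b1, W2 = fit$W2, b2 = fit$b2,
    bounds = bounds, levels = levels(y),
    feature_names = colnames(x),
    final_mse = fit$final_mse, mse_history = fit$mse_history,
    epochs = fit$epochs, converged = fit$converged,
    cfg = cfg
  ), class = "bpnn")
}

# forward pass on normalized inputs (reference R implementation)
.bpnn_forward <- function(model, xn) {
  h <- 1 / (1 + exp(-(xn %*% t(model$W1) + rep(model$b1, each = nrow(xn)))))
  o <- 1 / (1 + exp(-(h %*% t(model$W2) + rep(model$b2, each = nrow(h)))))
  o
}

#' Predict seed grades from a fitted network
#'
#' Applies the stored normalization bounds (clipping to \[0, 1\]), runs the
#' forward pass, and labels each row by the larger of the two output
#' activations. Exact ties go to the second class level (the reject class
#' `ng` under the conventional `good`/`ng` coding).
#'
#' @param object a fitted `"bpnn"`.
#' @param newdata matrix or data frame with `object$n_input` feature
#'   columns (matched by name when available).
#' @param ... unused.
#' @return list with `label` (factor) and `outputs` (n x 2 activation
#'   matrix, columns named by class).
#' @export
predict.bpnn <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (!is.null(colnames(x)) && all(object$feature_names %in% colnames(x)))
    x <- x[, object$feature_names, drop = FALSE]
  if (ncol(x) != object$n_input)
    stop(sprintf("expected %d input features, got %d", object$n_input, ncol(x)))
  o <- .bpnn_forward(object, normalize_apply(object$bounds, x))
  colnames(o) <- object$levels
  lab <- ifelse(o[, 1] > o[, 2], object$levels[1], object$levels[2])
  list(label = factor(lab, levels = object$levels), outputs = o)
}

#' @export
print.bpnn <- function(x, ...) {
  cat(sprintf("Back-propagation network: %d-%d-%d (input-hidden-output)\n",
              x$n_input, x$n_hidden, x$n_output))
  cat(sprintf("Classes: %s | trained %d epochs, final MSE %.4g%s\n",
              paste(x$levels, collapse = "/"), x$epochs, x$final_mse,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' @export
summary.bpnn <- function(object, ...) {
  res <- list(sizes = c(input = object$n_input, hidden = object$n_hidden,
                        output = object$n_output),
              n_weights = length(object$W1) + length(object$b1) +
                length(object$W2) + length(object$b2),
              epochs = object$epochs, final_mse = object$final_mse,
              converged = object$converged, cfg = object$cfg,
              levels = object$levels)
  class(res) <- "summary.bpnn"
  res
}

#' @export
print.summary.bpnn <- function(x, ...) {
  cat(sprintf("bpnn %d-%d-%d, %d free parameters\n",
              x$sizes[1], x$sizes[2], x$sizes[3], x$n_weights))
  cat(sprintf("learning rate %g, MSE tolerance %g, seed %d\n",
              x$cfg$learning_rate, x$cfg$mse_tolerance, x$cfg$rng_seed))
  cat(sprintf("%d epochs, final MSE %.4g, converged: %s\n",
              x$epochs, x$final_mse, x$converged))
  invisible(x)
}

#' @export
coef.bpnn <- function(object, ...) {
  list(W1 = object$W1, b1 = object$b1, W2 = object$W2, b2 = object$b2)
}

#' @export
plot.bpnn <- function(x, ...) {
  graphics::plot(seq_along(x$mse_history), x$mse_history, type = "l",
                 xlab = "epoch", ylab = "mean squared error",
                 main = "BPNN training error", log = "y", ...)
  graphics::abline(h = x$cfg$mse_tolerance, lty = 2)
  invisible(x)
}

#' Combine the two per-aspect network decisions (AND rule)
#'
#' A seed is graded good only when the shape network and the color-texture
#' network both grade it good; any other combination is the reject class.
#'
#' @param shape_label,colortex_label vectors of `"good"`/`"ng"` labels.
#' @return character vector of combined labels.
#' @export
combine_labels <- function(shape_label, colortex_label) {
  ifelse(as.character(shape_label) == "good" &
           as.character(colortex_label) == "good", "good", "ng")
}

#' Serialize / restore a fitted network as JSON
#'
#' @param model a `"bpnn"` object.
#' @param path output (input) JSON path.
#' @return `path` invisibly; `read_bpnn` returns the restored model.
#' @export
write_bpnn <- function(model, path) {
  obj <- unclass(model)
  obj$cfg <- unclass(obj$cfg)
  obj$W1 <- as.list(as.data.frame(obj$W1))
  obj$W2 <- as.list(as.data.frame(obj$W2))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_bpnn
#' @export
read_bpnn <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$W1 <- as.matrix(as.data.frame(obj$W1))
  obj$W2 <- as.matrix(as.data.frame(obj$W2))
  dimnames(obj$W1) <- dimnames(obj$W2) <- NULL
  obj$bounds <- list(min = unlist(obj$bounds$min), max = unlist(obj$bounds$max))
  obj$cfg <- structure(obj$cfg, class = "train_config")
  structure(obj, class = "bpnn")
}

# ---- reference loss/gradient (used by the finite-difference check) ------

# pack/unpack a parameter vector for a (ni, nh, no) network
.bpnn_unpack <- function(par, ni, nh, no) {
  i <- 0L
  W1 <- matrix(par[i + seq_len(nh * ni)], nh, ni); i <- i + nh * ni
  b1 <- par[i + seq_len(nh)]; i <- i + nh
  W2 <- matrix(par[i + seq_len(no * nh)], no, nh); i <- i + no * nh
  b2 <- par[i + seq_len(no)]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

# batch MSE loss: mean over samples and output units of squared error
bpnn_loss <- function(par, x, targets, ni, nh, no) {
  w <- .bpnn_unpack(par, ni, nh, no)
  h <- 1 / (1 + exp(-(x %*% t(w$W1) + rep(w$b1, each = nrow(x)))))
  o <- 1 / (1 + exp(-(h %*% t(w$W2) + rep(w$b2, each = nrow(h)))))
  mean((o - targets)^2)
}

# analytic gradient of bpnn_loss by back-propagation
bpnn_gradient <- function(par, x, targets, ni, nh, no) {
  w <- .bpnn_unpack(par, ni, nh, no)
  n <- nrow(x)
  h <- 1 / (1 + exp(-(x %*% t(w$W1) + rep(w$b1, each = n))))
  o <- 1 / (1 + exp(-(h %*% t(w$W2) + rep(w$b2, each = n))))
  dout <- (2 / (n * no)) * (o - targets) * o * (1 - o)   # n x no
  dW2 <- t(dout) %*% h
  db2 <- colSums(dout)
  dhid <- (dout %*% w$W2) * h * (1 - h)                  # n x nh
  dW1 <- t(dhid) %*% x
  db1 <- colSums(dhid)
  c(as.vector(dW1), db1, as.vector(dW2), db2)
}
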