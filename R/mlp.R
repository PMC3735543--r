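# The 4-3-1 perceptron: initialization, forward pass, analytic gradient and
# full-batch back-propagation training.  The numeric kernels live in
# src/mlp.cpp; parameters travel as the 19-vector c(W1 col-major, b1, w2, b2).

#' Training hyperparameters
#'
#' @param learningRate initial gradient-descent step size.
#' @param maxEpochs maximum number of full-batch epochs.
#' @param stopThreshold convergence criterion: training stops when the
#'   largest absolute component of the error gradient falls below this.
#' @param initRange half-width of the uniform initialization interval.
#' @return a named list of hyperparameters.
#' @export
trainConfig <- function(learningRate = 0.05, maxEpochs = 100000L,
                        stopThreshold = 0.01, initRange = 0.5) {
  stopifnot(learningRate > 0, maxEpochs >= 1, stopThreshold > 0,
            initRange > 0)
  list(learningRate = learningRate, maxEpochs = as.integer(maxEpochs),
       stopThreshold = stopThreshold, initRange = initRange)
}

#' Randomly initialize a perceptron
#'
#' All 19 parameters are drawn independently from the uniform distribution on
#' `(-initRange, +initRange)`.  The same seed always yields the identical
#' model; the caller's RNG state is left untouched.
#'
#' @param seed integer seed.
#' @param initRange half-width of the uniform interval (> 0).
#' @return an [MlpModel-class].
#' @export
initMlp <- function(seed, initRange = 0.5) {
  stopifnot(initRange > 0)
  par <- withSeed(seed, runif(19, -initRange, initRange))
  parToMlp(par)
}

# Coerce network input to an n x 4 matrix.
asInputMatrix <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != 4) stop("network input must have 4 columns")
  if (!all(is.finite(x))) stop("network input must be finite")
  storage.mode(x) <- "double"
  x
}

#' Forward pass
#'
#' Computes the predicted likelihood `y = sigma(w2 . sigma(W1 x + b1) + b2)`,
#' strictly inside (0, 1) for finite weights.
#'
#' @param model an [MlpModel-class].
#' @param x a length-4 input vector or an n x 4 matrix.
#' @return numeric vector of predicted likelihoods.
#' @export
mlpForward <- function(model, x) {
  cpp_mlp_forward(mlpToPar(model), asInputMatrix(x))
}

#' Analytic gradient of the training loss
#'
#' Back-propagated gradient of the sum-of-squared-errors loss
#' `E = sum_i (y_i - t_i)^2 / 2` with respect to all 19 parameters.
#'
#' @param model an [MlpModel-class].
#' @param x n x 4 input matrix.
#' @param target length-n vector of 0/1 targets.
#' @return list with `gradient` (19-vector, same packing as the parameters)
#'   and `error` (the loss at `model`).
#' @export
mlpGradient <- function(model, x, target) {
  x <- asInputMatrix(x)
  stopifnot(length(target) == nrow(x), all(is.finite(target)))
  cpp_mlp_gradient(mlpToPar(model), x, as.numeric(target))
}

#' Train a perceptron by full-batch back-propagation
#'
#' Gradient descent on the sum-of-squared-errors loss.  A step that would
#' increase the loss is rejected and the step size halved (so the loss is
#' non-increasing over accepted steps); accepted steps grow the step size
#' slightly.  Training stops when the largest absolute gradient component
#' drops below `config$stopThreshold` or after `config$maxEpochs` epochs.
#'
#' @param model an [MlpModel-class] (typically from [initMlp()]).
#' @param x n x 4 input matrix.
#' @param target length-n vector of 0/1 targets.
#' @param config hyperparameters from [trainConfig()].
#' @return list with `model` (trained [MlpModel-class]), `error` (final
#'   loss), `epochs` (epochs used) and `converged` (logical).
#' @examples
#' enc <- encodeInsertions(generateTrainingLike(synthConfig(seed = 1)))
#' fit <- trainMlp(initMlp(7), enc$x, enc$target, trainConfig())
#' fit$converged
#' @export
trainMlp <- function(model, x, target, config = trainConfig()) {
  x <- asInputMatrix(x)
  if (nrow(x) == 0) stop("training set is empty")
  stopifnot(length(target) == nrow(x), all(is.finite(target)))
  fit <- cpp_mlp_train(mlpToPar(model), x, as.numeric(target),
                       config$learningRate, config$maxEpochs,
                       config$stopThreshold)
  if (!is.finite(fit$error))
    stop("training diverged: non-finite loss after ", fit$epochs, " epochs")
  list(model = parToMlp(fit$par), error = fit$error, epochs = fit$epochs,
       converged = fit$converged)
}
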