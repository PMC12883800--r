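# Classifiers: random forest and RBF support vector machine baselines, a
# two-hidden-layer backpropagation network (ReLU, softmax, full-batch Adam),
# and the particle-swarm-optimized BPNN in which PSO first searches the
# hidden-layer sizes and learning rate and then the initial weight vector.

.fitScaler <- function(X) {
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  list(center = center, scale = scale)
}

.applyScaler <- function(X, scaler) {
  sweep(sweep(X, 2, scaler$center, "-"), 2, scaler$scale, "/")
}

.checkFeatures <- function(features, featureNames) {
  X <- as.matrix(features)
  miss <- setdiff(featureNames, colnames(X))
  if (length(miss))
    stop("missing feature column(s): ", paste(miss, collapse = ", "))
  X[, featureNames, drop = FALSE]
}

.presentClasses <- function(labels) {
  cls <- vegClasses()
  present <- intersect(cls, unique(labels))
  extra <- setdiff(unique(labels), cls)
  c(present, sort(extra))
}

#' Train a baseline classifier (random forest or SVM)
#'
#' RF: 50 trees, maximum depth 8, seeded (default 42). SVM: RBF kernel,
#' C = 100, adaptive kernel coefficient gamma = 1/(d * var(X)) computed on
#' the standardized features, probability outputs. Features are standardized
#' before fitting for both kinds (harmless for RF, required for SVM).
#'
#' @param kind "RF" or "SVM".
#' @param features matrix or data.frame of numeric features.
#' @param labels class labels; at least two classes required.
#' @param seed RNG seed (default 42).
#' @return A [TrainedClassifier-class] subclass.
#' @export
trainBaseline <- function(kind = c("RF", "SVM"), features, labels, seed = 42L) {
  kind <- match.arg(kind)
  X <- as.matrix(features)
  if (length(unique(labels)) < 2L) stop("single-class input: need >= 2 classes")
  classOrder <- .presentClasses(labels)
  y <- factor(labels, levels = classOrder)
  scaler <- .fitScaler(X)
  Xs <- .applyScaler(X, scaler)
  if (kind == "RF") {
    fit <- ranger::ranger(x = as.data.frame(Xs), y = y, num.trees = 50L,
                          max.depth = 8L, probability = TRUE,
                          seed = seed, num.threads = 1L)
    new("RFClassifier", kind = "RF", classOrder = classOrder,
        scaler = scaler, featureNames = colnames(X), fit = fit)
  } else {
    set.seed(seed)
    gamma <- 1 / (ncol(Xs) * max(stats::var(as.vector(Xs)), 1e-12))
    fit <- e1071::svm(x = Xs, y = y, kernel = "radial", cost = 100,
                      gamma = gamma, probability = TRUE, scale = FALSE)
    new("SVMClassifier", kind = "SVM", classOrder = classOrder,
        scaler = scaler, featureNames = colnames(X), fit = fit)
  }
}

# ---- two-hidden-layer MLP with full-batch Adam ----

.mlpInit <- function(d, h1, h2, K, seed, initScale = NULL) {
  set.seed(seed)
  he <- function(fin, fout) {
    s <- if (is.null(initScale)) sqrt(2 / fin) else initScale
    matrix(stats::rnorm(fin * fout, 0, s), fin, fout)
  }
  list(W1 = he(d, h1), b1 = rep(0, h1),
       W2 = he(h1, h2), b2 = rep(0, h2),
       W3 = he(h2, K), b3 = rep(0, K),
       dims = c(d = d, h1 = h1, h2 = h2, K = K))
}

.mlpFlatten <- function(net) {
  c(as.vector(net$W1), net$b1, as.vector(net$W2), net$b2,
    as.vector(net$W3), net$b3)
}

.mlpUnflatten <- function(theta, dims) {
  d <- dims["d"]; h1 <- dims["h1"]; h2 <- dims["h2"]; K <- dims["K"]
  i <- 0L
  take <- function(n) { v <- theta[(i + 1L):(i + n)]; i <<- i + n; v }
  list(W1 = matrix(take(d * h1), d, h1), b1 = take(h1),
       W2 = matrix(take(h1 * h2), h1, h2), b2 = take(h2),
       W3 = matrix(take(h2 * K), h2, K), b3 = take(K),
       dims = dims)
}

.mlpForward <- function(net, X) {
  Z1 <- sweep(X %*% net$W1, 2, net$b1, "+"); A1 <- pmax(Z1, 0)
  Z2 <- sweep(A1 %*% net$W2, 2, net$b2, "+"); A2 <- pmax(Z2, 0)
  Z3 <- sweep(A2 %*% net$W3, 2, net$b3, "+")
  Z3 <- Z3 - apply(Z3, 1, max)
  E <- exp(Z3)
  P <- E / rowSums(E)
  list(P = P, A1 = A1, A2 = A2)
}

.mlpLoss <- function(P, Y) -mean(log(pmax(rowSums(P * Y), 1e-300)))

.mlpTrain <- function(net, X, Y, lr, epochs) {
  n <- nrow(X)
  loss <- numeric(epochs)
  if (epochs == 0L) return(list(net = net, loss = loss))
  adam <- lapply(c("W1", "b1", "W2", "b2", "W3", "b3"), function(nm)
    list(m = net[[nm]] * 0, v = net[[nm]] * 0))
  names(adam) <- c("W1", "b1", "W2", "b2", "W3", "b3")
  b1a <- 0.9; b2a <- 0.999; eps <- 1e-8
  for (t in seq_len(epochs)) {
    fw <- .mlpForward(net, X)
    loss[t] <- .mlpLoss(fw$P, Y)
    if (!is.finite(loss[t]))
      stop("non-finite training loss at epoch ", t,
           " (learning rate ", lr, ")")
    G3 <- (fw$P - Y) / n
    gW3 <- t(fw$A2) %*% G3; gb3 <- colSums(G3)
    G2 <- (G3 %*% t(net$W3)) * (fw$A2 > 0)
    gW2 <- t(fw$A1) %*% G2; gb2 <- colSums(G2)
    G1 <- (G2 %*% t(net$W2)) * (fw$A1 > 0)
    gW1 <- t(X) %*% G1; gb1 <- colSums(G1)
    grads <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2, W3 = gW3, b3 = gb3)
    for (nm in names(grads)) {
      adam[[nm]]$m <- b1a * adam[[nm]]$m + (1 - b1a) * grads[[nm]]
      adam[[nm]]$v <- b2a * adam[[nm]]$v + (1 - b2a) * grads[[nm]]^2
      mhat <- adam[[nm]]$m / (1 - b1a^t)
      vhat <- adam[[nm]]$v / (1 - b2a^t)
      net[[nm]] <- net[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(net = net, loss = loss)
}

.oneHot <- function(labels, classOrder) {
  Y <- matrix(0, length(labels), length(classOrder))
  Y[cbind(seq_along(labels), match(labels, classOrder))] <- 1
  Y
}

#' Train a backpropagation neural network
#'
#' Feedforward network with two ReLU hidden layers and a softmax output,
#' trained with full-batch Adam on cross-entropy. Deterministic under the
#' seed; the per-epoch loss trajectory is stored on the returned object.
#'
#' @param features matrix/data.frame of numeric features.
#' @param labels class labels.
#' @param hidden two positive integers, hidden layer sizes (default 50, 50).
#' @param learningRate Adam step size (default 0.01).
#' @param epochs training epochs (default 300). `epochs = 0` returns the
#'   randomly initialized network unchanged.
#' @param seed RNG seed for the weight initialization.
#' @param initTheta optional flat numeric vector of initial weights (used by
#'   the PSO-initialized variant).
#' @param kind classifier tag stored on the object (default "BPNN").
#' @return A [TrainedClassifier-class] (`BPNNClassifier`), with slots
#'   `lossTrace` and `spec`.
#' @export
trainBpnn <- function(features, labels, hidden = c(50L, 50L),
                      learningRate = 0.01, epochs = 300L, seed = 1L,
                      initTheta = NULL, kind = "BPNN") {
  X <- as.matrix(features)
  if (length(unique(labels)) < 2L) stop("single-class input: need >= 2 classes")
  stopifnot(length(hidden) == 2L, all(hidden >= 1L), epochs >= 0L,
            learningRate > 0)
  classOrder <- .presentClasses(labels)
  scaler <- .fitScaler(X)
  Xs <- .applyScaler(X, scaler)
  K <- length(classOrder)
  net <- .mlpInit(ncol(Xs), hidden[1], hidden[2], K, seed)
  if (!is.null(initTheta)) net <- .mlpUnflatten(initTheta, net$dims)
  Y <- .oneHot(labels, classOrder)
  fit <- .mlpTrain(net, Xs, Y, learningRate, as.integer(epochs))
  new("BPNNClassifier", kind = kind, classOrder = classOrder,
      scaler = scaler, featureNames = colnames(X), net = fit$net,
      lossTrace = fit$loss,
      spec = list(hidden = hidden, learningRate = learningRate,
                  epochs = epochs, seed = seed))
}

#' PSO configuration
#'
#' @param swarmSize number of particles (default 50).
#' @param iterations number of generations (default 100).
#' @param c1,c2 cognitive and social learning factors (default 1.5 each).
#' @param wStart,wEnd inertia weight, linearly decreased from `wStart` (0.9)
#'   to `wEnd` (0.4) over the iterations.
#' @param velocityClamp maximum |velocity| as a fraction of each dimension's
#'   range (default 0.2).
#' @param seed RNG seed.
#' @return list of class `PSOConfig`.
#' @export
psoConfig <- function(swarmSize = 50L, iterations = 100L, c1 = 1.5, c2 = 1.5,
                      wStart = 0.9, wEnd = 0.4, velocityClamp = 0.2,
                      seed = 1L) {
  stopifnot(swarmSize >= 2L, iterations >= 0L, wStart >= wEnd,
            velocityClamp > 0)
  structure(list(swarmSize = as.integer(swarmSize),
                 iterations = as.integer(iterations), c1 = c1, c2 = c2,
                 wStart = wStart, wEnd = wEnd,
                 velocityClamp = velocityClamp, seed = as.integer(seed)),
            class = "PSOConfig")
}

#' Particle swarm minimization
#'
#' Canonical inertia-weight PSO: v <- w v + c1 r1 (pbest - x) +
#' c2 r2 (gbest - x), x <- x + v, with per-dimension uniform r1, r2,
#' linearly decaying inertia, velocity clamping and position clipping to the
#' bounds. Non-finite fitness values are penalized with +Inf and the run
#' continues. The global best is monotonically nonincreasing by
#' construction; with `iterations = 0` the best of the random initial swarm
#' is returned.
#'
#' @param fitness function mapping a position vector to a scalar to minimize.
#' @param lower,upper numeric bounds per dimension.
#' @param config a [psoConfig()].
#' @param init optional matrix of initial positions (rows), recycled into the
#'   swarm before random initialization fills the rest.
#' @return list(position, value, trajectory) where `trajectory[k]` is the
#'   global best after k-1 iterations (length iterations + 1).
#' @export
psoMinimize <- function(fitness, lower, upper, config = psoConfig(),
                        init = NULL) {
  stopifnot(length(lower) == length(upper), all(lower <= upper))
  d <- length(lower)  # dimensions with lower == upper are pinned
  S <- config$swarmSize
  set.seed(config$seed)
  range <- upper - lower
  X <- matrix(stats::runif(S * d), S, d)
  X <- sweep(sweep(X, 2, range, "*"), 2, lower, "+")
  if (!is.null(init)) {
    init <- matrix(init, ncol = d)
    k <- min(nrow(init), S)
    X[seq_len(k), ] <- init[seq_len(k), , drop = FALSE]
  }
  vmax <- config$velocityClamp * range
  V <- matrix(stats::runif(S * d, -1, 1), S, d) %*% diag(vmax, d, d)
  evalFit <- function(x) {
    v <- suppressWarnings(fitness(x))
    if (!is.finite(v)) Inf else v
  }
  pbestX <- X
  pbestF <- apply(X, 1, evalFit)
  g <- which.min(pbestF)
  gbestX <- X[g, ]; gbestF <- pbestF[g]
  traj <- numeric(config$iterations + 1L)
  traj[1] <- gbestF
  if (config$iterations > 0) {
    for (t in seq_len(config$iterations)) {
      w <- if (config$iterations == 1L) config$wStart
           else config$wStart - (config$wStart - config$wEnd) *
                  (t - 1) / (config$iterations - 1)
      r1 <- matrix(stats::runif(S * d), S, d)
      r2 <- matrix(stats::runif(S * d), S, d)
      V <- w * V + config$c1 * r1 * (pbestX - X) +
        config$c2 * r2 * sweep(-X, 2, gbestX, "+")
      V <- pmin(pmax(V, matrix(-vmax, S, d, byrow = TRUE)),
                matrix(vmax, S, d, byrow = TRUE))
      X <- X + V
      X <- pmin(pmax(X, matrix(lower, S, d, byrow = TRUE)),
                matrix(upper, S, d, byrow = TRUE))
      f <- apply(X, 1, evalFit)
      better <- f < pbestF
      pbestX[better, ] <- X[better, , drop = FALSE]
      pbestF[better] <- f[better]
      g <- which.min(pbestF)
      if (pbestF[g] < gbestF) { gbestF <- pbestF[g]; gbestX <- pbestX[g, ] }
      traj[t + 1L] <- gbestF
    }
  }
  list(position = gbestX, value = gbestF, trajectory = traj)
}

#' Train the PSO-optimized BPNN
#'
#' Two-stage hybrid. Stage 1: PSO over (hidden1, hidden2, learning rate)
#' within `archBounds`; the fitness of a candidate architecture is the
#' validation cross-entropy after a short proxy training on an internal
#' stratified 80/20 split of the training data; hidden sizes are rounded to
#' integers. Stage 2 (optional): PSO over the initial weight vector of the
#' stage-1 architecture within +/- `weightBound`, same proxy fitness, with
#' one particle seeded at the standard random initialization. Finally the
#' network is trained in full (Adam, `finalEpochs`) from the stage-2 best
#' initialization.
#'
#' @param features,labels training data.
#' @param psoStage1,psoStage2 [psoConfig()]s for the two stages.
#' @param archBounds list(hidden = c(16, 128), lr = c(0.001, 0.1)).
#' @param proxyEpochs epochs of the proxy training inside the PSO fitness
#'   (default 30).
#' @param finalEpochs epochs of the final full training (default 300).
#' @param stage2 set FALSE to skip the initial-weight optimization.
#' @param weightBound half-width of the stage-2 search box (default 0.5).
#' @param valFraction internal validation fraction (default 0.2).
#' @param seed seed for the internal split and trainings.
#' @return A `BPNNClassifier` with kind "PSO-BPNN"; `spec` records the chosen
#'   architecture, learning rate and both PSO trajectories.
#' @export
trainPsoBpnn <- function(features, labels,
                         psoStage1 = psoConfig(),
                         psoStage2 = psoConfig(),
                         archBounds = list(hidden = c(16, 128),
                                           lr = c(0.001, 0.1)),
                         proxyEpochs = 30L, finalEpochs = 300L,
                         stage2 = TRUE, weightBound = 0.5,
                         valFraction = 0.2, seed = 1L) {
  X <- as.matrix(features)
  if (length(unique(labels)) < 2L) stop("single-class input: need >= 2 classes")
  classOrder <- .presentClasses(labels)
  scaler <- .fitScaler(X)
  Xs <- .applyScaler(X, scaler)
  Y <- .oneHot(labels, classOrder)
  K <- length(classOrder)
  sp <- trainTestSplit(labels, trainFraction = 1 - valFraction, seed = seed)
  tr <- sp$train; va <- sp$test
  proxyFit <- function(net, lr) {
    fit <- tryCatch(.mlpTrain(net, Xs[tr, , drop = FALSE],
                              Y[tr, , drop = FALSE], lr,
                              as.integer(proxyEpochs)),
                    error = function(e) NULL)
    if (is.null(fit)) return(list(val = Inf, net = NULL))
    P <- .mlpForward(fit$net, Xs[va, , drop = FALSE])$P
    list(val = .mlpLoss(P, Y[va, , drop = FALSE]), net = fit$net)
  }
  fit1 <- function(pos) {
    h1 <- as.integer(round(pos[1])); h2 <- as.integer(round(pos[2]))
    net <- .mlpInit(ncol(Xs), h1, h2, K, seed)
    proxyFit(net, pos[3])$val
  }
  lowerA <- c(archBounds$hidden[1], archBounds$hidden[1], archBounds$lr[1])
  upperA <- c(archBounds$hidden[2], archBounds$hidden[2], archBounds$lr[2])
  s1 <- psoMinimize(fit1, lowerA, upperA, psoStage1)
  h1 <- as.integer(round(s1$position[1]))
  h2 <- as.integer(round(s1$position[2]))
  lr <- s1$position[3]
  net0 <- .mlpInit(ncol(Xs), h1, h2, K, seed)
  theta0 <- .mlpFlatten(net0)
  s2 <- NULL
  if (isTRUE(stage2)) {
    dims <- net0$dims
    fit2 <- function(theta) proxyFit(.mlpUnflatten(theta, dims), lr)$val
    nW <- length(theta0)
    s2 <- psoMinimize(fit2, rep(-weightBound, nW), rep(weightBound, nW),
                      psoStage2,
                      init = matrix(pmin(pmax(theta0, -weightBound),
                                         weightBound), 1))
    theta0 <- s2$position
  }
  model <- trainBpnn(X, labels, hidden = c(h1, h2), learningRate = lr,
                     epochs = finalEpochs, seed = seed, initTheta = theta0,
                     kind = "PSO-BPNN")
  model@spec <- c(model@spec,
                  list(stage1 = list(position = s1$position,
                                     value = s1$value,
                                     trajectory = s1$trajectory),
                       stage2 = if (!is.null(s2))
                         list(value = s2$value,
                              trajectory = s2$trajectory)))
  model
}

#' Predict class labels and probabilities
#'
#' Features are matched by name to the training columns and standardized with
#' the stored scaler. The label is the argmax of the probability vector, with
#' ties broken toward the earlier class in the model's class order.
#'
#' @param model a [TrainedClassifier-class].
#' @param features matrix/data.frame including all training feature columns.
#' @return list(labels = character, probabilities = matrix with one column
#'   per class in class order; rows sum to 1).
#' @export
setGeneric("predictClasses", function(model, features)
  standardGeneric("predictClasses"))

.finishPrediction <- function(P, classOrder) {
  P <- P[, classOrder, drop = FALSE]
  P <- P / rowSums(P)
  k <- max.col(P, ties.method = "first")
  list(labels = classOrder[k], probabilities = P)
}

#' @rdname predictClasses
#' @export
setMethod("predictClasses", "RFClassifier", function(model, features) {
  X <- .applyScaler(.checkFeatures(features, model@featureNames), model@scaler)
  P <- stats::predict(model@fit, data = as.data.frame(X),
                      num.threads = 1L)$predictions
  .finishPrediction(P, model@classOrder)
})

#' @rdname predictClasses
#' @export
setMethod("predictClasses", "SVMClassifier", function(model, features) {
  X <- .applyScaler(.checkFeatures(features, model@featureNames), model@scaler)
  pred <- stats::predict(model@fit, newdata = X, probability = TRUE)
  P <- attr(pred, "probabilities")
  .finishPrediction(P, model@classOrder)
})

#' @rdname predictClasses
#' @export
setMethod("predictClasses", "BPNNClassifier", function(model, features) {
  X <- .applyScaler(.checkFeatures(features, model@featureNames), model@scaler)
  P <- .mlpForward(model@net, X)$P
  colnames(P) <- model@classOrder
  .finishPrediction(P, model@classOrder)
})
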