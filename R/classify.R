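#' @include classes.R
NULL

#' Generalized RBF kernel
#'
#' K(x, z) = exp(-||x - z||^tau / (2 sigma^tau)). With tau = 2 this is the
#' standard Gaussian RBF of bandwidth sigma; smaller tau gives heavier
#' tails (tau = 1 is the Laplacian kernel). The center parameter translates
#' both arguments before evaluation (operative through the explicit
#' centering in [trainSMSVM()]).
#'
#' @param x,z numeric vectors of equal length.
#' @param params a [grbfParams()].
#' @return Kernel value in (0, 1]; K(x, x) = 1.
#' @examples
#' grbfKernel(0, 1, grbfParams(sigma = 1, tau = 1))  # exp(-0.5)
#' @export
grbfKernel <- function(x, z, params = grbfParams()) {
  if (length(x) != length(z)) stop("x and z must have equal dimension")
  xc <- x - params@center; zc <- z - params@center
  d <- sqrt(sum((xc - zc)^2))
  exp(-d^params@tau / (2 * params@sigma^params@tau))
}

#' Generalized-RBF Gram matrix between two feature sets
#'
#' @param X n x d feature matrix.
#' @param Z m x d feature matrix (defaults to X).
#' @param params a [grbfParams()].
#' @return n x m kernel matrix; symmetric with unit diagonal when Z = X.
#' @export
grbfKernelMatrix <- function(X, Z = X, params = grbfParams()) {
  X <- sweep(as.matrix(X), 2, rep_len(params@center, ncol(X)))
  Z <- sweep(as.matrix(Z), 2, rep_len(params@center, ncol(Z)))
  d2 <- outer(rowSums(X^2), rowSums(Z^2), "+") - 2 * tcrossprod(X, Z)
  # rounding can leave ~1e-13 where the true distance is 0; for tau < 2 the
  # tau-th root would inflate that to a visible diagonal deficit
  d2[d2 < 1e-12] <- 0
  exp(-sqrt(d2)^params@tau / (2 * params@sigma^params@tau))
}

#' Train a soft-margin SVM with the generalized RBF kernel
#'
#' Solves the standard C-SVM dual on the precomputed GRBF Gram matrix. The
#' Gram matrix is checked for positive semidefiniteness first: a negative
#' eigenvalue beyond numerical noise means an invalid kernel configuration
#' (only possible for tau outside (0, 2], which [grbfParams()] already
#' rejects). Deterministic given inputs.
#'
#' @param features n x d numeric matrix (or data.frame of numerics).
#' @param labels length-n class labels (exactly two classes, >= 2 each).
#' @param C soft-margin regularization constant.
#' @param params a [grbfParams()].
#' @return An [SMSVMModel-class].
#' @export
trainSMSVM <- function(features, labels, C = 1, params = grbfParams()) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (length(lev) != 2L)
    stop("need exactly two classes, got: ", paste(lev, collapse = ", "))
  if (min(table(labels)) < 2L) stop("need >= 2 samples per class")
  K <- grbfKernelMatrix(features, features, params)
  minEig <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  if (minEig < -1e-8)
    stop(sprintf("Gram matrix indefinite (min eigenvalue %.3g); use tau <= 2",
                 minEig))
  y <- factor(labels, levels = lev)
  fit <- kernlab::ksvm(kernlab::as.kernelMatrix(K), y, type = "C-svc",
                       C = C, prob.model = FALSE)
  new("SMSVMModel", svm = fit, trainFeatures = features, levels = lev,
      cost = C, params = params)
}

#' Decision values and class predictions of a trained SMSVM
#'
#' @param model an [SMSVMModel-class].
#' @param newdata m x d feature matrix.
#' @param type "response" for class labels, "decision" for the signed
#'   decision values.
#' @return Character vector of labels, or numeric decision values.
#' @export
predictSMSVM <- function(model, newdata, type = c("response", "decision")) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  Ktest <- grbfKernelMatrix(newdata, model@trainFeatures, model@params)
  Ksub <- kernlab::as.kernelMatrix(
    Ktest[, kernlab::SVindex(model@svm), drop = FALSE])
  if (type == "decision")
    as.numeric(kernlab::predict(model@svm, Ksub, type = "decision"))
  else
    as.character(kernlab::predict(model@svm, Ksub))
}

#' Stratified random 70/25/5 split
#'
#' Partitions the rows into training (70%), test (25%) and validation (5%)
#' sets, stratified by label with largest-remainder rounding inside each
#' class; the three parts are disjoint and exhaustive, and reproducible
#' from the seed. The validation part is deliberately held out of all model
#' selection.
#'
#' @param labels per-row class labels (>= 20 rows, >= 3 per class).
#' @param seed RNG seed.
#' @param proportions length-3 numeric summing to 1.
#' @return list with integer index vectors `train`, `test`, `validation`.
#' @export
splitTrainTestVal <- function(labels, seed = NULL,
                              proportions = c(0.70, 0.25, 0.05)) {
  labels <- as.character(labels)
  n <- length(labels)
  if (n < 20L) stop("need >= 20 rows to split 70/25/5")
  if (min(table(labels)) < 3L) stop("every class needs >= 3 rows")
  stopifnot(abs(sum(proportions) - 1) < 1e-9)
  withSeed(seed, function() {
    # global part sizes by largest remainder, then per-class allocation that
    # respects the global targets (so 100 rows split exactly 70/25/5)
    gExact <- proportions * n
    gSizes <- floor(gExact)
    gRem <- n - sum(gSizes)
    if (gRem > 0) {
      give <- order(gExact - gSizes, decreasing = TRUE)[seq_len(gRem)]
      gSizes[give] <- gSizes[give] + 1L
    }
    deficit <- gSizes
    out <- list(train = integer(0), test = integer(0), validation = integer(0))
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      m <- length(idx)
      exact <- proportions * m
      sizes <- pmin(floor(exact), deficit)
      rem <- m - sum(sizes)
      while (rem > 0) {
        open <- which(deficit - sizes > 0)
        give <- open[order((exact - sizes)[open], decreasing = TRUE)][1L]
        sizes[give] <- sizes[give] + 1L
        rem <- rem - 1L
      }
      deficit <- deficit - sizes
      out$train <- c(out$train, idx[seq_len(sizes[1])])
      out$test <- c(out$test, idx[sizes[1] + seq_len(sizes[2])])
      out$validation <- c(out$validation,
                          idx[sizes[1] + sizes[2] + seq_len(sizes[3])])
    }
    lapply(out, sort)
  })
}

#' Paired t test between two matched feature arrays
#'
#' Classical two-sided paired t test on the differences, used to screen
#' whether a feature separates the two classes before classification.
#'
#' @param a,b equal-length numeric vectors (matched pairs, n >= 2).
#' @return list with elements `statistic` and `p.value`.
#' @export
pairedFeatureTTest <- function(a, b) {
  if (length(a) != length(b)) stop("paired arrays must have equal length")
  if (length(a) < 2L) stop("need n >= 2 pairs")
  d <- a - b
  if (sd(d) == 0)
    stop("zero-variance differences: paired t test undefined")
  ht <- t.test(a, b, paired = TRUE)
  list(statistic = unname(ht$statistic), p.value = ht$p.value)
}

# Deterministic stratified k folds (1-based fold id per row).
stratifiedFolds <- function(labels, k) {
  folds <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Stratified k-fold cross-validated accuracy of the SMSVM
#'
#' @param features n x d feature matrix.
#' @param labels per-row class labels.
#' @param k number of folds (>= 2).
#' @param C regularization constant.
#' @param params a [grbfParams()].
#' @param seed RNG seed (fold assignment).
#' @return Mean held-out accuracy in [0, 1].
#' @export
crossValidatedAccuracy <- function(features, labels, k = 5L, C = 1,
                                   params = grbfParams(), seed = NULL) {
  features <- as.matrix(features); labels <- as.character(labels)
  if (k < 2L) stop("k must be >= 2")
  withSeed(seed, function() {
    folds <- stratifiedFolds(labels, k)
    accs <- vapply(seq_len(k), function(f) {
      tr <- folds != f; te <- !tr
      if (length(unique(labels[tr])) < 2L || !any(te))
        stop("degenerate fold: a fold lost one of the classes")
      model <- trainSMSVM(features[tr, , drop = FALSE], labels[tr], C, params)
      mean(predictSMSVM(model, features[te, , drop = FALSE]) == labels[te])
    }, numeric(1))
    mean(accs)
  })
}

#' Median-heuristic kernel width
#'
#' The median pairwise Euclidean distance between feature rows, a standard
#' default for RBF bandwidths.
#'
#' @param features n x d feature matrix.
#' @return Positive scalar.
#' @export
medianHeuristicSigma <- function(features) {
  features <- as.matrix(features)
  d <- dist(features)
  m <- median(d[d > 0])
  if (!is.finite(m) || m <= 0) 1 else m
}
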