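#' Polynomial kernel parameters
#'
#' The kernel is `K(u, v) = (gamma * <u, v> + coef0)^degree`, the libsvm
#' polynomial convention (gamma multiplies the dot product; the tuned
#' gamma is only meaningful under this form). Defaults are the
#' grid-searched values for the glycation task: gamma = 0.03125,
#' coef0 = 0, degree = 3.
#'
#' @param gamma positive dot-product scale.
#' @param coef0 additive constant.
#' @param degree integer polynomial degree, >= 1.
#' @return list of class `KernelParams`.
#' @export
kernelParams <- function(gamma = 0.03125, coef0 = 0, degree = 3L) {
  degree <- as.integer(degree)
  if (gamma <= 0) stop("gamma must be positive")
  if (is.na(degree) || degree < 1L) stop("degree must be an integer >= 1")
  structure(list(gamma = gamma, coef0 = coef0, degree = degree),
            class = "KernelParams")
}

#' Evaluate the polynomial kernel
#'
#' @param u,v numeric vectors of equal length, or matrices with samples
#'   in rows (a Gram matrix is returned for matrix input).
#' @param params a [kernelParams()].
#' @return scalar for vector input; `nrow(u) x nrow(v)` matrix otherwise.
#' @export
polynomialKernel <- function(u, v, params = kernelParams()) {
  if (is.matrix(u) || is.matrix(v)) {
    if (!is.matrix(u)) u <- matrix(u, 1L)
    if (!is.matrix(v)) v <- matrix(v, 1L)
    if (ncol(u) != ncol(v)) stop("dimension mismatch in kernel")
    return((params$gamma * tcrossprod(u, v) + params$coef0)^params$degree)
  }
  if (length(u) != length(v)) stop("dimension mismatch in kernel")
  (params$gamma * sum(u * v) + params$coef0)^params$degree
}

#' Train a polynomial-kernel SVM on a labelled dataset
#'
#' Fits a soft-margin SVM (C-classification) with the polynomial kernel
#' via the libsvm solver (through e1071), then extracts support vectors,
#' dual coefficients and bias into a self-contained [PolySVM-class] whose
#' decision function is evaluated by [decisionValue()] without the
#' solver. A min-max scaler is fitted on the training data (unless one
#' is supplied, e.g. a fold-specific scaler inside cross-validation) and
#' stored with the model; positive decision values predict the glycated
#' class.
#'
#' @param dataset a [GlycDataset-class] containing both classes.
#' @param C soft-margin cost (default 512).
#' @param kernel a [kernelParams()].
#' @param scaler optional pre-fitted `ScalerParams`; fitted on
#'   `dataset` when `NULL`.
#' @param seed optional integer; libsvm C-classification is
#'   deterministic, the seed is set only so any future stochastic
#'   extension stays reproducible.
#' @return a [PolySVM-class].
#' @export
trainSVM <- function(dataset, C = 512, kernel = kernelParams(),
                     scaler = NULL, seed = NULL) {
  y <- dataset@y
  if (length(unique(y)) < 2L)
    stop("training requires both classes to be present")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(scaler)) scaler <- fitScaler(dataset@x)
  xs <- applyScaler(dataset@x, scaler)
  yf <- factor(ifelse(y == 1L, "pos", "neg"), levels = c("pos", "neg"))
  fit <- e1071::svm(x = xs, y = yf, scale = FALSE,
                    type = "C-classification", kernel = "polynomial",
                    degree = kernel$degree, gamma = kernel$gamma,
                    coef0 = kernel$coef0, cost = C)
  coefs <- as.numeric(fit$coefs)
  bias <- -fit$rho
  # libsvm signs decisions for whichever class it met first; make
  # positive decisions mean the glycated class.
  dv <- attr(predict(fit, xs[1, , drop = FALSE],
                     decision.values = TRUE),
             "decision.values")
  if (!identical(colnames(dv), "pos/neg")) {
    coefs <- -coefs
    bias <- -bias
  }
  sv <- as.matrix(fit$SV)
  dimnames(sv) <- NULL
  new("PolySVM", supportVectors = sv, dualCoefs = coefs, bias = bias,
      gamma = kernel$gamma, coef0 = kernel$coef0,
      degree = kernel$degree, cost = as.numeric(C),
      scalerMin = as.numeric(scaler$min),
      scalerMax = as.numeric(scaler$max))
}

#' SVM decision value(s)
#'
#' Evaluates `f(x) = sum_i alpha_i y_i K(x_i, x) + beta` with the model's
#' own support vectors and kernel parameters. Input is given on the raw
#' feature scale and passed through the model's stored scaler first
#' (pass `scaled = TRUE` for already-scaled input).
#'
#' @param model a [PolySVM-class].
#' @param x numeric vector, or matrix with samples in rows.
#' @param scaled set TRUE if `x` is already on the model's scaled scale.
#' @return numeric decision value(s); positive predicts glycated.
#' @export
decisionValue <- function(model, x, scaled = FALSE) {
  if (!is.matrix(x)) x <- matrix(x, 1L)
  if (ncol(x) != ncol(model@supportVectors))
    stop(sprintf("model expects %d features, got %d",
                 ncol(model@supportVectors), ncol(x)))
  if (!scaled)
    x <- applyScaler(x, structure(list(min = model@scalerMin,
                                       max = model@scalerMax),
                                  class = "ScalerParams"))
  K <- polynomialKernel(x, model@supportVectors,
                        kernelParams(model@gamma, model@coef0,
                                     model@degree))
  as.numeric(K %*% model@dualCoefs + model@bias)
}

#' Predict site labels from decision values
#'
#' Strictly positive decisions map to the glycated class (1); zero or
#' negative decisions to non-glycated (0). The zero -> 0 convention is
#' the conservative choice given the clinical cost of false-positive
#' glycation calls.
#'
#' @inheritParams decisionValue
#' @return integer labels in \{0, 1\}.
#' @export
predictLabel <- function(model, x, scaled = FALSE) {
  as.integer(decisionValue(model, x, scaled = scaled) > 0)
}

#' Grid search over (C, gamma)
#'
#' Evaluates mean stratified cross-validation performance for every grid
#' cell and returns the maximiser; ties are broken by smaller C, then
#' smaller gamma. Default grids follow the usual libsvm-guide
#' exponential ladder.
#'
#' @param dataset a two-class [GlycDataset-class].
#' @param Cgrid candidate costs (default `2^seq(-5, 15, 2)`).
#' @param gammaGrid candidate gammas (default `2^seq(-15, 3, 2)`).
#' @param kernel a [kernelParams()]; its gamma is overridden per cell.
#' @param cv a [cvConfig()] (default 5-fold, 1 repeat).
#' @param objective score to maximise, `"accuracy"` (default) or
#'   `"mcc"`.
#' @return list with `best` (named vector `C`, `gamma`), `score` and
#'   `table` (data.frame of all cells).
#' @export
gridSearch <- function(dataset, Cgrid = 2^seq(-5, 15, 2),
                       gammaGrid = 2^seq(-15, 3, 2),
                       kernel = kernelParams(),
                       cv = cvConfig(k = 5L, repeats = 1L, seed = 1L),
                       objective = c("accuracy", "mcc")) {
  objective <- match.arg(objective)
  if (!length(Cgrid) || !length(gammaGrid))
    stop("grids must be non-empty")
  cells <- expand.grid(C = sort(Cgrid), gamma = sort(gammaGrid),
                       KEEP.OUT.ATTRS = FALSE)
  score <- numeric(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    kp <- kernelParams(cells$gamma[i], kernel$coef0, kernel$degree)
    s <- runKFoldCV(dataset, C = cells$C[i], kernel = kp, cv = cv)
    m <- metricMeans(s)
    score[i] <- if (objective == "accuracy") m["Acc"] else m["MCC"]
  }
  cells$score <- score
  ord <- order(-cells$score, cells$C, cells$gamma)
  best <- cells[ord[1], ]
  list(best = c(C = best$C, gamma = best$gamma), score = best$score,
       table = cells)
}

#' Serialize a PolySVM model to a versioned text file
#'
#' Self-describing plain-text format holding kernel parameters, cost,
#' scaler, bias, dual coefficients and support vectors at full double
#' precision, so a round-trip through [readModel()] preserves every
#' decision value to machine precision.
#'
#' @param model a [PolySVM-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeModel <- function(model, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  num <- function(x) paste(sprintf("%.17g", x), collapse = " ")
  writeLines(c(
    "GlycSitePolySVM v1",
    sprintf("gamma %.17g", model@gamma),
    sprintf("coef0 %.17g", model@coef0),
    sprintf("degree %d", model@degree),
    sprintf("cost %.17g", model@cost),
    sprintf("bias %.17g", model@bias),
    sprintf("dim %d", ncol(model@supportVectors)),
    sprintf("nsv %d", nrow(model@supportVectors)),
    paste("scaler_min", num(model@scalerMin)),
    paste("scaler_max", num(model@scalerMax)),
    paste("dual_coefs", num(model@dualCoefs)),
    "support_vectors",
    vapply(seq_len(nrow(model@supportVectors)),
           function(i) num(model@supportVectors[i, ]), character(1))
  ), con)
  invisible(path)
}

#' Read a PolySVM model from its text serialization
#'
#' @param path file written by [writeModel()].
#' @return a [PolySVM-class].
#' @export
readModel <- function(path) {
  lines <- readLines(path)
  if (!identical(lines[1], "GlycSitePolySVM v1"))
    stop("unrecognised model file version: ", lines[1])
  field <- function(name) {
    ln <- lines[startsWith(lines, paste0(name, " "))][1]
    if (is.na(ln)) stop("model file missing field: ", name)
    as.numeric(strsplit(ln, " ", fixed = TRUE)[[1]][-1])
  }
  dim <- as.integer(field("dim"))
  nsv <- as.integer(field("nsv"))
  svStart <- which(lines == "support_vectors")[1]
  sv <- t(vapply(lines[svStart + seq_len(nsv)],
                 function(ln) as.numeric(strsplit(ln, " ",
                                                  fixed = TRUE)[[1]]),
                 numeric(dim)))
  dimnames(sv) <- NULL
  new("PolySVM", supportVectors = sv, dualCoefs = field("dual_coefs"),
      bias = field("bias"), gamma = field("gamma"),
      coef0 = field("coef0"), degree = as.integer(field("degree")),
      cost = field("cost"), scalerMin = field("scaler_min"),
      scalerMax = field("scaler_max"))
}
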