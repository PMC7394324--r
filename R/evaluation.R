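#' Tally a binary confusion table
#'
#' Label 1 is the positive (glycated) class.
#'
#' @param truth,predicted equal-length binary vectors.
#' @return named integer vector `TP, FP, TN, FN, N`.
#' @export
confusionCounts <- function(truth, predicted) {
  if (length(truth) != length(predicted) || length(truth) < 1L)
    stop("truth and predicted must be equal-length, non-empty")
  if (!all(truth %in% c(0, 1)) || !all(predicted %in% c(0, 1)))
    stop("labels must be binary (0/1)")
  tp <- sum(truth == 1 & predicted == 1)
  fp <- sum(truth == 0 & predicted == 1)
  tn <- sum(truth == 0 & predicted == 0)
  fn <- sum(truth == 1 & predicted == 0)
  c(TP = tp, FP = fp, TN = tn, FN = fn, N = tp + fp + tn + fn)
}

#' Sensitivity, specificity, accuracy and MCC from a confusion table
#'
#' Sn = TP/(TP+FN), Sp = TN/(TN+FP), Acc = (TP+TN)/N and
#' MCC = (TN*TP - FN*FP) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).
#' Any metric with a zero denominator is defined as 0.
#'
#' @param counts named vector from [confusionCounts()] (or any vector
#'   with TP, FP, TN, FN entries).
#' @return named numeric vector `Sn, Sp, Acc, MCC`.
#' @export
computeMetrics <- function(counts) {
  tp <- as.numeric(counts["TP"]); fp <- as.numeric(counts["FP"])
  tn <- as.numeric(counts["TN"]); fn <- as.numeric(counts["FN"])
  n <- tp + fp + tn + fn
  if (n < 1) stop("empty confusion table")
  safe <- function(num, den) if (den == 0) 0 else num / den
  mccDen <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  c(Sn = safe(tp, tp + fn),
    Sp = safe(tn, tn + fp),
    Acc = (tp + tn) / n,
    MCC = if (mccDen == 0) 0 else (tn * tp - fn * fp) / mccDen)
}

#' Area under the ROC curve
#'
#' Computed by the rank (Mann-Whitney) formulation: the probability that
#' a random positive scores above a random negative, ties counting half.
#' Equivalent to sweeping a threshold over the decision values.
#'
#' @param truth binary labels, both classes present.
#' @param scores numeric decision values, larger = more positive.
#' @return AUC in \[0, 1\].
#' @export
rocAuc <- function(truth, scores) {
  if (length(truth) != length(scores))
    stop("truth and scores must have equal length")
  npos <- sum(truth == 1); nneg <- sum(truth == 0)
  if (npos == 0L || nneg == 0L)
    stop("AUC requires both classes in truth")
  r <- rank(scores)
  (sum(r[truth == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' ROC curve points
#'
#' @param truth binary labels.
#' @param scores decision values.
#' @return data.frame `threshold, fpr, tpr` sorted by descending
#'   threshold.
#' @export
rocPoints <- function(truth, scores) {
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  npos <- sum(truth == 1); nneg <- sum(truth == 0)
  tpr <- vapply(thr, function(t) sum(scores >= t & truth == 1) / npos,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & truth == 0) / nneg,
                numeric(1))
  data.frame(threshold = thr, fpr = fpr, tpr = tpr)
}

#' Cross-validation configuration
#'
#' @param k fold count (>= 2); 6, 8 and 10 are the conventional choices
#'   for this task.
#' @param repeats randomized re-partitions to average (the full protocol
#'   uses 50).
#' @param seed integer seed all partitions are drawn from.
#' @param stratified keep the class ratio in every fold (default TRUE;
#'   with a few hundred samples unstratified folds can go degenerate).
#' @return list of class `CVConfig`.
#' @export
cvConfig <- function(k = 10L, repeats = 50L, seed = 1L,
                     stratified = TRUE) {
  k <- as.integer(k); repeats <- as.integer(repeats)
  if (is.na(k) || k < 2L) stop("k must be >= 2")
  if (is.na(repeats) || repeats < 1L) stop("repeats must be >= 1")
  structure(list(k = k, repeats = repeats, seed = as.integer(seed),
                 stratified = stratified), class = "CVConfig")
}

## One stratified (or plain) random partition into k roughly equal folds.
.drawFolds <- function(y, k, stratified) {
  n <- length(y)
  fold <- integer(n)
  if (stratified) {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      fold[idx[sample.int(length(idx))]] <-
        rep_len(seq_len(k), length(idx))
    }
  } else {
    fold[sample.int(n)] <- rep_len(seq_len(k), n)
  }
  fold
}

## Fit on train rows, return decision values for test rows. The scaler
## is fitted on the training rows only, so no test information leaks
## into the preprocessing.
.foldDecisions <- function(dataset, train, test, C, kernel) {
  sc <- fitScaler(dataset@x[train, , drop = FALSE])
  model <- trainSVM(subsetDataset(dataset, train), C = C,
                    kernel = kernel, scaler = sc)
  decisionValue(model, dataset@x[test, , drop = FALSE])
}

#' Repeated stratified k-fold cross-validation
#'
#' For every repeat a fresh seeded partition into k roughly equal folds
#' is drawn; each fold is held out once while the scaler and SVM are
#' fitted on the remaining folds, so every sample is tested exactly once
#' per repeat. Metrics are pooled over the held-out predictions of a
#' repeat (micro-averaged) and then averaged over repeats.
#'
#' @param dataset a two-class [GlycDataset-class] with `n >= k`.
#' @param C soft-margin cost.
#' @param kernel a [kernelParams()].
#' @param cv a [cvConfig()].
#' @param knnWithinFold optional [knnFilterConfig()]: when supplied, kNN
#'   cleaning is applied to the training portion of every fold instead
#'   of once up front (the leakage-free variant).
#' @return a [CVSummary-class].
#' @export
runKFoldCV <- function(dataset, C = 512, kernel = kernelParams(),
                       cv = cvConfig(), knnWithinFold = NULL) {
  y <- dataset@y
  n <- length(y)
  if (n < cv$k) stop("need at least k samples")
  if (length(unique(y)) < 2L) stop("dataset must contain both classes")
  set.seed(cv$seed)
  rows <- vector("list", cv$repeats)
  for (r in seq_len(cv$repeats)) {
    for (attempt in 1:100) {
      fold <- .drawFolds(y, cv$k, cv$stratified)
      ok <- all(vapply(seq_len(cv$k), function(f)
        length(unique(y[fold != f])) == 2L, logical(1)))
      if (ok) break
      if (attempt == 100L)
        stop("could not draw a partition with two-class training sets")
    }
    scores <- numeric(n)
    for (f in seq_len(cv$k)) {
      train <- which(fold != f); test <- which(fold == f)
      if (!length(test)) next
      if (!is.null(knnWithinFold)) {
        cleaned <- knnClean(subsetDataset(dataset, train),
                            knnWithinFold)
        sc <- fitScaler(cleaned$dataset@x)
        model <- trainSVM(cleaned$dataset, C = C, kernel = kernel,
                          scaler = sc)
        scores[test] <- decisionValue(model,
                                      dataset@x[test, , drop = FALSE])
      } else {
        scores[test] <- .foldDecisions(dataset, train, test, C, kernel)
      }
    }
    pred <- as.integer(scores > 0)
    m <- computeMetrics(confusionCounts(y, pred))
    rows[[r]] <- data.frame(run = r, Sn = m["Sn"], Sp = m["Sp"],
                            Acc = m["Acc"], MCC = m["MCC"],
                            AUC = rocAuc(y, scores),
                            row.names = NULL)
  }
  new("CVSummary", perRun = do.call(rbind, rows), k = cv$k,
      repeats = cv$repeats, seed = cv$seed)
}

#' Jackknife (leave-one-out) evaluation
#'
#' n deterministic fits: each sample is predicted by the model trained
#' on the other n - 1; metrics come from the pooled n predictions.
#' There is no randomness, so a single pass is reported.
#'
#' @param dataset a two-class [GlycDataset-class] with n >= 3.
#' @param C soft-margin cost.
#' @param kernel a [kernelParams()].
#' @return a [CVSummary-class] with one run and `k = n`.
#' @export
runJackknife <- function(dataset, C = 512, kernel = kernelParams()) {
  n <- length(dataset@y)
  if (n < 3L) stop("jackknife requires n >= 3")
  if (length(unique(dataset@y)) < 2L)
    stop("dataset must contain both classes")
  scores <- numeric(n)
  for (i in seq_len(n)) {
    train <- setdiff(seq_len(n), i)
    if (length(unique(dataset@y[train])) < 2L)
      stop("leave-one-out training set lost a class")
    scores[i] <- .foldDecisions(dataset, train, i, C, kernel)
  }
  m <- computeMetrics(confusionCounts(dataset@y,
                                      as.integer(scores > 0)))
  new("CVSummary",
      perRun = data.frame(run = 1L, Sn = m["Sn"], Sp = m["Sp"],
                          Acc = m["Acc"], MCC = m["MCC"],
                          AUC = rocAuc(dataset@y, scores),
                          row.names = NULL),
      k = as.integer(n), repeats = 1L, seed = NA_integer_)
}

#' Scan segment window sizes
#'
#' Re-segments, re-encodes (vector length delta x 8), re-filters and
#' re-evaluates the full pipeline for every requested window length.
#'
#' @param bundle a [GlycBundle-class].
#' @param deltas odd window lengths >= 3 (the conventional scan runs
#'   3 to 39).
#' @param C,kernel model settings.
#' @param cv a [cvConfig()].
#' @param knn a [knnFilterConfig()] applied before CV per delta.
#' @return data.frame, one row per delta: `delta, dim, Sn, Sp, Acc,
#'   MCC, AUC`.
#' @export
windowSizeScan <- function(bundle, deltas = seq(3L, 39L, 2L), C = 512,
                           kernel = kernelParams(), cv = cvConfig(),
                           knn = knnFilterConfig()) {
  if (any(deltas %% 2L == 0L)) stop("window lengths must be odd")
  rows <- lapply(deltas, function(d) {
    segs <- segmentDataset(bundle, windowConfig(d))
    ds <- assembleDataset(segs, bundle@profiles)
    cleaned <- knnClean(ds, knn)
    s <- runKFoldCV(cleaned$dataset, C = C, kernel = kernel, cv = cv)
    m <- metricMeans(s)
    data.frame(delta = d, dim = ncol(ds@x), Sn = m["Sn"], Sp = m["Sp"],
               Acc = m["Acc"], MCC = m["MCC"], AUC = m["AUC"],
               row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Paired t-test between two methods' per-run metrics
#'
#' Standard two-sided paired t-test on the per-run differences. When the
#' differences have zero variance the degenerate convention is: all-zero
#' differences give p = 1, constant non-zero differences give p = 0.
#'
#' @param a,b equal-length numeric vectors of paired per-run metrics
#'   (length >= 2).
#' @return list with `t` and `p.value`.
#' @export
pairedMetricTest <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2L)
    stop("paired test needs equal-length vectors of length >= 2")
  d <- a - b
  if (sd(d) == 0) {
    if (mean(d) == 0) return(list(t = 0, p.value = 1))
    return(list(t = sign(mean(d)) * Inf, p.value = 0))
  }
  ht <- t.test(a, b, paired = TRUE)
  list(t = unname(ht$statistic), p.value = ht$p.value)
}

#' Write cross-validation results as CSVs
#'
#' Emits a per-run CSV (one row per (k, repeat)) and a summary CSV
#' (one row per evaluation scheme) mirroring the usual benchmark-table
#' layout.
#'
#' @param summaries named list of [CVSummary-class] objects (names used
#'   as the scheme column, e.g. "10-fold", "jackknife").
#' @param dir output directory.
#' @return character vector of the two file paths, invisibly.
#' @export
writeCvResults <- function(summaries, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  per <- do.call(rbind, lapply(names(summaries), function(nm) {
    cbind(scheme = nm, summaries[[nm]]@perRun)
  }))
  sum <- do.call(rbind, lapply(names(summaries), function(nm) {
    m <- metricMeans(summaries[[nm]])
    data.frame(scheme = nm, k = summaries[[nm]]@k,
               repeats = summaries[[nm]]@repeats,
               Sn = m["Sn"], Sp = m["Sp"], Acc = m["Acc"],
               MCC = m["MCC"], AUC = m["AUC"], row.names = NULL)
  }))
  perPath <- file.path(dir, "cv_runs.csv")
  sumPath <- file.path(dir, "cv_summary.csv")
  utils::write.csv(per, perPath, row.names = FALSE)
  utils::write.csv(sum, sumPath, row.names = FALSE)
  invisible(c(perPath, sumPath))
}
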