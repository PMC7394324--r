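#' Encode one segment as a numeric feature vector
#'
#' Concatenates, in N-to-C slot order, the 8-value structural feature
#' block `(ASA, phi, psi, theta, tau, ph, pe, pc)` of the residue each
#' window slot resolves to. Mirrored slots take the features of their
#' reflected source residue. The result has length delta x 8 (104 under
#' the default 13-residue window).
#'
#' @param segment a [SegmentSet-class] of length 1.
#' @param profile the [StructuralProfile-class] of the segment's protein.
#' @return named numeric vector of length `delta * 8`.
#' @export
buildFeatureVector <- function(segment, profile) {
  if (length(segment) != 1L)
    stop("buildFeatureVector expects a single segment")
  if (profile@proteinId != segment@proteinId)
    stop(sprintf("profile is for %s but segment is from %s",
                 profile@proteinId, segment@proteinId))
  idx <- as.integer(segment@sourceIndices[1L, ])
  if (any(idx > nrow(profile@features)))
    stop("segment indices exceed profile length")
  block <- profile@features[idx, , drop = FALSE]
  v <- as.numeric(t(block))
  offs <- rep(seq_len(segment@delta) - segment@sigma - 1L,
              each = length(RESIDUE_FEATURES))
  names(v) <- sprintf("s%+d.%s", offs, rep(RESIDUE_FEATURES,
                                           segment@delta))
  v
}

#' Fit a per-dimension min-max scaler
#'
#' @param x numeric matrix (rows = samples) or a [GlycDataset-class].
#' @return list of class `ScalerParams` with per-dimension `min`, `max`.
#' @export
fitScaler <- function(x) {
  if (is(x, "GlycDataset")) x <- x@x
  if (!is.matrix(x) || nrow(x) == 0L)
    stop("cannot fit a scaler on an empty collection")
  structure(list(min = apply(x, 2L, min), max = apply(x, 2L, max)),
            class = "ScalerParams")
}

#' Apply a min-max scaler
#'
#' Maps each value to `(v - min) / (max - min)`: 0 at the fitted minimum,
#' 1 at the maximum. Values outside the fitted range are deliberately
#' not clipped (test-fold values may fall outside \[0, 1\]). Degenerate
#' dimensions (max == min in the fitting set) map to 0.
#'
#' @param x numeric vector or matrix.
#' @param params a `ScalerParams` from [fitScaler()].
#' @return scaled object of the same shape.
#' @export
applyScaler <- function(x, params) {
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, 1L)
  if (ncol(x) != length(params$min))
    stop(sprintf("scaler has %d dimensions but data has %d",
                 length(params$min), ncol(x)))
  range <- params$max - params$min
  out <- sweep(x, 2L, params$min, "-")
  degen <- range == 0
  range[degen] <- 1
  out <- sweep(out, 2L, range, "/")
  if (any(degen)) out[, degen] <- 0
  if (vec) out[1L, ] else out
}

#' Invert a min-max scaler on non-degenerate dimensions
#'
#' @param x scaled vector or matrix.
#' @param params a `ScalerParams`.
#' @return values on the original scale (degenerate dimensions return
#'   the fitted minimum).
#' @export
invertScaler <- function(x, params) {
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, 1L)
  range <- params$max - params$min
  out <- sweep(sweep(x, 2L, range, "*"), 2L, params$min, "+")
  if (vec) out[1L, ] else out
}

#' Assemble the labelled feature dataset from segments and profiles
#'
#' Encodes every segment with [buildFeatureVector()]; rows keep the
#' segment order (deterministic given [segmentDataset()]'s ordering).
#' Features are stored raw; scaling is fitted where it is used (inside
#' cross-validation on training folds, or at final model fit).
#'
#' @param segments a [SegmentSet-class].
#' @param profiles named list of [StructuralProfile-class] objects.
#' @return a [GlycDataset-class] with `n = length(segments)` rows and
#'   `delta * 8` columns.
#' @export
assembleDataset <- function(segments, profiles) {
  n <- length(segments)
  if (n == 0L) stop("cannot assemble an empty dataset")
  p <- segments@delta * length(RESIDUE_FEATURES)
  x <- matrix(NA_real_, n, p)
  for (i in seq_len(n)) {
    one <- new("SegmentSet",
               proteinId = segments@proteinId[i],
               position = segments@position[i],
               label = segments@label[i],
               residues = segments@residues[i],
               sourceIndices = segments@sourceIndices[i, , drop = FALSE],
               mirrored = segments@mirrored[i, , drop = FALSE],
               delta = segments@delta, sigma = segments@sigma)
    prof <- profiles[[segments@proteinId[i]]]
    if (is.null(prof))
      stop("no profile for protein ", segments@proteinId[i])
    v <- buildFeatureVector(one, prof)
    if (i == 1L) colnames(x) <- names(v)
    x[i, ] <- v
  }
  new("GlycDataset", x = x,
      y = segments@label,
      keys = data.frame(protein_id = segments@proteinId,
                        position = segments@position,
                        stringsAsFactors = FALSE))
}

#' Subset a GlycDataset by row indices
#'
#' @param dataset a [GlycDataset-class].
#' @param i integer or logical row index.
#' @return the subsetted [GlycDataset-class].
#' @export
subsetDataset <- function(dataset, i) {
  new("GlycDataset", x = dataset@x[i, , drop = FALSE],
      y = dataset@y[i],
      keys = dataset@keys[i, , drop = FALSE])
}

#' Write a dataset in sparse libsvm text format
#'
#' One line per sample: `label index:value ...` (1-based indices, zero
#' values omitted, full double precision so the round-trip through
#' [readLibsvm()] is bit-exact). Site keys go to a sidecar TSV.
#'
#' @param dataset a [GlycDataset-class].
#' @param path output file.
#' @param keysPath sidecar TSV of site keys (default `<path>.keys.tsv`).
#' @return `path`, invisibly.
#' @export
writeLibsvm <- function(dataset, path,
                        keysPath = paste0(path, ".keys.tsv")) {
  con <- file(path, "wb")
  lines <- vapply(seq_len(length(dataset)), function(i) {
    v <- dataset@x[i, ]
    nz <- which(v != 0)
    paste(c(sprintf("%d", dataset@y[i]),
            sprintf("%d:%.17g", nz, v[nz])), collapse = " ")
  }, character(1))
  writeLines(lines, con)
  close(con)
  keys <- cbind(dataset@keys, label = dataset@y)
  writeSiteAnnotations(
    data.frame(protein_id = keys$protein_id, position = keys$position,
               label = keys$label, stringsAsFactors = FALSE),
    keysPath)
  invisible(path)
}

#' Read a dataset from sparse libsvm text format
#'
#' @param path libsvm file written by [writeLibsvm()].
#' @param keysPath sidecar TSV of site keys.
#' @param dim number of feature dimensions; inferred from the largest
#'   index present when `NULL`.
#' @return a [GlycDataset-class].
#' @export
readLibsvm <- function(path, keysPath = paste0(path, ".keys.tsv"),
                       dim = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, " ", fixed = TRUE)
  y <- vapply(parts, function(p) as.integer(p[1]), integer(1))
  feats <- lapply(parts, function(p) {
    if (length(p) < 2L) return(cbind(integer(0), numeric(0)))
    kv <- strsplit(p[-1], ":", fixed = TRUE)
    cbind(vapply(kv, function(z) as.integer(z[1]), integer(1)),
          vapply(kv, function(z) as.numeric(z[2]), numeric(1)))
  })
  if (is.null(dim))
    dim <- max(vapply(feats, function(m)
      if (nrow(m)) max(m[, 1]) else 0L, numeric(1)))
  x <- matrix(0, length(y), dim)
  for (i in seq_along(feats)) {
    m <- feats[[i]]
    if (nrow(m)) x[i, m[, 1]] <- m[, 2]
  }
  keys <- readSiteAnnotations(keysPath)
  new("GlycDataset", x = x, y = y,
      keys = keys[, c("protein_id", "position"), drop = FALSE])
}
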