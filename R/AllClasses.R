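#' @import methods
#' @importFrom stats runif rnorm rgamma sd t.test predict
#' @importFrom utils head read.table write.table
NULL

## Per-residue structural feature track, in fixed column order:
## accessible surface area, four backbone angles, three secondary-structure
## state probabilities (helix, strand, coil).
RESIDUE_FEATURES <- c("ASA", "phi", "psi", "theta", "tau", "ph", "pe", "pc")

#' StructuralProfile: per-residue structural features of one protein
#'
#' Holds, for a single protein of length L, the 8-value structural feature
#' track of every residue: predicted accessible surface area (ASA,
#' Angstrom^2), backbone angles phi/psi/theta/tau (degrees, in
#' \[-180, 180\]) and the three-state secondary-structure probabilities
#' ph/pe/pc (helix/strand/coil, each in \[0, 1\]). Residue letters are
#' stored alongside so the profile can be checked against the sequence
#' it was computed from.
#'
#' @slot proteinId single accession string.
#' @slot residues character vector of single residue letters, length L.
#' @slot features numeric L x 8 matrix, columns
#'   `ASA, phi, psi, theta, tau, ph, pe, pc`.
#'
#' @seealso [structuralProfile()], [parseSpd3()]
#' @export
setClass("StructuralProfile",
  representation(
    proteinId = "character",
    residues = "character",
    features = "matrix"
  )
)

setValidity("StructuralProfile", function(object) {
  msg <- character()
  if (length(object@proteinId) != 1L || !nzchar(object@proteinId))
    msg <- c(msg, "proteinId must be a single non-empty string")
  f <- object@features
  if (!is.numeric(f))
    msg <- c(msg, "features must be numeric")
  if (!identical(colnames(f), RESIDUE_FEATURES))
    msg <- c(msg, sprintf("feature columns must be (%s)",
                          paste(RESIDUE_FEATURES, collapse = ", ")))
  if (nrow(f) != length(object@residues))
    msg <- c(msg, "feature row count must equal residue count")
  if (length(msg)) msg else {
    if (any(!is.finite(f)))
      return("all feature values must be finite")
    ang <- f[, c("phi", "psi", "theta", "tau"), drop = FALSE]
    if (any(ang < -180 | ang > 180))
      return("backbone angles must lie in [-180, 180] degrees")
    pr <- f[, c("ph", "pe", "pc"), drop = FALSE]
    if (any(pr < 0 | pr > 1))
      return("secondary-structure probabilities must lie in [0, 1]")
    if (any(f[, "ASA"] < 0))
      return("ASA must be non-negative")
    TRUE
  }
})

#' Construct a StructuralProfile
#'
#' Validates ranges and warns (without failing) when the three
#' secondary-structure probabilities of any residue sum outside
#' \[0.9, 1.1\] — predicted probabilities are not guaranteed to be
#' normalised.
#'
#' @param proteinId accession string.
#' @param residues character vector of residue letters (or a single
#'   string, which is split).
#' @param features numeric L x 8 matrix in the column order
#'   `ASA, phi, psi, theta, tau, ph, pe, pc`.
#' @return a [StructuralProfile-class] object.
#' @export
structuralProfile <- function(proteinId, residues, features) {
  if (length(residues) == 1L && nchar(residues) > 1L)
    residues <- strsplit(residues, "")[[1]]
  features <- as.matrix(features)
  colnames(features) <- RESIDUE_FEATURES
  storage.mode(features) <- "double"
  obj <- new("StructuralProfile", proteinId = as.character(proteinId),
             residues = toupper(residues), features = features)
  psum <- rowSums(features[, c("ph", "pe", "pc"), drop = FALSE])
  off <- which(psum < 0.9 | psum > 1.1)
  if (length(off))
    warning(sprintf(
      "profile %s: ph+pe+pc outside [0.9, 1.1] at %d residue(s) (first: %d)",
      proteinId, length(off), off[1]), call. = FALSE)
  obj
}

#' SegmentSet: fixed-length lysine-centred peptide windows
#'
#' A collection of peptide segments of odd length delta = 2*sigma + 1,
#' each centred on an annotated lysine. Flanks that run past the protein
#' termini are filled by mirror reflection (the terminal residue itself is
#' not duplicated); `mirrored` records which window slots were filled that
#' way and `sourceIndices` the 1-based residue index each slot reads from.
#'
#' @slot proteinId character, one accession per segment.
#' @slot position integer, 1-based index of the central lysine.
#' @slot label integer, 1 = glycated, 0 = non-glycated.
#' @slot residues character, the delta-letter window string per segment.
#' @slot sourceIndices integer n x delta matrix of resolved residue indices.
#' @slot mirrored logical n x delta matrix flagging reflected slots.
#' @slot delta,sigma integer window geometry.
#' @export
setClass("SegmentSet",
  representation(
    proteinId = "character",
    position = "integer",
    label = "integer",
    residues = "character",
    sourceIndices = "matrix",
    mirrored = "matrix",
    delta = "integer",
    sigma = "integer"
  )
)

setValidity("SegmentSet", function(object) {
  n <- length(object@proteinId)
  d <- object@delta
  if (length(d) != 1L || length(object@sigma) != 1L)
    return("delta and sigma must be scalars")
  if (d != 2L * object@sigma + 1L)
    return("delta must equal 2*sigma + 1")
  if (length(object@position) != n || length(object@label) != n ||
      length(object@residues) != n)
    return("per-segment slots must have equal length")
  if (n > 0 && (nrow(object@sourceIndices) != n ||
                ncol(object@sourceIndices) != d))
    return("sourceIndices must be n x delta")
  if (n > 0 && any(nchar(object@residues) != d))
    return("every residue window must have delta letters")
  if (n > 0 && any(substr(object@residues, object@sigma + 1L,
                          object@sigma + 1L) != "K"))
    return("central residue of every segment must be K")
  if (!all(object@label %in% c(0L, 1L)))
    return("labels must be 0 or 1")
  TRUE
})

#' GlycDataset: encoded lysine sites ready for classification
#'
#' Feature matrix of encoded segments (one row per lysine site, delta x 8
#' columns), binary labels (1 = glycated) and the (protein, position) key
#' of every row.
#'
#' @slot x numeric n x (delta*8) feature matrix.
#' @slot y integer labels in \{0, 1\}.
#' @slot keys data.frame with columns `protein_id`, `position`.
#' @export
setClass("GlycDataset",
  representation(x = "matrix", y = "integer", keys = "data.frame")
)

setValidity("GlycDataset", function(object) {
  if (nrow(object@x) != length(object@y))
    return("x and y must have matching length")
  if (nrow(object@keys) != length(object@y))
    return("keys must have one row per sample")
  if (!all(c("protein_id", "position") %in% names(object@keys)))
    return("keys must have protein_id and position columns")
  if (!all(object@y %in% c(0L, 1L)))
    return("labels must be 0 or 1")
  if (any(!is.finite(object@x)))
    return("feature values must be finite")
  TRUE
})

#' PolySVM: self-contained polynomial-kernel SVM model
#'
#' Stores everything needed to evaluate the SVM decision function
#' f(x) = sum_i alpha_i y_i K(x_i, x) + beta with the polynomial kernel
#' K(u, v) = (gamma * <u, v> + coef0)^degree, independently of the solver
#' that produced it: support vectors, dual coefficients alpha_i*y_i, bias,
#' kernel parameters, the soft-margin cost and the min-max scaler fitted
#' on the training data. Positive decision values predict the glycated
#' class.
#'
#' @slot supportVectors numeric nSV x p matrix (scaled feature space).
#' @slot dualCoefs numeric alpha_i * y_i per support vector.
#' @slot bias numeric scalar beta.
#' @slot gamma,coef0 numeric kernel parameters.
#' @slot degree integer polynomial degree.
#' @slot cost numeric soft-margin cost C.
#' @slot scalerMin,scalerMax numeric per-dimension training min/max.
#' @export
setClass("PolySVM",
  representation(
    supportVectors = "matrix",
    dualCoefs = "numeric",
    bias = "numeric",
    gamma = "numeric",
    coef0 = "numeric",
    degree = "integer",
    cost = "numeric",
    scalerMin = "numeric",
    scalerMax = "numeric"
  )
)

setValidity("PolySVM", function(object) {
  if (nrow(object@supportVectors) != length(object@dualCoefs))
    return("one dual coefficient per support vector required")
  if (nrow(object@supportVectors) < 1L)
    return("model must retain at least one support vector")
  if (object@gamma <= 0) return("gamma must be positive")
  if (object@degree < 1L) return("degree must be >= 1")
  if (any(abs(object@dualCoefs) > object@cost + 1e-8))
    return("|dual coefficients| must not exceed C")
  p <- ncol(object@supportVectors)
  if (length(object@scalerMin) != p || length(object@scalerMax) != p)
    return("scaler dimension must match support vectors")
  TRUE
})

#' CVSummary: metrics of a repeated cross-validation run
#'
#' Per-repeat sensitivity, specificity, accuracy, MCC and AUC (each repeat
#' pools the held-out predictions of its k folds) plus their means.
#'
#' @slot perRun data.frame, one row per repeat with columns
#'   `run, Sn, Sp, Acc, MCC, AUC`.
#' @slot k integer fold count (n for jackknife).
#' @slot repeats integer number of random re-partitions averaged.
#' @slot seed integer seed the partitions were drawn from.
#' @export
setClass("CVSummary",
  representation(perRun = "data.frame", k = "integer",
                 repeats = "integer", seed = "integer")
)

setValidity("CVSummary", function(object) {
  need <- c("run", "Sn", "Sp", "Acc", "MCC", "AUC")
  if (!all(need %in% names(object@perRun)))
    return(sprintf("perRun must have columns (%s)",
                   paste(need, collapse = ", ")))
  if (nrow(object@perRun) < 1L) return("at least one run required")
  TRUE
})

#' GlycBundle: validated dataset of sequences, site labels and profiles
#'
#' The three input artifacts after cross-validation of their consistency:
#' every annotated site refers to an existing protein, sits on a lysine,
#' and every annotated protein carries a structural profile whose residues
#' match its sequence.
#'
#' @slot proteins [Biostrings::AAStringSet] named by accession.
#' @slot sites data.frame with columns `protein_id, position, label`.
#' @slot profiles named list of [StructuralProfile-class] objects.
#' @export
setClass("GlycBundle",
  representation(proteins = "ANY", sites = "data.frame", profiles = "list")
)
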