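#' Accessors for GlycSite classes
#'
#' Small accessor generics: `featureMatrix` returns the numeric feature
#' matrix of a dataset or profile, `siteKeys` the (protein, position, label)
#' table of a dataset or segment set, `siteLabels` the binary label vector,
#' `metricMeans` the averaged metrics of a cross-validation summary and
#' `perRunMetrics` its per-repeat table.
#'
#' @param x object.
#' @return see individual methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname accessors
#' @export
setGeneric("siteKeys", function(x) standardGeneric("siteKeys"))

#' @rdname accessors
#' @export
setGeneric("siteLabels", function(x) standardGeneric("siteLabels"))

#' @rdname accessors
#' @export
setGeneric("metricMeans", function(x) standardGeneric("metricMeans"))

#' @rdname accessors
#' @export
setGeneric("perRunMetrics", function(x) standardGeneric("perRunMetrics"))

#' @rdname accessors
#' @export
setMethod("featureMatrix", "GlycDataset", function(x) x@x)

#' @rdname accessors
#' @export
setMethod("featureMatrix", "StructuralProfile", function(x) x@features)

#' @rdname accessors
#' @export
setMethod("siteKeys", "GlycDataset", function(x) x@keys)

#' @rdname accessors
#' @export
setMethod("siteKeys", "SegmentSet", function(x)
  data.frame(protein_id = x@proteinId, position = x@position,
             label = x@label, stringsAsFactors = FALSE))

#' @rdname accessors
#' @export
setMethod("siteLabels", "GlycDataset", function(x) x@y)

#' @rdname accessors
#' @export
setMethod("siteLabels", "SegmentSet", function(x) x@label)

#' @rdname accessors
#' @export
setMethod("metricMeans", "CVSummary", function(x)
  colMeans(x@perRun[, c("Sn", "Sp", "Acc", "MCC", "AUC"), drop = FALSE]))

#' @rdname accessors
#' @export
setMethod("perRunMetrics", "CVSummary", function(x) x@perRun)

#' @export
setMethod("length", "SegmentSet", function(x) length(x@proteinId))

#' @export
setMethod("length", "GlycDataset", function(x) length(x@y))

setMethod("show", "StructuralProfile", function(object) {
  cat(sprintf("StructuralProfile for %s: %d residues x %d features\n",
              object@proteinId, nrow(object@features),
              ncol(object@features)))
})

setMethod("show", "SegmentSet", function(object) {
  cat(sprintf(
    "SegmentSet: %d segment(s), window delta=%d (flank sigma=%d), %d positive\n",
    length(object), object@delta, object@sigma, sum(object@label == 1L)))
})

setMethod("show", "GlycDataset", function(object) {
  cat(sprintf(
    "GlycDataset: %d sites x %d features (%d glycated, %d non-glycated)\n",
    length(object@y), ncol(object@x), sum(object@y == 1L),
    sum(object@y == 0L)))
})

setMethod("show", "PolySVM", function(object) {
  cat(sprintf(
    "PolySVM: %d support vectors, dim %d; kernel (gamma=%g * <u,v> + %g)^%d, C=%g\n",
    nrow(object@supportVectors), ncol(object@supportVectors),
    object@gamma, object@coef0, object@degree, object@cost))
})

setMethod("show", "CVSummary", function(object) {
  m <- metricMeans(object)
  cat(sprintf("CVSummary: %d-fold x %d repeat(s)\n", object@k,
              object@repeats))
  cat(sprintf("  mean Sn=%.4f Sp=%.4f Acc=%.4f MCC=%.4f AUC=%.4f\n",
              m["Sn"], m["Sp"], m["Acc"], m["MCC"], m["AUC"]))
})

setMethod("show", "GlycBundle", function(object) {
  cat(sprintf(
    "GlycBundle: %d proteins, %d sites (%d glycated / %d non-glycated), %d profiles\n",
    length(object@proteins), nrow(object@sites),
    sum(object@sites$label == 1L), sum(object@sites$label == 0L),
    length(object@profiles)))
})
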