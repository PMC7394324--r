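#' Window configuration for lysine-centred segments
#'
#' The segment length delta is odd so the lysine sits centrally with
#' sigma = (delta - 1)/2 flanking residues on each side. The default
#' delta = 13 (sigma = 6) is the window length at which prediction
#' performance plateaus in window-size scans.
#'
#' @param delta odd segment length in residues, >= 3.
#' @return list with components `delta` and `sigma`.
#' @export
windowConfig <- function(delta = 13L) {
  delta <- as.integer(delta)
  if (length(delta) != 1L || is.na(delta) || delta < 3L ||
      delta %% 2L == 0L)
    stop("delta must be a single odd integer >= 3")
  list(delta = delta, sigma = (delta - 1L) %/% 2L)
}

#' Resolve a window position through mirror reflection
#'
#' Maps any integer window position `q` to a valid 1-based residue index
#' of a protein of length `L`. In-range positions are returned unchanged;
#' positions before the N-terminus reflect about position 1 (q -> 2 - q,
#' the terminal residue itself is not duplicated) and positions past the
#' C-terminus reflect about position L (q -> 2L - q). Reflection is
#' applied repeatedly (ping-pong) until the index lands in \[1, L\], so
#' the mapping is total for every protein of length >= 2.
#'
#' @param q integer vector of window positions (may be outside \[1, L\]).
#' @param L protein length, >= 2 whenever any `q` is out of range.
#' @return integer vector of resolved residue indices in \[1, L\].
#' @export
resolveMirroredIndex <- function(q, L) {
  q <- as.integer(q); L <- as.integer(L)
  out <- q < 1L | q > L
  if (any(out) && L < 2L)
    stop("mirroring is undefined for proteins of length < 2")
  while (any(q < 1L | q > L)) {
    q <- ifelse(q < 1L, 2L - q, q)
    q <- ifelse(q > L, 2L * L - q, q)
  }
  q
}

#' Extract the peptide segment around one lysine
#'
#' Builds the window of positions `position - sigma .. position + sigma`,
#' resolving out-of-range slots by [resolveMirroredIndex()] and flagging
#' them in the mirrored mask.
#'
#' @param protein single named sequence (element of an
#'   [Biostrings::AAStringSet] or named character string).
#' @param position 1-based index of the central residue; must be a
#'   lysine (K).
#' @param config [windowConfig()].
#' @param label binary site label (default `NA` -> stored as 0).
#' @return a [SegmentSet-class] of length 1.
#' @export
extractSegment <- function(protein, position, config = windowConfig(),
                           label = 0L) {
  seq <- as.character(protein)[1]
  id <- names(protein)[1]
  if (is.null(id) || !nzchar(id)) stop("protein must be named")
  L <- nchar(seq)
  if (L < 2L) stop("cannot extract segments from a 1-residue protein")
  position <- as.integer(position)
  if (position < 1L || position > L)
    stop(sprintf("position %d outside protein %s (L=%d)", position, id, L))
  if (substr(seq, position, position) != "K")
    stop(sprintf("residue at %s:%d is '%s', not K", id, position,
                 substr(seq, position, position)))
  raw <- (position - config$sigma):(position + config$sigma)
  src <- resolveMirroredIndex(raw, L)
  mirrored <- raw < 1L | raw > L
  letters <- strsplit(seq, "")[[1]][src]
  lab <- suppressWarnings(as.integer(label))
  if (length(lab) != 1L || is.na(lab)) lab <- 0L
  if (!lab %in% c(0L, 1L)) stop("label must be 0 or 1")
  new("SegmentSet",
      proteinId = id, position = position,
      label = lab,
      residues = paste(letters, collapse = ""),
      sourceIndices = matrix(src, 1L, config$delta),
      mirrored = matrix(mirrored, 1L, config$delta),
      delta = config$delta, sigma = config$sigma)
}

#' Extract segments for every annotated site of a bundle
#'
#' One segment per annotation, in deterministic (protein id, position)
#' order, labels carried through.
#'
#' @param bundle a [GlycBundle-class].
#' @param config [windowConfig()].
#' @return a [SegmentSet-class] with one row per annotation.
#' @export
segmentDataset <- function(bundle, config = windowConfig()) {
  sites <- bundle@sites
  ord <- order(sites$protein_id, sites$position)
  sites <- sites[ord, , drop = FALSE]
  n <- nrow(sites)
  d <- config$delta
  src <- matrix(NA_integer_, n, d)
  mir <- matrix(FALSE, n, d)
  res <- character(n)
  seqs <- as.character(bundle@proteins)
  for (i in seq_len(n)) {
    pid <- sites$protein_id[i]
    one <- seqs[pid]
    names(one) <- pid
    s <- extractSegment(one, sites$position[i], config, sites$label[i])
    src[i, ] <- s@sourceIndices
    mir[i, ] <- s@mirrored
    res[i] <- s@residues
  }
  new("SegmentSet",
      proteinId = sites$protein_id, position = sites$position,
      label = as.integer(sites$label), residues = res,
      sourceIndices = src, mirrored = mir,
      delta = d, sigma = config$sigma)
}

#' Write segments as FASTA-like records for inspection
#'
#' Record ids take the form `<protein>@<position>|y=<label>`.
#'
#' @param segments a [SegmentSet-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSegmentsFasta <- function(segments, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste0(">", segments@proteinId, "@", segments@position,
                    "|y=", segments@label, "\n", segments@residues),
             con, sep = "\n")
  invisible(path)
}
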