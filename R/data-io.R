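#' Read protein sequences from a FASTA file
#'
#' Wraps [Biostrings::readAAStringSet()]. The header token before the
#' first whitespace becomes the accession; sequences are uppercased and
#' stop (`*`) or gap (`-`, `.`) characters are stripped with a warning.
#' No length restriction is imposed: records from 2 residues to several
#' thousand are accepted.
#'
#' @param path FASTA file.
#' @return a named [Biostrings::AAStringSet], one entry per record.
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) stop("FASTA file contains no records: ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (any(!nzchar(ids))) stop("FASTA record with empty id in ", path)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate FASTA id(s): ", paste(dup, collapse = ", "))
  chars <- toupper(as.character(seqs))
  cleaned <- gsub("[*.-]", "", chars)
  if (any(cleaned != chars))
    warning("stripped '*' or gap characters from ",
            sum(cleaned != chars), " record(s)", call. = FALSE)
  empty <- which(!nzchar(cleaned))
  if (length(empty))
    stop("zero-length sequence for record(s): ",
         paste(ids[empty], collapse = ", "))
  out <- Biostrings::AAStringSet(cleaned)
  names(out) <- ids
  out
}

#' Write protein sequences to FASTA
#'
#' @param proteins named [Biostrings::AAStringSet].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(proteins, path) {
  Biostrings::writeXStringSet(proteins, path, width = 60L)
  invisible(path)
}

#' Read lysine site annotations
#'
#' Parses a tab-separated table with columns `protein_id`, `position`
#' (1-based) and `label` (0/1 or `non-glycated`/`glycated`); a header
#' line is optional. Malformed positions, unknown labels and duplicate
#' (protein, position) pairs are errors reported with their line number.
#'
#' @param path TSV file.
#' @return data.frame with columns `protein_id` (character), `position`
#'   (integer), `label` (integer 0/1).
#' @export
readSiteAnnotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("annotation file is empty: ", path)
  first <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  start <- 1L
  # a header has a non-numeric position AND a non-label third column
  if (length(first) >= 3L &&
      is.na(suppressWarnings(as.numeric(first[2]))) &&
      !trimws(first[3]) %in% c("0", "1", "glycated", "non-glycated"))
    start <- 2L
  if (start > length(lines)) stop("annotation file has a header but no rows")
  n <- length(lines) - start + 1L
  pid <- character(n); pos <- integer(n); lab <- integer(n)
  vocab <- c("0" = 0L, "1" = 1L, "non-glycated" = 0L, "glycated" = 1L)
  for (i in seq_len(n)) {
    lineno <- start + i - 1L
    f <- strsplit(lines[[lineno]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop(sprintf("line %d: expected 3 tab-separated fields", lineno))
    p <- suppressWarnings(as.numeric(f[2]))
    if (is.na(p) || p != as.integer(p) || p < 1)
      stop(sprintf("line %d: position '%s' is not a positive integer",
                   lineno, f[2]))
    l <- vocab[trimws(f[3])]
    if (is.na(l))
      stop(sprintf("line %d: label '%s' not in {0, 1, glycated, non-glycated}",
                   lineno, f[3]))
    pid[i] <- trimws(f[1]); pos[i] <- as.integer(p); lab[i] <- unname(l)
  }
  key <- paste(pid, pos)
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1]
    stop(sprintf("line %d: duplicate site %s:%d", start + d - 1L,
                 pid[d], pos[d]))
  }
  data.frame(protein_id = pid, position = pos, label = lab,
             stringsAsFactors = FALSE)
}

#' Write lysine site annotations as TSV
#'
#' @param sites data.frame as returned by [readSiteAnnotations()].
#' @param path output file.
#' @param header write a header line (default TRUE).
#' @return `path`, invisibly.
#' @export
writeSiteAnnotations <- function(sites, path, header = TRUE) {
  con <- file(path, "wb")
  on.exit(close(con))
  if (header)
    writeLines("protein_id\tposition\tlabel", con)
  writeLines(sprintf("%s\t%d\t%d", sites$protein_id, sites$position,
                     sites$label), con)
  invisible(path)
}

## Column synonyms used across structural-profile file versions; matched
## case-insensitively, with prefix matching for the annotated angle
## headers like "Theta(i-1=>i+1)".
.spd3Columns <- function(tokens) {
  lower <- tolower(tokens)
  find <- function(exact, prefix = NULL) {
    i <- which(lower %in% exact)
    if (!length(i) && !is.null(prefix))
      i <- which(startsWith(lower, prefix))
    if (!length(i)) NA_integer_ else i[1]
  }
  c(index = find("index", "#"),
    AA = find(c("aa", "res", "residue")),
    SS = find(c("ss", "sstate")),
    ASA = find("asa"),
    phi = find("phi", "phi"),
    psi = find("psi", "psi"),
    theta = find("theta", "theta"),
    tau = find("tau", "tau"),
    pc = find(c("p(c)", "pc"), "p(c)"),
    pe = find(c("p(e)", "pe"), "p(e)"),
    ph = find(c("p(h)", "ph"), "p(h)"))
}

#' Parse a structural profile in .spd3 format
#'
#' Reads the whitespace-delimited per-residue table emitted by structure
#' prediction tools in the SPIDER2 `.spd3` dialect: columns index,
#' residue letter, secondary-structure class, ASA, Phi, Psi, Theta, Tau,
#' P(C), P(E), P(H) (coil probability first in the file). When a `#`
#' header is present columns are located by name; otherwise positionally.
#' The profile is checked row-by-row against the protein sequence:
#' a row-count or residue-letter mismatch is an error.
#'
#' @param path `.spd3` file.
#' @param protein a single named sequence: one element of an
#'   [Biostrings::AAStringSet], or a named character string.
#' @return a [StructuralProfile-class].
#' @export
parseSpd3 <- function(path, protein) {
  if (!file.exists(path)) stop("spd3 file not found: ", path)
  seq <- as.character(protein)[1]
  id <- names(protein)[1]
  if (is.null(id) || !nzchar(id)) stop("protein must be named")
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  headed <- length(lines) && startsWith(trimws(lines[[1]]), "#")
  if (headed) {
    htok <- strsplit(trimws(sub("^#", "", lines[[1]])), "\\s+")[[1]]
    cols <- .spd3Columns(htok)
    lines <- lines[-1]
  } else {
    cols <- c(index = 1L, AA = 2L, SS = 3L, ASA = 4L, phi = 5L, psi = 6L,
              theta = 7L, tau = 8L, pc = 9L, pe = 10L, ph = 11L)
  }
  numcols <- c("ASA", "phi", "psi", "theta", "tau", "pc", "pe", "ph")
  if (any(is.na(cols[c("AA", numcols)])))
    stop("spd3 header is missing required columns in ", path)
  L <- nchar(seq)
  if (length(lines) != L)
    stop(sprintf("spd3 %s: %d rows but protein %s has %d residues",
                 path, length(lines), id, L))
  feats <- matrix(NA_real_, L, 8L,
                  dimnames = list(NULL, RESIDUE_FEATURES))
  letters <- character(L)
  for (i in seq_len(L)) {
    f <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    letters[i] <- toupper(f[cols["AA"]])
    v <- suppressWarnings(as.numeric(f[cols[numcols]]))
    if (any(is.na(v)))
      stop(sprintf("spd3 %s row %d: unparseable numeric field", path, i))
    feats[i, ] <- v[match(RESIDUE_FEATURES,
                          c("ASA", "phi", "psi", "theta", "tau",
                            "pc", "pe", "ph"))]
  }
  mism <- which(letters != strsplit(seq, "")[[1]])
  if (length(mism))
    stop(sprintf("spd3 %s: residue mismatch at position %d ('%s' vs sequence '%s')",
                 path, mism[1], letters[mism[1]],
                 substr(seq, mism[1], mism[1])))
  structuralProfile(id, seq, feats)
}

#' Write a structural profile in .spd3 format
#'
#' Inverse of [parseSpd3()] up to numeric formatting (6 decimal places,
#' round-trip relative error below 1e-6). The secondary-structure class
#' column is derived as the argmax of (pc, pe, ph).
#'
#' @param profile a [StructuralProfile-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSpd3 <- function(profile, path) {
  f <- profile@features
  ss <- c("C", "E", "H")[max.col(f[, c("pc", "pe", "ph"), drop = FALSE],
                                 ties.method = "first")]
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines("# index AA SS ASA Phi Psi Theta(i-1=>i+1) Tau(i-2=>i+2) P(C) P(E) P(H)",
             con)
  writeLines(sprintf(
    "%d %s %s %.6f %.6f %.6f %.6f %.6f %.6f %.6f %.6f",
    seq_len(nrow(f)), profile@residues, ss,
    f[, "ASA"], f[, "phi"], f[, "psi"], f[, "theta"], f[, "tau"],
    f[, "pc"], f[, "pe"], f[, "ph"]), con)
  invisible(path)
}

#' Validate sequences, annotations and profiles into a bundle
#'
#' Cross-checks the three input artifacts: every annotation must
#' reference an existing protein, lie within its length, sit on a lysine
#' (K), and every annotated protein must carry a structural profile whose
#' residues match the sequence. The result is independent of input
#' ordering (sites are sorted by protein, then position).
#'
#' @param proteins named [Biostrings::AAStringSet].
#' @param sites annotation data.frame ([readSiteAnnotations()]).
#' @param profiles named list of [StructuralProfile-class] objects.
#' @return a [GlycBundle-class]; its `counts` ([bundleCounts()]) give
#'   `n_proteins`, `n_pos`, `n_neg`.
#' @export
validateDataset <- function(proteins, sites, profiles) {
  ids <- names(proteins)
  missing <- setdiff(unique(sites$protein_id), ids)
  if (length(missing))
    stop("annotations reference unknown protein(s): ",
         paste(missing, collapse = ", "))
  lens <- Biostrings::width(proteins)
  names(lens) <- ids
  bad <- sites$position < 1L | sites$position > lens[sites$protein_id]
  if (any(bad))
    stop("annotation position out of range: ",
         paste(sprintf("%s:%d", sites$protein_id[bad],
                       sites$position[bad]), collapse = ", "))
  res <- substr(as.character(proteins[sites$protein_id]),
                sites$position, sites$position)
  nonK <- res != "K"
  if (any(nonK))
    stop("annotation at non-lysine residue: ",
         paste(sprintf("%s:%d", sites$protein_id[nonK],
                       sites$position[nonK]), collapse = ", "))
  annotated <- unique(sites$protein_id)
  noProf <- setdiff(annotated, names(profiles))
  if (length(noProf))
    stop("missing structural profile for protein(s): ",
         paste(noProf, collapse = ", "))
  for (pid in annotated) {
    prof <- profiles[[pid]]
    sq <- strsplit(as.character(proteins[[pid]]), "")[[1]]
    if (length(prof@residues) != length(sq))
      stop(sprintf("profile %s has %d rows but sequence has %d residues",
                   pid, length(prof@residues), length(sq)))
    mism <- which(prof@residues != sq)
    if (length(mism))
      stop(sprintf("profile %s residue mismatch at position %d",
                   pid, mism[1]))
  }
  ord <- order(sites$protein_id, sites$position)
  new("GlycBundle", proteins = proteins, sites = sites[ord, , drop = FALSE],
      profiles = profiles[intersect(ids, names(profiles))])
}

#' Site counts of a validated bundle
#'
#' @param bundle a [GlycBundle-class].
#' @return named integer vector `n_proteins`, `n_pos`, `n_neg`.
#' @export
bundleCounts <- function(bundle) {
  c(n_proteins = length(bundle@proteins),
    n_pos = sum(bundle@sites$label == 1L),
    n_neg = sum(bundle@sites$label == 0L))
}

#' Load a bundle from files on disk
#'
#' Convenience loader: FASTA + annotation TSV + one `<protein_id>.spd3`
#' per annotated protein in `spd3Dir`, passed through [validateDataset()].
#'
#' @param fastaPath FASTA file.
#' @param sitesPath annotation TSV.
#' @param spd3Dir directory of `.spd3` files.
#' @return a [GlycBundle-class].
#' @export
readBundle <- function(fastaPath, sitesPath, spd3Dir) {
  proteins <- readFasta(fastaPath)
  sites <- readSiteAnnotations(sitesPath)
  annotated <- unique(sites$protein_id)
  profiles <- list()
  for (pid in annotated) {
    fp <- file.path(spd3Dir, paste0(pid, ".spd3"))
    if (!file.exists(fp))
      stop("missing structural profile file for protein ", pid, ": ", fp)
    profiles[[pid]] <- parseSpd3(fp, proteins[pid])
  }
  validateDataset(proteins, sites, profiles)
}
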