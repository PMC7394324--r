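# Fixture builders and independent oracles shared across test files.

# Random but valid per-residue feature matrix for a sequence.
randomFeatures <- function(L) {
  pr <- matrix(rgamma(L * 3, shape = c(2, 1, 2)[rep(1:3, each = L)]),
               L, 3)
  pr <- pr / rowSums(pr)
  cbind(ASA = abs(rnorm(L, 60, 25)),
        phi = runif(L, -180, 0), psi = runif(L, -120, 180),
        theta = runif(L, 70, 150), tau = runif(L, -180, 180),
        ph = pr[, 1], pe = pr[, 2], pc = pr[, 3])
}

tinyProfile <- function(id, seq, seed = 1) {
  set.seed(seed)
  structuralProfile(id, seq, randomFeatures(nchar(seq)))
}

# Three-protein bundle with hand-placed lysines; 6 sites (2 positive).
tinyBundle <- function(seed = 1) {
  seqs <- c(PA = "ACDKGAMKLWYTRK", PB = "MKACDEFGHIKLMN",
            PC = "GGKGGGGGGGKGG")
  proteins <- Biostrings::AAStringSet(seqs)
  sites <- data.frame(
    protein_id = c("PA", "PA", "PA", "PB", "PB", "PC"),
    position = c(4L, 8L, 14L, 2L, 11L, 3L),
    label = c(1L, 0L, 0L, 1L, 0L, 0L),
    stringsAsFactors = FALSE)
  profiles <- lapply(names(seqs), function(id)
    tinyProfile(id, seqs[[id]], seed + match(id, names(seqs))))
  names(profiles) <- names(seqs)
  validateDataset(proteins, sites, profiles)
}

# Labelled dataset with a clear class separation along the first
# dimensions; optionally fully separable.
separableDataset <- function(n = 40, p = 8, gap = 4, seed = 1) {
  set.seed(seed)
  y <- rep(c(1L, 0L), length.out = n)
  x <- matrix(rnorm(n * p), n, p)
  x[y == 1L, 1:2] <- x[y == 1L, 1:2] + gap
  new("GlycDataset", x = x, y = y,
      keys = data.frame(protein_id = sprintf("P%03d", seq_len(n)),
                        position = seq_len(n)))
}

randomDataset <- function(n, p, posFrac = 0.3, seed = 1) {
  set.seed(seed)
  npos <- max(1L, round(posFrac * n))
  y <- c(rep(1L, npos), rep(0L, n - npos))[sample.int(n)]
  new("GlycDataset", x = matrix(rnorm(n * p), n, p), y = y,
      keys = data.frame(protein_id = sprintf("P%03d", seq_len(n)),
                        position = seq_len(n)))
}

# Brute-force kNN cleaning oracle: full scaled distance matrix via
# dist(), per-positive sort over all negatives, union. Independent of
# the implementation's per-positive partial computation.
bruteKnnRemoved <- function(dataset, k) {
  x <- dataset@x
  mins <- apply(x, 2, min); maxs <- apply(x, 2, max)
  rng <- maxs - mins
  xs <- sweep(x, 2, mins, "-")
  for (j in seq_len(ncol(xs)))
    xs[, j] <- if (rng[j] == 0) 0 else xs[, j] / rng[j]
  D <- as.matrix(dist(xs))
  pos <- which(dataset@y == 1L); neg <- which(dataset@y == 0L)
  removed <- integer(0)
  for (i in pos) {
    d <- D[i, neg]
    ord <- order(d, seq_along(neg))
    removed <- union(removed, neg[head(ord, min(k, length(neg)))])
  }
  sort(removed)
}

# Pairwise-comparison AUC oracle: explicit double loop over
# positive-negative pairs, ties counting one half.
aucOracle <- function(truth, scores) {
  sp <- scores[truth == 1]; sn <- scores[truth == 0]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# Write a minimal spd3 file for a profile-free parser test.
writeSpd3Text <- function(path, rows, header = TRUE) {
  lines <- character(0)
  if (header)
    lines <- "# index AA SS ASA Phi Psi Theta(i-1=>i+1) Tau(i-2=>i+2) P(C) P(E) P(H)"
  writeLines(c(lines, rows), path)
}
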