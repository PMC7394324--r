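test_that("readFasta parses records, ids and lengths", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">P1 some description", "ACDKG"), f)
  seqs <- readFasta(f)
  expect_length(seqs, 1L)
  expect_identical(names(seqs), "P1")
  expect_equal(Biostrings::width(seqs), 5L)

  # no length restriction: a multi-thousand-residue record is fine
  set.seed(4008)
  long <- paste(sample(c("A", "C", "D", "K"), 4008, replace = TRUE),
                collapse = "")
  writeLines(c(">Q86XX4-like", long), f)
  expect_equal(Biostrings::width(readFasta(f)), 4008L)
})

test_that("readFasta rejects duplicates and empties, strips gaps", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">A", "MK", ">A", "MK"), f)
  expect_error(readFasta(f), "duplicate")

  writeLines(c(">A", "MK*", ">B", "ac-d"), f)
  expect_warning(seqs <- readFasta(f), "stripped")
  expect_identical(as.character(seqs), c(A = "MK", B = "ACD"))

  writeLines(character(0), f)
  expect_error(readFasta(f))
})

test_that("FASTA write/read round-trips", {
  seqs <- Biostrings::AAStringSet(c(P1 = "ACDKG", P2 = "MKWWR"))
  f <- withr::local_tempfile(fileext = ".fasta")
  writeFasta(seqs, f)
  back <- readFasta(f)
  expect_identical(as.character(back), as.character(seqs))
})

test_that("readSiteAnnotations parses rows, labels and headers", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("P1\t4\t1", f)
  ann <- readSiteAnnotations(f)
  expect_identical(ann$position, 4L)
  expect_identical(ann$label, 1L)

  writeLines(c("protein_id\tposition\tlabel", "P1\t4\tglycated",
               "P2\t9\tnon-glycated"), f)
  ann <- readSiteAnnotations(f)
  expect_identical(ann$label, c(1L, 0L))
})

test_that("readSiteAnnotations flags bad rows with line numbers", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("P1\t4\t1", "P1\t4\t0"), f)
  expect_error(readSiteAnnotations(f), "line 2.*duplicate")
  writeLines(c("P1\tx\t1"), f)
  expect_error(readSiteAnnotations(f), "line 1.*integer")
  writeLines(c("P1\t4\tmaybe"), f)
  expect_error(readSiteAnnotations(f), "label")
})

test_that("annotation write/read round-trips", {
  ann <- data.frame(protein_id = c("P1", "P2"), position = c(4L, 9L),
                    label = c(1L, 0L), stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeSiteAnnotations(ann, f)
  expect_identical(readSiteAnnotations(f), ann)
})

test_that("parseSpd3 maps columns to features (coil listed first)", {
  f <- withr::local_tempfile(fileext = ".spd3")
  writeSpd3Text(f, c(
    "1 A C 50.0 -60.0 130.0 95.0 -160.0 0.5 0.2 0.3",
    "2 C C 40.0 -70.0 120.0 90.0 -150.0 0.4 0.3 0.3",
    "3 D E 30.0 -80.0 110.0 85.0 -140.0 0.2 0.7 0.1",
    "4 K C 102.1 -65.0 140.0 91.2 -170.3 0.6 0.1 0.3",
    "5 G H 20.0 -55.0 100.0 80.0 -130.0 0.1 0.1 0.8"))
  prot <- c(P1 = "ACDKG")
  prof <- parseSpd3(f, prot)
  expect_s4_class(prof, "StructuralProfile")
  expect_equal(nrow(featureMatrix(prof)), 5L)
  k <- featureMatrix(prof)[4, ]
  expect_equal(unname(k), c(102.1, -65.0, 140.0, 91.2, -170.3,
                            0.3, 0.1, 0.6))  # (ph, pe, pc) from P(H/E/C)
})

test_that("parseSpd3 works without a header (positional columns)", {
  f <- withr::local_tempfile(fileext = ".spd3")
  writeSpd3Text(f, c("1 M C 50.0 -60.0 130.0 95.0 -160.0 0.5 0.2 0.3",
                     "2 K H 60.0 -50.0 120.0 90.0 -150.0 0.1 0.2 0.7"),
                header = FALSE)
  prof <- parseSpd3(f, c(PX = "MK"))
  expect_equal(unname(featureMatrix(prof)[2, "ph"]), 0.7)
})

test_that("parseSpd3 rejects mismatches and bad numerics", {
  f <- withr::local_tempfile(fileext = ".spd3")
  writeSpd3Text(f, c("1 A C 50 -60 130 95 -160 0.5 0.2 0.3",
                     "2 C C 40 -70 120 90 -150 0.4 0.3 0.3",
                     "3 E C 30 -80 110 85 -140 0.2 0.7 0.1"))
  expect_error(parseSpd3(f, c(P1 = "ACD")), "mismatch at position 3")

  writeSpd3Text(f, c("1 A C 50 -60 130 95 -160 0.5 0.2 0.3"))
  expect_error(parseSpd3(f, c(P1 = "ACD")), "3 residues")

  writeSpd3Text(f, c("1 A C oops -60 130 95 -160 0.5 0.2 0.3"))
  expect_error(parseSpd3(f, c(P1 = "A")), "row 1")
})

test_that("spd3 write/parse round-trips within 1e-6 relative", {
  prof <- tinyProfile("PX", "ACDKGAMKLWYTRK", seed = 3)
  f <- withr::local_tempfile(fileext = ".spd3")
  writeSpd3(prof, f)
  back <- parseSpd3(f, c(PX = "ACDKGAMKLWYTRK"))
  expect_equal(featureMatrix(back), featureMatrix(prof),
               tolerance = 1e-6)
})

test_that("validateDataset enforces lysine sites and profile coverage", {
  proteins <- Biostrings::AAStringSet(c(P1 = "ACDKG"))
  profiles <- list(P1 = tinyProfile("P1", "ACDKG"))
  ok <- data.frame(protein_id = "P1", position = 4L, label = 1L)
  bundle <- validateDataset(proteins, ok, profiles)
  expect_equal(unname(bundleCounts(bundle)), c(1L, 1L, 0L))

  bad <- data.frame(protein_id = "P1", position = 1L, label = 1L)
  expect_error(validateDataset(proteins, bad, profiles),
               "non-lysine.*P1:1")
  expect_error(validateDataset(proteins, ok, list()),
               "missing structural profile")
  unknown <- data.frame(protein_id = "P9", position = 1L, label = 0L)
  expect_error(validateDataset(proteins, unknown, profiles),
               "unknown protein")
})

test_that("validateDataset is idempotent and order-independent", {
  b1 <- tinyBundle()
  shuffled <- b1@sites[c(4, 1, 6, 3, 2, 5), ]
  b2 <- validateDataset(b1@proteins, shuffled, b1@profiles)
  expect_identical(b1@sites, b2@sites)
  b3 <- validateDataset(b2@proteins, b2@sites, b2@profiles)
  expect_identical(b2@sites, b3@sites)
})
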