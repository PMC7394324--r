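#' End-to-end pipeline configuration
#'
#' Aggregates every stage's settings with the task's standard defaults:
#' 13-residue window, k = 16 neighbour cleaning, polynomial kernel
#' (gamma = 0.03125, coef0 = 0, degree = 3) at C = 512, and 6/8/10-fold
#' cross-validation averaged over 50 repeats.
#'
#' @param fastaPath,sitesPath,spd3Dir input artifact locations.
#' @param outDir output directory for models/reports/CSVs.
#' @param window a [windowConfig()].
#' @param filter a [knnFilterConfig()].
#' @param kernel a [kernelParams()].
#' @param C soft-margin cost.
#' @param kfolds fold counts to evaluate.
#' @param repeats CV repeats to average.
#' @param jackknife also run leave-one-out during [runEvaluate()].
#' @param filterPlacement `"pre-cv"` (filter once before CV, the
#'   replicated protocol) or `"within-fold"` (leakage-free variant:
#'   filter each training fold only).
#' @param seed master seed for all randomness.
#' @return list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(fastaPath = NULL, sitesPath = NULL,
                           spd3Dir = NULL, outDir = ".",
                           window = windowConfig(),
                           filter = knnFilterConfig(),
                           kernel = kernelParams(), C = 512,
                           kfolds = c(6L, 8L, 10L), repeats = 50L,
                           jackknife = FALSE,
                           filterPlacement = c("pre-cv", "within-fold"),
                           seed = 1L) {
  structure(list(fastaPath = fastaPath, sitesPath = sitesPath,
                 spd3Dir = spd3Dir, outDir = outDir, window = window,
                 filter = filter, kernel = kernel, C = C,
                 kfolds = as.integer(kfolds),
                 repeats = as.integer(repeats),
                 jackknife = isTRUE(jackknife),
                 filterPlacement = match.arg(filterPlacement),
                 seed = as.integer(seed)), class = "PipelineConfig")
}

#' Read a pipeline configuration from a flat key = value file
#'
#' Sections in square brackets group keys
#' (`[paths] fasta = ..., sites = ..., spd3_dir = ..., out_dir = ...`;
#' `[window] delta`; `[filter] k, mode`; `[model] C, gamma, coef0,
#' degree`; `[cv] kfolds, repeats, jackknife, filter_placement`;
#' `[seed] seed`). Unknown keys are an error.
#'
#' @param path config file.
#' @return a `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  section <- ""
  kv <- list()
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("\\[|\\]", "", ln)
    } else {
      parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(parts) != 2L)
        stop("malformed config line: ", ln)
      kv[[paste0(section, ".", trimws(parts[1]))]] <- trimws(parts[2])
    }
  }
  get <- function(key, default) {
    if (is.null(kv[[key]])) default else kv[[key]]
  }
  known <- c("paths.fasta", "paths.sites", "paths.spd3_dir",
             "paths.out_dir", "window.delta", "filter.k", "filter.mode",
             "model.C", "model.gamma", "model.coef0", "model.degree",
             "cv.kfolds", "cv.repeats", "cv.jackknife",
             "cv.filter_placement", "seed.seed")
  unknown <- setdiff(names(kv), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  pipelineConfig(
    fastaPath = get("paths.fasta", NULL),
    sitesPath = get("paths.sites", NULL),
    spd3Dir = get("paths.spd3_dir", NULL),
    outDir = get("paths.out_dir", "."),
    window = windowConfig(as.integer(get("window.delta", 13L))),
    filter = knnFilterConfig(
      k = as.integer(get("filter.k", 16L)),
      mode = get("filter.mode", "positive-neighborhood")),
    kernel = kernelParams(
      gamma = as.numeric(get("model.gamma", 0.03125)),
      coef0 = as.numeric(get("model.coef0", 0)),
      degree = as.integer(get("model.degree", 3L))),
    C = as.numeric(get("model.C", 512)),
    kfolds = as.integer(strsplit(get("cv.kfolds", "6,8,10"),
                                 ",")[[1]]),
    repeats = as.integer(get("cv.repeats", 50L)),
    jackknife = as.logical(get("cv.jackknife", "FALSE")),
    filterPlacement = get("cv.filter_placement", "pre-cv"),
    seed = as.integer(get("seed.seed", 1L)))
}

.log <- function(...) message("[GlycSite] ", sprintf(...))

## Shared front half of train/evaluate: load, validate, segment, encode.
.loadEncoded <- function(config) {
  .log("loading bundle: %s", config$fastaPath)
  bundle <- readBundle(config$fastaPath, config$sitesPath,
                       config$spd3Dir)
  counts <- bundleCounts(bundle)
  .log("validated %d proteins, %d glycated / %d non-glycated sites",
       counts["n_proteins"], counts["n_pos"], counts["n_neg"])
  .log("segmenting with delta=%d (sigma=%d)", config$window$delta,
       config$window$sigma)
  segs <- segmentDataset(bundle, config$window)
  ds <- assembleDataset(segs, bundle@profiles)
  .log("encoded %d sites x %d features", length(ds), ncol(ds@x))
  list(bundle = bundle, dataset = ds, counts = counts)
}

#' Train a model end to end
#'
#' load -> validate -> segment -> encode -> kNN-clean -> fit scaler and
#' SVM on all retained samples -> serialize. The report records pre- and
#' post-filter class counts and the parameters actually used.
#'
#' @param config a [pipelineConfig()] with paths set.
#' @return list with `model` ([PolySVM-class]), `modelPath`, `report`.
#' @export
runTrain <- function(config) {
  enc <- .loadEncoded(config)
  .log("kNN cleaning with k=%d (%s)", config$filter$k,
       config$filter$mode)
  cleaned <- knnClean(enc$dataset, config$filter)
  post <- c(n_pos = sum(cleaned$dataset@y == 1L),
            n_neg = sum(cleaned$dataset@y == 0L))
  .log("negatives %d -> %d (positives unchanged at %d)",
       enc$counts["n_neg"], post["n_neg"], post["n_pos"])
  .log("training SVM: C=%g, kernel (gamma=%g, coef0=%g, degree=%d)",
       config$C, config$kernel$gamma, config$kernel$coef0,
       config$kernel$degree)
  model <- trainSVM(cleaned$dataset, C = config$C,
                    kernel = config$kernel, seed = config$seed)
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  modelPath <- file.path(config$outDir, "model.txt")
  writeModel(model, modelPath)
  writeRemovalReport(cleaned, file.path(config$outDir,
                                        "knn_removals.tsv"))
  report <- list(pre = enc$counts, post = post,
                 n_sv = nrow(model@supportVectors),
                 window = config$window, filter = config$filter,
                 kernel = config$kernel, C = config$C,
                 seed = config$seed)
  .log("model written to %s (%d support vectors)", modelPath,
       report$n_sv)
  list(model = model, modelPath = modelPath, report = report)
}

#' Evaluate the pipeline by repeated cross-validation
#'
#' Runs the configured k-fold schemes (and optionally the jackknife) on
#' the encoded, kNN-cleaned dataset, writing per-run and summary CSVs
#' plus ROC points.
#'
#' @param config a [pipelineConfig()] with paths set.
#' @return named list of [CVSummary-class] objects.
#' @export
runEvaluate <- function(config) {
  enc <- .loadEncoded(config)
  withinFold <- NULL
  ds <- enc$dataset
  if (config$filterPlacement == "pre-cv") {
    cleaned <- knnClean(ds, config$filter)
    ds <- cleaned$dataset
    .log("pre-CV kNN cleaning: negatives %d -> %d",
         enc$counts["n_neg"], sum(ds@y == 0L))
  } else {
    withinFold <- config$filter
    .log("within-fold kNN cleaning enabled (leakage-free variant)")
  }
  summaries <- list()
  for (k in config$kfolds) {
    .log("%d-fold CV x %d repeats (seed %d)", k, config$repeats,
         config$seed)
    summaries[[sprintf("%d-fold", k)]] <-
      runKFoldCV(ds, C = config$C, kernel = config$kernel,
                 cv = cvConfig(k = k, repeats = config$repeats,
                               seed = config$seed),
                 knnWithinFold = withinFold)
  }
  if (config$jackknife) {
    .log("jackknife (leave-one-out) over %d samples", length(ds))
    summaries[["jackknife"]] <- runJackknife(ds, C = config$C,
                                             kernel = config$kernel)
  }
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  writeCvResults(summaries, config$outDir)
  # ROC points from a deterministic single partition of the largest k
  sc <- fitScaler(ds@x)
  model <- trainSVM(ds, C = config$C, kernel = config$kernel,
                    scaler = sc)
  roc <- rocPoints(ds@y, decisionValue(model, ds@x))
  utils::write.csv(roc, file.path(config$outDir, "roc_points.csv"),
                   row.names = FALSE)
  invisible(summaries)
}

#' Predict glycation for every lysine of new proteins
#'
#' Applies a serialized model to all lysines of the supplied sequences,
#' using their structural profiles; emits one row per lysine with the
#' decision value and predicted label.
#'
#' @param modelPath file written by [writeModel()].
#' @param fastaPath FASTA of query proteins.
#' @param spd3Dir directory with `<id>.spd3` per query protein.
#' @param outPath optional TSV output path.
#' @return data.frame `protein_id, position, decision, label`.
#' @export
runPredict <- function(modelPath, fastaPath, spd3Dir, outPath = NULL) {
  model <- readModel(modelPath)
  delta <- ncol(model@supportVectors) %/% length(RESIDUE_FEATURES)
  if (delta * length(RESIDUE_FEATURES) != ncol(model@supportVectors))
    stop("model dimension is not a multiple of the per-residue ",
         "feature count")
  cfg <- windowConfig(delta)
  proteins <- readFasta(fastaPath)
  rows <- list()
  for (pid in names(proteins)) {
    seq <- as.character(proteins[[pid]])
    kpos <- which(strsplit(seq, "")[[1]] == "K")
    if (!length(kpos)) next
    prof <- parseSpd3(file.path(spd3Dir, paste0(pid, ".spd3")),
                      proteins[pid])
    one <- as.character(proteins[pid])
    names(one) <- pid
    for (p in kpos) {
      seg <- extractSegment(one, p, cfg)
      v <- buildFeatureVector(seg, prof)
      d <- decisionValue(model, v)
      rows[[length(rows) + 1L]] <-
        data.frame(protein_id = pid, position = p, decision = d,
                   label = as.integer(d > 0),
                   stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(protein_id = character(0),
                         position = integer(0), decision = numeric(0),
                         label = integer(0))
  if (!is.null(outPath)) {
    con <- file(outPath, "wb")
    writeLines(c("protein_id\tposition\tdecision\tlabel",
                 if (nrow(out))
                   sprintf("%s\t%d\t%.10g\t%d", out$protein_id,
                           out$position, out$decision, out$label)),
               con)
    close(con)
  }
  out
}
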