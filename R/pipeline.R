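#' Pipeline configuration
#'
#' Bundles the per-stage configurations (simulation regimes, filter rules,
#' classifier settings, scoring and validation constants) with a single
#' global seed. A run with the same configuration and seed is bit-identical.
#'
#' @slot simPlant,simHuman [SimConfig-class] for the two labeling regimes.
#' @slot filter A [FilterConfig-class].
#' @slot model A [ModelConfig-class].
#' @slot nLabeledCands,nUnlabeledCands,nJunk Benchmark sizes.
#' @slot scoreC Stability constant of the candidate score.
#' @slot minFold,minN Validation-caller thresholds.
#' @slot topK Candidates forwarded to annotation.
#' @slot seed Global seed; stage seeds are derived from it.
#' @aliases PipelineConfig
#' @exportClass PipelineConfig
setClass("PipelineConfig",
  representation(simPlant = "SimConfig", simHuman = "SimConfig",
                 filter = "FilterConfig", model = "ModelConfig",
                 nLabeledCands = "integer", nUnlabeledCands = "integer",
                 nJunk = "integer", scoreC = "numeric", minFold = "numeric",
                 minN = "integer", topK = "integer", seed = "integer"))

#' @param simPlant,simHuman,filter,model,nLabeledCands,nUnlabeledCands See slots.
#' @param nJunk,scoreC,minFold,minN,topK,seed See slots.
#' @rdname PipelineConfig-class
#' @export
pipelineConfig <- function(simPlant = simConfig(rho = 0.15, mixFraction = 1),
                           simHuman = simConfig(rho = 0.15, mixFraction = 0.2),
                           filter = filterConfig(),
                           model = modelConfig(),
                           nLabeledCands = 272, nUnlabeledCands = 928,
                           nJunk = 20, scoreC = 0.01, minFold = 1.5,
                           minN = 3, topK = 20, seed = 1) {
  new("PipelineConfig", simPlant = simPlant, simHuman = simHuman,
      filter = filter, model = model,
      nLabeledCands = as.integer(nLabeledCands),
      nUnlabeledCands = as.integer(nUnlabeledCands),
      nJunk = as.integer(nJunk), scoreC = scoreC, minFold = minFold,
      minN = as.integer(minN), topK = as.integer(topK),
      seed = as.integer(seed))
}

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig: seed", object@seed, "\n",
      " benchmark:", object@nLabeledCands, "labeled +",
      object@nUnlabeledCands, "unlabeled +", object@nJunk, "junk candidates\n",
      " regimes: plant rho =", object@simPlant@rho, "f =",
      object@simPlant@mixFraction, "| human rho =", object@simHuman@rho,
      "f =", object@simHuman@mixFraction, "\n")
})

.REQUIRED_CONFIG_KEYS <- c("seed", "rho_plant", "rho_human",
                           "mix_fraction_plant", "mix_fraction_human",
                           "n_labeled_cands", "n_unlabeled_cands")

#' Read a pipeline configuration from a flat key-value file
#'
#' Recognized keys: `seed`, `rho_plant`, `rho_human`, `mix_fraction_plant`,
#' `mix_fraction_human`, `noise_sigma`, `detection_limit`, `base_intensity`,
#' `n_labeled_samples`, `n_unlabeled_samples`, `n_labeled_cands`,
#' `n_unlabeled_cands`, `n_junk`, `score_c`, `min_fold`, `min_n`, `top_k`.
#' Missing required keys are an error naming the key.
#'
#' @param path Config file in `key = value` format.
#' @return A [PipelineConfig-class].
#' @export
readPipelineConfig <- function(path) {
  kv <- readKeyValue(path)
  missing <- setdiff(.REQUIRED_CONFIG_KEYS, names(kv))
  if (length(missing))
    stop(sprintf("config is missing required key(s): %s",
                 paste(missing, collapse = ", ")))
  num <- function(k, d) if (k %in% names(kv)) as.numeric(kv[[k]]) else d
  seed <- as.integer(num("seed", 1))
  simShared <- list(noiseSigma = num("noise_sigma", 0.2),
                    detectionLimit = num("detection_limit", 200),
                    baseIntensity = num("base_intensity", 1e5),
                    nLabeledSamples = num("n_labeled_samples", 8),
                    nUnlabeledSamples = num("n_unlabeled_samples", 8))
  mk <- function(rho, f) do.call(simConfig, c(list(
    rho = rho, mixFraction = f, seed = seed), simShared))
  pipelineConfig(
    simPlant = mk(num("rho_plant", 0.15), num("mix_fraction_plant", 1)),
    simHuman = mk(num("rho_human", 0.15), num("mix_fraction_human", 0.2)),
    nLabeledCands = num("n_labeled_cands", 272),
    nUnlabeledCands = num("n_unlabeled_cands", 928),
    nJunk = num("n_junk", 20), scoreC = num("score_c", 0.01),
    minFold = num("min_fold", 1.5), minN = num("min_n", 3),
    topK = num("top_k", 20), seed = seed)
}

#' @rdname readPipelineConfig
#' @param cfg A [PipelineConfig-class].
#' @export
writePipelineConfig <- function(cfg, path) {
  writeKeyValue(list(
    seed = cfg@seed,
    rho_plant = cfg@simPlant@rho, rho_human = cfg@simHuman@rho,
    mix_fraction_plant = cfg@simPlant@mixFraction,
    mix_fraction_human = cfg@simHuman@mixFraction,
    noise_sigma = cfg@simPlant@noiseSigma,
    detection_limit = cfg@simPlant@detectionLimit,
    base_intensity = cfg@simPlant@baseIntensity,
    n_labeled_samples = cfg@simPlant@nLabeledSamples,
    n_unlabeled_samples = cfg@simPlant@nUnlabeledSamples,
    n_labeled_cands = cfg@nLabeledCands,
    n_unlabeled_cands = cfg@nUnlabeledCands,
    n_junk = cfg@nJunk, score_c = cfg@scoreC, min_fold = cfg@minFold,
    min_n = cfg@minN, top_k = cfg@topK), path)
}

#' Run the full pipeline: simulate, filter, train, score, validate, annotate
#'
#' Executes the stages in order on the built-in synthetic benchmark and
#' writes every interchange table plus a JSON manifest (inputs, outputs,
#' seeds, md5 checksums, package version) to `outDir`. No stage mutates
#' another stage's outputs, and a rerun with the same configuration and
#' seed produces bit-identical files. A stage failure aborts with the stage
#' name and context.
#'
#' @param cfg A [PipelineConfig-class].
#' @param outDir Output directory (created if needed).
#' @param verbose Emit progress messages to stderr.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest path.
#' @export
runPipeline <- function(cfg = pipelineConfig(), outDir, verbose = TRUE) {
  stopifnot(is(cfg, "PipelineConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message("[deutracer] ", ...)
  stage <- function(name, expr) {
    say("stage: ", name)
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  fp <- function(f) file.path(outDir, f)

  bench <- stage("simulate", {
    b <- makeBenchmark(cfg@simPlant, cfg@simHuman, cfg@nLabeledCands,
                       cfg@nUnlabeledCands, cfg@nJunk, seed = cfg@seed)
    writeCandidates(b$candidates, fp("candidates.csv"))
    writeDelim(b$truth, fp("truth.csv"))
    b
  })

  filt <- stage("filter", {
    fr <- applyFilters(bench$candidates, cfg@filter)
    writeCandidates(fr$kept, fp("kept.csv"))
    writeDelim(filterReport(fr$rejected), fp("filter_report.csv"))
    fr
  })

  model <- stage("train", {
    ts <- buildTrainingSet(filt$kept, bench$truth)
    trainClassifier(ts, cfg@model, cv = FALSE)
  })

  scores <- stage("score", {
    sc <- scoreCandidates(model, filt$kept, c = cfg@scoreC)
    writeScores(sc, fp("scores.csv"))
    sc
  })

  calls <- stage("validate", {
    rs <- ratioSummary(filt$kept)
    writeDelim(rs, fp("ratio_summary.csv"))
    lc <- callLabels(filt$kept, minFold = cfg@minFold, minN = cfg@minN)
    writeDelim(lc, fp("label_calls.csv"))
    lc
  })

  annot <- stage("annotate", {
    top <- utils::head(scores, cfg@topK)
    info <- candidateInfo(filt$kept)
    m <- match(top$candidate_id, info$candidate_id)
    adduct <- ifelse(info$ion_mode[m] == "positive", "[M+H]+", "[M-H]-")
    neutral <- neutralMass(info$base_mz[m], adduct)
    lib <- metaboliteLibrary("all")
    best <- lapply(neutral, function(nm) {
      hits <- matchFormula(nm, lib, tolPpm = 10)
      if (nrow(hits)) hits[1, ] else
        data.frame(name = NA_character_, mass = NA_real_, ppm = NA_real_)
    })
    best <- do.call(rbind, best)
    an <- data.frame(candidate_id = top$candidate_id,
                     mz = info$base_mz[m], adduct = adduct,
                     neutral_mass = neutral,
                     formula_match = best$name, match_ppm = best$ppm,
                     stringsAsFactors = FALSE)
    writeDelim(an, fp("annotation.csv"))
    an
  })

  manifestPath <- stage("manifest", {
    files <- c("candidates.csv", "truth.csv", "kept.csv",
               "filter_report.csv", "scores.csv", "ratio_summary.csv",
               "label_calls.csv", "annotation.csv")
    manifest <- list(
      package = "deutracer",
      version = as.character(utils::packageVersion("deutracer")),
      seed = cfg@seed,
      config = list(
        rho_plant = cfg@simPlant@rho, rho_human = cfg@simHuman@rho,
        mix_fraction_plant = cfg@simPlant@mixFraction,
        mix_fraction_human = cfg@simHuman@mixFraction,
        n_labeled_cands = cfg@nLabeledCands,
        n_unlabeled_cands = cfg@nUnlabeledCands, n_junk = cfg@nJunk,
        n_trees = cfg@model@nTrees, max_depth = cfg@model@maxDepth,
        min_instances = cfg@model@minInstances,
        score_c = cfg@scoreC, min_fold = cfg@minFold, min_n = cfg@minN),
      outputs = lapply(stats::setNames(files, files), function(f)
        list(md5 = unname(tools::md5sum(fp(f))))))
    jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    fp("manifest.json")
  })
  say("done: ", outDir)
  invisible(list(benchmark = bench, filtered = filt, model = model,
                 scores = scores, calls = calls, annotation = annot,
                 manifest = manifestPath))
}
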