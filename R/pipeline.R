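# Config-driven orchestration: simulate or load a cohort, then run the
# full analysis (cohort summary, coverage-standardized alpha diversity
# with LRT association tests, rarefied UniFrac distances, joint
# PERMANOVA with distance-based effect sizes, PCoA, taxon signatures),
# writing one TSV per report. Outputs are byte-identical across runs
# with the same config, and stages can be resumed from cached files.

.roundHalfUp <- function(x, digits = 1) {
  s <- 10^digits
  floor(x * s + 0.5) / s
}

#' Cohort summary stratified by age
#'
#' Per age stratum (split at `ageCutoff` years): count and percentage
#' (one decimal, half-up rounding) of females, whites, subjects with
#' BMI above 30 kg/m^2, alcohol users and smokers.
#'
#' @param meta a [SampleMetadata-class] with the canonical schema.
#' @param ageCutoff stratum boundary in years (default 50).
#' @return data.frame with columns `stratum`, `variable`, `count`,
#'   `n`, `percent`.
#' @export
summarizeCohort <- function(meta, ageCutoff = 50) {
  md <- sampleData(meta)
  if (!"age" %in% names(md) || all(is.na(md$age))) stop("age missing from metadata")
  strata <- list()
  strata[[sprintf("age<%d", ageCutoff)]] <- which(md$age < ageCutoff)
  strata[[sprintf("age>=%d", ageCutoff)]] <- which(md$age >= ageCutoff)
  vars <- list(`Sex, F` = function(d) d$sex == "F",
               `Race, W` = function(d) d$race == "white",
               `BMI >30` = function(d) d$bmi > 30,
               `Alcohol use (Y)` = function(d) d$alcohol == "Y",
               `Smoking (Y)` = function(d) d$tobacco == "Y")
  rows <- list()
  for (s in names(strata)) {
    d <- md[strata[[s]], , drop = FALSE]
    n <- nrow(d)
    for (v in names(vars)) {
      cnt <- sum(vars[[v]](d), na.rm = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = s, variable = v, count = cnt, n = n,
        percent = if (n > 0) .roundHalfUp(100 * cnt / n, 1) else NA_real_)
    }
  }
  do.call(rbind, rows)
}

#' Canonicalize a pipeline configuration
#'
#' @param config a list, or the path to a YAML file. Recognized
#'   fields: `simulate` (list of [simConfig] arguments, or TRUE for
#'   defaults) or `input` (list with paths `counts`, `tree`,
#'   `taxonomy`, `metadata`); `covariates`; `batch`; `nPerm`; `seed`;
#'   `rarefyDepth`; `targetCoverage`; `qThreshold`.
#' @return validated config list with defaults filled in.
#' @export
pipelineConfig <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(simulate = NULL, input = NULL,
                   covariates = c("age", "sex", "bmi", "race", "tobacco",
                                  "alcohol"),
                   batch = "batch", nPerm = 1000, seed = 7,
                   rarefyDepth = "auto", targetCoverage = "auto",
                   qThreshold = 0.10,
                   signatureCovariates = c("bmi", "sex", "race", "tobacco",
                                           "alcohol"))
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  if (is.null(config$simulate) && is.null(config$input))
    stop("config needs either a 'simulate' block or an 'input' block")
  if (!is.null(config$simulate) && !is.null(config$input))
    stop("config must not have both 'simulate' and 'input'")
  if (config$nPerm < 1) stop("nPerm must be >= 1")
  config
}

.writeReport <- function(df, path, provenance) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# ", provenance), con)
  df2 <- df
  for (j in seq_along(df2)) if (is.numeric(df2[[j]]))
    df2[[j]] <- vapply(df2[[j]], function(v)
      if (is.na(v)) "NA" else format(v, digits = 15, scientific = FALSE,
                                     trim = TRUE), "")
  write.table(df2, con, sep = "\t", quote = FALSE, row.names = FALSE,
              eol = "\n")
}

#' Run the full analysis pipeline
#'
#' Executes simulate/load, alignment, cohort summary, alpha diversity
#' with LRT tests, rarefaction + UniFrac (both metrics), joint
#' PERMANOVA with R2 / adjusted R2 per covariate, PCoA, and taxon
#' signatures. Artifacts written to `outDir`: `counts.tsv`,
#' `tree.nwk`, `taxonomy.tsv`, `metadata.tsv`, `cohort_summary.tsv`,
#' `alpha.tsv`, `alpha_assoc.tsv`, `dist_unweighted.tsv`,
#' `dist_weighted.tsv`, `beta_assoc.tsv`, `effect_sizes.tsv`,
#' `pcoa.tsv`, `signatures.tsv` and `manifest.yaml`. Runs are
#' byte-identical for identical configs; with `resume = TRUE` a stage
#' whose outputs already exist is skipped (its files are reloaded when
#' later stages need them).
#'
#' @param config pipeline config (list or YAML path), see
#'   [pipelineConfig].
#' @param outDir output directory (created if needed).
#' @param resume reuse existing stage outputs (default FALSE).
#' @return invisibly, a list of the in-memory stage results.
#' @export
runPipeline <- function(config, outDir, resume = FALSE) {
  cfg <- pipelineConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(outDir, f)
  prov <- sprintf("microdemog %s; seed=%s; nPerm=%d",
                  as.character(utils::packageVersion("microdemog")),
                  format(cfg$seed), as.integer(cfg$nPerm))
  done <- function(...) all(file.exists(vapply(list(...), path, "")))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s (fix the inputs/config for this stage and re-run, or use resume=TRUE to keep earlier stages)",
                   name, conditionMessage(e)), call. = FALSE))
    message(sprintf("[%s] done in %.1fs", name,
                    proc.time()[["elapsed"]] - t0))
    res
  }
  results <- list()

  dataFiles <- c("counts.tsv", "tree.nwk", "taxonomy.tsv", "metadata.tsv")
  if (resume && done("counts.tsv", "tree.nwk", "taxonomy.tsv", "metadata.tsv")) {
    message("[data] reusing cached inputs")
    cohort <- list(table = readCountTable(path("counts.tsv")),
                   tree = readNewick(path("tree.nwk")),
                   taxonomy = readTaxonomy(path("taxonomy.tsv")),
                   meta = readSampleMetadata(path("metadata.tsv")))
  } else {
    cohort <- stage("data", {
      if (!is.null(cfg$simulate)) {
        args <- if (isTRUE(cfg$simulate)) list() else cfg$simulate
        if (is.null(args$seed)) args$seed <- cfg$seed
        sc <- do.call(simConfig, args)
        simulateCohort(sc)
      } else {
        list(table = readCountTable(cfg$input$counts),
             tree = readNewick(cfg$input$tree),
             taxonomy = readTaxonomy(cfg$input$taxonomy),
             meta = readSampleMetadata(cfg$input$metadata))
      }
    })
    al <- alignExperiment(cohort$table, cohort$meta, cohort$tree,
                          cohort$taxonomy)
    cohort <- list(table = al$table, meta = al$meta, tree = al$tree,
                   taxonomy = cohort$taxonomy)
    writeCountTable(cohort$table, path("counts.tsv"))
    ape::write.tree(cohort$tree, path("tree.nwk"))
    writeTaxonomy(cohort$taxonomy, path("taxonomy.tsv"))
    writeSampleMetadata(cohort$meta, path("metadata.tsv"))
  }
  results$cohort <- cohort

  if (!(resume && done("cohort_summary.tsv"))) {
    summary <- stage("summary", summarizeCohort(cohort$meta))
    .writeReport(summary, path("cohort_summary.tsv"), prov)
    results$summary <- summary
  }

  if (!(resume && done("alpha.tsv", "alpha_assoc.tsv"))) {
    alpha <- stage("alpha", alphaDiversity(cohort$table,
                                           targetCoverage = cfg$targetCoverage))
    .writeReport(alpha, path("alpha.tsv"), prov)
    assocA <- stage("alpha-assoc", {
      rows <- list()
      for (metric in c("observed_otus", "shannon")) {
        v <- alpha$value[alpha$metric == metric]
        names(v) <- alpha$sample_id[alpha$metric == metric]
        for (cv in cfg$covariates) {
          r <- alphaLRT(v, cohort$meta, designSpec(cv, batch = cfg$batch))
          rows[[length(rows) + 1L]] <- cbind(metric = metric, r)
        }
      }
      do.call(rbind, rows)
    })
    .writeReport(assocA, path("alpha_assoc.tsv"), prov)
    results$alpha <- alpha
    results$alphaAssoc <- assocA
  }

  if (resume && done("dist_unweighted.tsv", "dist_weighted.tsv")) {
    message("[beta] reusing cached distance matrices")
    dists <- list(unweighted = readDistanceMatrix(path("dist_unweighted.tsv")),
                  weighted = readDistanceMatrix(path("dist_weighted.tsv")))
  } else {
    dists <- stage("beta", {
      list(unweighted = pairwiseDistances(cohort$table, cohort$tree,
                                          "unweighted",
                                          rarefyDepth = cfg$rarefyDepth,
                                          seed = .substream(cfg$seed, "beta")),
           weighted = pairwiseDistances(cohort$table, cohort$tree,
                                        "weighted",
                                        rarefyDepth = cfg$rarefyDepth,
                                        seed = .substream(cfg$seed, "beta")))
    })
    writeDistanceMatrix(dists$unweighted, path("dist_unweighted.tsv"))
    writeDistanceMatrix(dists$weighted, path("dist_weighted.tsv"))
  }
  results$dists <- dists

  if (!(resume && done("beta_assoc.tsv", "effect_sizes.tsv", "pcoa.tsv"))) {
    assocB <- stage("beta-assoc", {
      rows <- list()
      for (metric in names(dists)) {
        for (cv in cfg$covariates) {
          r <- permanovaJoint(dists[[metric]], cohort$meta,
                              designSpec(cv, batch = cfg$batch),
                              nPerm = cfg$nPerm, seed = cfg$seed)
          rows[[length(rows) + 1L]] <- cbind(metric = metric, r)
        }
      }
      do.call(rbind, rows)
    })
    .writeReport(assocB, path("beta_assoc.tsv"), prov)
    eff <- assocB[assocB$metric == "unweighted",
                  c("covariate", "r2", "r2_adj", "n")]
    eff$r2_pct <- .roundHalfUp(100 * eff$r2, 2)
    eff$r2_adj_pct <- .roundHalfUp(100 * pmax(eff$r2_adj, 0), 2)
    .writeReport(eff, path("effect_sizes.tsv"), prov)
    ord <- stage("pcoa", pcoaOrdination(dists$unweighted,
                                        k = min(2, nrow(as.matrix(dists$unweighted)) - 1)))
    co <- as.data.frame(ordCoordinates(ord))
    co <- cbind(sample_id = rownames(co), co)
    .writeReport(co, path("pcoa.tsv"),
                 paste0(prov, "; explained=",
                        paste(sprintf("%.4f", explainedVariance(ord)),
                              collapse = ",")))
    results$betaAssoc <- assocB
    results$effectSizes <- eff
    results$ordination <- ord
  }

  if (!(resume && done("signatures.tsv"))) {
    sig <- stage("signatures",
                 signatureReport(cohort$table, cohort$taxonomy, cohort$meta,
                                 covariates = cfg$signatureCovariates,
                                 qThreshold = cfg$qThreshold,
                                 nPerm = cfg$nPerm, seed = cfg$seed,
                                 batch = cfg$batch))
    .writeReport(sig, path("signatures.tsv"), prov)
    results$signatures <- sig
  }

  manifest <- list(
    package = "microdemog",
    version = as.character(utils::packageVersion("microdemog")),
    seed = cfg$seed,
    substreams = list(beta = .substream(cfg$seed, "beta")),
    nPerm = cfg$nPerm,
    qThreshold = cfg$qThreshold,
    covariates = cfg$covariates,
    nSamples = length(sampleIDs(cohort$table)),
    nOtus = length(otuIDs(cohort$table)),
    simulated = !is.null(cfg$simulate),
    outputs = c(dataFiles, "cohort_summary.tsv", "alpha.tsv",
                "alpha_assoc.tsv", "dist_unweighted.tsv",
                "dist_weighted.tsv", "beta_assoc.tsv", "effect_sizes.tsv",
                "pcoa.tsv", "signatures.tsv"))
  yaml::write_yaml(manifest, path("manifest.yaml"))
  invisible(results)
}
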