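## Known configuration keys, used for strict validation.
.configKeys <- list(
  top = c("seed", "simulate", "input", "qc", "normalize", "top_n",
          "network", "alpha", "permutations"),
  simulate = c("expression", "compendium"),
  simulate_expression = c("nGenes", "nModules", "moduleSize",
                          "nTraitModules", "withinModuleCor",
                          "treatmentEffect", "samplesPerGroup", "noiseSd",
                          "outlierSample", "latents"),
  simulate_compendium = c("nCompounds", "instancesPerCompound", "mimics",
                          "reversers"),
  input = c("matrix", "annotation", "compendium_ranks", "compendium_meta"),
  qc = c("k"),
  network = c("beta", "adjacencyType", "minModuleSize",
              "cutHeightFraction", "mergeDissThreshold"))

checkKeys_ <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown))
    stop("configuration error: unknown key(s) in ", where, ": ",
         paste(unknown, collapse = ", "))
}

#' Read and validate a pipeline configuration
#'
#' The configuration is a YAML file holding every tunable of
#' [runScreen()]: global `seed`, `simulate` blocks (synthetic inputs) or
#' `input` paths, `qc` (`k`), `normalize` (logical), `top_n`, a `network`
#' block (see [networkParams()]), `alpha` and `permutations`. Unknown keys
#' are rejected.
#'
#' @param path YAML file path.
#' @return A validated configuration list.
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  validatePipelineConfig(cfg)
}

#' @rdname readPipelineConfig
#' @param cfg a configuration list (as parsed from YAML).
#' @export
validatePipelineConfig <- function(cfg) {
  checkKeys_(cfg, .configKeys$top, "config")
  if (!is.null(cfg$simulate)) {
    checkKeys_(cfg$simulate, .configKeys$simulate, "simulate")
    checkKeys_(cfg$simulate$expression, .configKeys$simulate_expression,
               "simulate$expression")
    checkKeys_(cfg$simulate$compendium, .configKeys$simulate_compendium,
               "simulate$compendium")
  }
  if (!is.null(cfg$input)) checkKeys_(cfg$input, .configKeys$input, "input")
  if (!is.null(cfg$network))
    checkKeys_(cfg$network, .configKeys$network, "network")
  if (!is.null(cfg$qc)) checkKeys_(cfg$qc, .configKeys$qc, "qc")
  if (is.null(cfg$seed)) cfg$seed <- 1
  cfg
}

stage_ <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full in-silico screening pipeline
#'
#' Executes the stages QC, quantile normalization, variance filtering,
#' module detection, module-trait statistics, signature extraction,
#' connectivity scoring and compound ranking in order, writing every
#' stage's output under `outDir` together with a run manifest
#' (`manifest.json`) recording the configuration hash, the seed, and an
#' MD5 checksum per stage output. Inputs are either read from the `input`
#' paths of the configuration or generated by the `simulate` block. Any
#' stage error aborts with the stage name; outputs of completed stages are
#' retained. Identical (configuration, seed) pairs produce bit-identical
#' outputs.
#'
#' @param cfg configuration list (see [readPipelineConfig()]).
#' @param outDir output directory (created if needed).
#' @return Invisibly, a list with `qc`, `decomposition`, `moduleTrait`,
#'   `signature`, `report` and `manifest`.
#' @export
runScreen <- function(cfg, outDir) {
  cfg <- validatePipelineConfig(cfg)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg$seed
  outputs <- list()  # stage -> file paths
  addOutput <- function(stage, ...) outputs[[stage]] <<- c(...)

  ## --- inputs -------------------------------------------------------------
  simCfg <- cfg$simulate
  truth <- NULL
  if (!is.null(simCfg)) {
    ex <- do.call(simulateExpression,
                  c(simCfg$expression,
                    list(seed = deriveSeed(seed, "expression"))))
    ds <- ex$dataset
    truth <- ex$truth
  } else {
    if (is.null(cfg$input$matrix) || is.null(cfg$input$annotation))
      stop("configuration error: input matrix/annotation paths required ",
           "unless simulation is requested")
    ds <- readExpressionMatrix(cfg$input$matrix, cfg$input$annotation)
  }

  ## --- qc -----------------------------------------------------------------
  qc <- stage_("qc", {
    k <- if (is.null(cfg$qc$k)) 3 else cfg$qc$k
    rep <- sampleQC(ds, k = k)
    writeQCReport(rep, file.path(outDir, "qc.json"))
    rep
  })
  addOutput("qc", file.path(outDir, "qc.json"))
  ds <- dropOutlierSamples(ds, qc)

  ## --- normalize ----------------------------------------------------------
  ds <- stage_("normalize", {
    out <- if (is.null(cfg$normalize) || isTRUE(cfg$normalize))
      quantileNormalize(ds) else ds
    writeExpressionMatrix(out, file.path(outDir, "normalized.tsv"),
                          file.path(outDir, "annotation.tsv"))
    out
  })
  addOutput("normalize", file.path(outDir, "normalized.tsv"),
            file.path(outDir, "annotation.tsv"))

  ## --- filter -------------------------------------------------------------
  ds <- stage_("filter", {
    topN <- if (is.null(cfg$top_n)) 10000 else cfg$top_n
    out <- selectMostVariableGenes(ds, n = topN)
    writeExpressionMatrix(out, file.path(outDir, "filtered.tsv"))
    out
  })
  addOutput("filter", file.path(outDir, "filtered.tsv"))

  ## --- modules ------------------------------------------------------------
  params <- do.call(networkParams, as.list(cfg$network))
  decomp <- stage_("modules", {
    out <- detectModules(ds, params)
    writeModuleAssignment(out, file.path(outDir, "modules.tsv"))
    writeEigengenes(out, file.path(outDir, "eigengenes.tsv"))
    out
  })
  addOutput("modules", file.path(outDir, "modules.tsv"),
            file.path(outDir, "eigengenes.tsv"))

  ## --- module-trait -------------------------------------------------------
  mt <- stage_("module_trait", {
    trait <- as.numeric(sampleGroups(ds) == "treated")
    out <- moduleTraitRelationships(decomp, trait)
    write.table(out, file.path(outDir, "module_trait.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    out
  })
  addOutput("module_trait", file.path(outDir, "module_trait.tsv"))

  ## --- signature ----------------------------------------------------------
  sig <- stage_("signature", {
    alpha <- if (is.null(cfg$alpha)) 0.005 else cfg$alpha
    de <- differentialExpression(ds)
    writeDifferentialExpression(de, file.path(outDir, "de.tsv"))
    s <- buildQuerySignature(de, alpha = alpha)
    writeSignature(s, file.path(outDir, "signature"))
    s
  })
  addOutput("signature", file.path(outDir, "de.tsv"),
            file.path(outDir, "signature_up.grp"),
            file.path(outDir, "signature_down.grp"))

  ## --- connectivity -------------------------------------------------------
  comp <- stage_("connectivity", {
    if (!is.null(simCfg)) {
      sc <- do.call(simulateCompendium,
                    c(list(universe = rownames(ds),
                           upGenes = intersect(truth$upGenes, rownames(ds)),
                           downGenes = intersect(truth$downGenes,
                                                 rownames(ds)),
                           seed = deriveSeed(seed, "compendium")),
                      simCfg$compendium))
      writeCompendium(sc$compendium, file.path(outDir, "compendium.tsv"),
                      file.path(outDir, "compendium_meta.tsv"))
      addOutput("connectivity", file.path(outDir, "compendium.tsv"),
                file.path(outDir, "compendium_meta.tsv"))
      sc$compendium
    } else {
      if (is.null(cfg$input$compendium_ranks) ||
          is.null(cfg$input$compendium_meta))
        stop("compendium paths required unless simulation is requested")
      addOutput("connectivity", cfg$input$compendium_ranks,
                cfg$input$compendium_meta)
      readCompendium(cfg$input$compendium_ranks,
                     cfg$input$compendium_meta)
    }
  })

  ## --- ranking ------------------------------------------------------------
  report <- stage_("ranking", {
    B <- if (is.null(cfg$permutations)) 1000 else cfg$permutations
    rep <- connectivityScreen(sig, comp, B = B,
                              seed = deriveSeed(seed, "connectivity"))
    writeConnectivityReport(rep, file.path(outDir, "instances.tsv"),
                            file.path(outDir, "ranking.tsv"),
                            file.path(outDir, "report.json"))
    rep
  })
  addOutput("ranking", file.path(outDir, "instances.tsv"),
            file.path(outDir, "ranking.tsv"),
            file.path(outDir, "report.json"))

  ## --- manifest -----------------------------------------------------------
  cfgHash <- digestConfig_(cfg)
  manifest <- list(
    config_hash = cfgHash,
    seed = seed,
    stages = lapply(outputs, function(fs)
      lapply(setNames(as.list(fs), basename(fs)),
             function(f) unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(qc = qc, decomposition = decomp, moduleTrait = mt,
                 signature = sig, report = report, manifest = manifest))
}

## Hash of the canonicalized (YAML-serialized) configuration.
digestConfig_ <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg[order(names(cfg))], tmp)
  unname(tools::md5sum(tmp))
}
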