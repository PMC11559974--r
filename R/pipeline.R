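## Pipeline orchestration: simulate -> flow map -> network -> community
## detection -> quality metrics -> report, for the three behavioral
## cases.  The preferred-depth and suitable-habitat cases share one
## simulation so stochastic transport differences cannot cause
## discrepancies between them.

#' Assemble a run configuration
#'
#' A plain list gathering every knob of a pipeline run.  All seeds are
#' explicit; nothing is seeded from the wall clock.
#'
#' @param cases character subset of `c("FD", "PD", "SH")`.
#' @param fieldsFile optional path to a gridded fields file
#'   ([readFields()]); when `NULL` the synthetic double-gyre fixture is
#'   generated from `fixture` parameters.
#' @param habitatFile optional path to a habitat CSV ([readHabitat()]);
#'   when `NULL` and "SH" is requested, synthetic habitat patches are
#'   generated.
#' @param fixture named list of overrides for [makeDoubleGyre()] /
#'   [makeMldAndBathy()] / [makeHabitatPatches()].
#' @param simConfig a [SimConfig-class] object.
#' @param behaviorConfig a [BehaviorConfig-class] for the
#'   preferred-depth cases; the FD case uses its fixed-depth variant.
#' @param mapEqConfig a [MapEqConfig-class] object.
#' @param classifierConfig a [ClassifierConfig-class] object.
#' @param outDir output directory (`NULL` for no file output).
#' @param label run label used in file names.
#' @return a `larvanetRunConfig` list.
#' @export
runConfig <- function(cases = c("FD", "PD", "SH"),
                      fieldsFile = NULL, habitatFile = NULL,
                      fixture = list(),
                      simConfig = SimConfig(),
                      behaviorConfig = BehaviorConfig(mode = "preferred_depth"),
                      mapEqConfig = MapEqConfig(),
                      classifierConfig = ClassifierConfig(),
                      outDir = NULL, label = "run") {
  cases <- match.arg(cases, several.ok = TRUE)
  structure(list(cases = cases, fieldsFile = fieldsFile,
                 habitatFile = habitatFile, fixture = fixture,
                 simConfig = simConfig, behaviorConfig = behaviorConfig,
                 mapEqConfig = mapEqConfig,
                 classifierConfig = classifierConfig,
                 outDir = outDir, label = label),
            class = "larvanetRunConfig")
}

#' Read a run configuration file
#'
#' YAML file with flat `key: value` sections per module (`sim`,
#' `behavior`, `mapeq`, `classifier`, `fixture`, plus top-level `cases`,
#' `fields_file`, `habitat_file`, `out_dir`, `label`).  Unknown keys are
#' an error; referenced files must exist.
#'
#' @param file path to the YAML config.
#' @return a `larvanetRunConfig` list.
#' @export
readRunConfig <- function(file) {
  y <- yaml::read_yaml(file)
  known <- c("cases", "fields_file", "habitat_file", "out_dir", "label",
             "sim", "behavior", "mapeq", "classifier", "fixture")
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  for (f in c(y$fields_file, y$habitat_file)) {
    if (!is.null(f) && !file.exists(f)) stop("referenced file missing: ", f)
  }
  sc <- do.call(SimConfig, if (is.null(y$sim)) list() else y$sim)
  bc <- do.call(BehaviorConfig,
                c(list(mode = "preferred_depth"),
                  if (is.null(y$behavior)) list() else y$behavior))
  mc <- do.call(MapEqConfig, if (is.null(y$mapeq)) list() else y$mapeq)
  cc <- do.call(ClassifierConfig,
                if (is.null(y$classifier)) list() else y$classifier)
  runConfig(cases = if (is.null(y$cases)) c("FD", "PD", "SH") else toupper(y$cases),
            fieldsFile = y$fields_file, habitatFile = y$habitat_file,
            fixture = if (is.null(y$fixture)) list() else y$fixture,
            simConfig = sc, behaviorConfig = bc, mapEqConfig = mc,
            classifierConfig = cc, outDir = y$out_dir,
            label = if (is.null(y$label)) "run" else y$label)
}

.fateTally <- function(cohort) {
  as.list(table(cohort@particles$status))
}

#' Run the full dispersal-to-subpopulation pipeline
#'
#' Executes, for each requested case: particle simulation (FD its own,
#' PD and SH sharing one), settlement resolution, flow-map construction
#' and pruning, transport-network normalization, seed-ensemble community
#' detection, quality metrics, connectivity matrix and boundary
#' persistence.  When `outDir` is set, every stage artifact is written
#' (settlement and flow-map CSVs, Pajek and TSV networks, partition
#' CSVs, quality/connectivity/boundary CSVs, cell GeoJSON) along with a
#' JSON run report (particle counts by fate, community count, codelength
#' per seed, global metrics, seeds and config echo).  Deterministic for
#' fixed seeds.
#'
#' @param config a `larvanetRunConfig` from [runConfig()] or
#'   [readRunConfig()].
#' @param verbose print stage progress (default TRUE).
#' @return the run report, invisibly a list (also written as JSON when
#'   `outDir` is set).
#' @export
runPipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "larvanetRunConfig"))
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  sc <- config$simConfig
  res <- sc@gridRes

  ## ---- fields & habitat ----
  fields <- stage("fields", {
    if (!is.null(config$fieldsFile)) readFields(config$fieldsFile)
    else {
      fx <- config$fixture
      gyreArgs <- fx[intersect(names(fx),
                               names(formals(makeDoubleGyre)))]
      f <- do.call(makeDoubleGyre, gyreArgs)
      mldArgs <- fx[intersect(names(fx),
                              setdiff(names(formals(makeMldAndBathy)), "fields"))]
      do.call(makeMldAndBathy, c(list(fields = f), mldArgs))
    }
  })
  habitat <- NULL
  if ("SH" %in% config$cases) {
    habitat <- stage("habitat", {
      if (!is.null(config$habitatFile)) readHabitat(config$habitatFile)
      else {
        fx <- config$fixture
        habArgs <- fx[intersect(names(fx),
                                setdiff(names(formals(makeHabitatPatches)),
                                        c("fields", "resolution")))]
        do.call(makeHabitatPatches,
                c(list(fields = fields, resolution = res), habArgs))
      }
    })
    if (is.null(habitat)) stop("SH case requested but no habitat available")
  }

  outDir <- config$outDir
  if (!is.null(outDir) && !dir.exists(outDir)) {
    dir.create(outDir, recursive = TRUE)
  }
  pathFor <- function(case, what) {
    file.path(outDir, sprintf("%s_%s_%s", config$label, case, what))
  }

  ## ---- simulations ----
  simFD <- NULL; simPD <- NULL
  if ("FD" %in% config$cases) {
    say("simulating fixed-depth cohort")
    bcFD <- config$behaviorConfig
    bcFD@mode <- "fixed_depth"
    simFD <- stage("simulate-FD",
                   runSimulation(seedCohort(fields, sc, bcFD), fields))
  }
  if (any(c("PD", "SH") %in% config$cases)) {
    say("simulating preferred-depth cohort (shared by PD and SH)")
    bcPD <- config$behaviorConfig
    bcPD@mode <- "preferred_depth"
    simPD <- stage("simulate-PD",
                   runSimulation(seedCohort(fields, sc, bcPD), fields))
  }

  report <- list(label = config$label,
                 seeds = list(sim = sc@rngSeed,
                              detection = seq_len(config$mapEqConfig@nSeeds) - 1L),
                 gridRes = res, markovTime = config$mapEqConfig@markovTime,
                 cases = list())

  for (case in config$cases) {
    say("case %s: settlement, network, detection, metrics", case)
    cohort <- switch(case,
                     FD = resolveSettlement(simFD, "FD"),
                     PD = resolveSettlement(simPD, "PD"),
                     SH = resolveSettlement(simPD, "SH", habitat = habitat))
    fm <- stage(paste0("flowmap-", case), pruneToClosed(buildFlowMap(cohort)))
    if (!nrow(fm@pairs)) {
      report$cases[[case]] <- list(fates = .fateTally(cohort),
                                   retained = 0L, note = "empty flow map")
      next
    }
    net <- stage(paste0("network-", case), asTransportNetwork(fm))
    det <- stage(paste0("detect-", case),
                 ensembleDetect(net, config$mapEqConfig))
    quality <- stage(paste0("metrics-", case),
                     communityQuality(net, fm, det$best,
                                      config$classifierConfig))
    conn <- connectivityMatrix(fm, det$best)
    bp <- stage(paste0("boundary-", case), boundaryPersistence(det$ensemble))

    report$cases[[case]] <- list(
      fates = .fateTally(cohort),
      retained = nrow(fm@pairs),
      nNodes = length(net@nodes),
      nCommunities = nCommunities(det$best),
      bestSeed = det$best@seed,
      codelengthPerSeed = vapply(det$ensemble, codelength, numeric(1L)),
      globalQuality = as.list(globalQuality(quality)))

    if (!is.null(outDir)) {
      writeSettlement(cohort, pathFor(case, "settlement.csv"))
      writeFlowMapCSV(fm, pathFor(case, "flowmap.csv"))
      writePajek(net, pathFor(case, "network.net"))
      writeEdgeList(net, pathFor(case, "edges.tsv"))
      writePartitionCSV(det$best, pathFor(case, "partition.csv"))
      writeClu(det$best, pathFor(case, "partition.clu"))
      writeQualityCSV(quality, pathFor(case, "quality.csv"))
      writeConnectivityCSV(conn, pathFor(case, "connectivity.csv"))
      writeBoundaryCSV(bp, pathFor(case, "boundary.csv"))
      exportCellsGeoJSON(net@nodes, pathFor(case, "cells.geojson"),
                         properties = data.frame(
                           community = det$best@membership[net@nodes]))
    }
  }

  if (!is.null(outDir)) {
    jsonlite::write_json(report, file.path(outDir,
                                           paste0(config$label, "_report.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(report)
}
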