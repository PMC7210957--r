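# Pipeline orchestration: wires phantom -> sit -> pose -> guild -> asr with
# per-stage configuration blocks, a global seed, file interchange
# (NRRD/PLY/JSON/CSV) and a provenance manifest with content hashes.

.known_stages <- c("phantom", "sit", "pose", "guild", "asr")

#' Run the analysis pipeline
#'
#' Executes the selected stages in order on a shared output directory.  Each
#' stage reads its inputs from the config block (or from the previous
#' stage's in-memory outputs) and writes its results as files; the manifest
#' records the package version, seed, config hash, and an md5 content hash
#' for every output file.  A stage failure aborts with a partial manifest on
#' disk.
#'
#' @param config path to a YAML config, or an equivalent named list.
#'   Recognized top-level fields: `stages` (subset of phantom, sit, pose,
#'   guild, asr), `seed`, `outDir`, plus per-stage blocks (`phantom`, `sit`,
#'   `pose`, `guild`, `asr`).  See the packaged demo config
#'   (`system.file("extdata", "demo-config.yaml", package = "SeqIsoTrim")`).
#' @param outDir output directory override.
#' @param seed global seed override; recorded in the manifest and used to
#'   derive per-stage seeds.
#' @return the manifest, invisibly (also written to `manifest.json`).
#' @export
runPipeline <- function(config, outDir = NULL, seed = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  stages <- if (is.null(cfg$stages)) .known_stages else cfg$stages
  unknown <- setdiff(stages, .known_stages)
  if (length(unknown))
    stop("unknown stage name(s): ", paste(unknown, collapse = ", "),
         " (known: ", paste(.known_stages, collapse = ", "), ")")
  if (is.null(outDir)) outDir <- if (!is.null(cfg$outDir)) cfg$outDir
                                 else tempfile("sitrun")
  if (is.null(seed)) seed <- if (!is.null(cfg$seed)) cfg$seed else 1L
  seed <- as.integer(seed)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "SeqIsoTrim",
                   version = as.character(utils::packageVersion("SeqIsoTrim")),
                   seed = seed, configHash = .hash_obj(cfg),
                   stages = list())
  manifestPath <- file.path(outDir, "manifest.json")
  writeManifest <- function() {
    jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                         digits = NA, force = TRUE)
  }
  addStage <- function(name, outputs, info = list()) {
    hashes <- lapply(outputs, function(f) unname(tools::md5sum(f)))
    names(hashes) <- basename(unlist(outputs))
    manifest$stages[[name]] <<- c(list(outputs = hashes), info)
    writeManifest()
  }
  state <- new.env(parent = emptyenv())

  runners <- list(
    phantom = function(blk) {
      spec <- if (!is.null(blk$gridShape))
        compactedSkullSpec(gridShape = as.integer(blk$gridShape),
                           seed = seed,
                           streakCount = if (!is.null(blk$streakCount))
                             as.integer(blk$streakCount) else 40L)
      else compactedSkullSpec(seed = seed)
      ph <- generatePhantom(spec)
      volPath <- file.path(outDir, "phantom.nrrd")
      writeVolumeNrrd(ph$volume, volPath)
      lblPath <- file.path(outDir, "phantom-labels.nrrd")
      writeVolumeNrrd(ph$truth@labelMap, lblPath)
      surfPath <- file.path(outDir, "phantom-surfaces.json")
      jsonlite::write_json(ph$truth@surfaces, surfPath, auto_unbox = TRUE,
                           digits = NA)
      state$volume <- ph$volume
      state$truth <- ph$truth
      addStage("phantom", list(volPath, lblPath, surfPath),
               list(seed = seed))
    },
    sit = function(blk) {
      vol <- if (!is.null(blk$volume)) readVolume(blk$volume)
             else if (!is.null(state$volume)) state$volume
             else stop("sit stage needs a volume (run phantom first or set ",
                       "sit.volume)")
      cfgS <- SITConfig(seed = seed)
      if (!is.null(blk$nLevels)) cfgS@nLevels <- as.integer(blk$nLevels)
      if (!is.null(blk$levelRange)) cfgS@levelRange <- as.numeric(blk$levelRange)
      if (!is.null(blk$aoNDirs)) cfgS@aoNDirs <- as.integer(blk$aoNDirs)
      res <- runSIT(vol, cfgS)
      meshPath <- file.path(outDir, "sit-mesh.ply")
      writeMeshPly(res$mesh, meshPath)
      repPath <- file.path(outDir, "sit-report.json")
      jsonlite::write_json(trimStages(res$report), repPath,
                           auto_unbox = TRUE, digits = NA, force = TRUE)
      state$mesh <- res$mesh
      addStage("sit", list(meshPath, repPath),
               list(finalFaces = nFaces(res$mesh)))
    },
    pose = function(blk) {
      if (!is.null(blk$mesh)) {
        mesh <- readMesh(blk$mesh)
        lmj <- jsonlite::read_json(blk$landmarks, simplifyVector = TRUE)
        lm <- RamusLandmarks(as.numeric(lmj$jointPoint),
                             as.numeric(lmj$anteriorTip))
      } else {
        toy <- toyRamusMesh()
        mesh <- toy$mesh
        lm <- toy$landmarks
      }
      pc <- PoseConfig()
      if (!is.null(blk$skullWidthMm)) pc@skullWidthMm <- blk$skullWidthMm
      if (!is.null(blk$angleGridDeg)) pc@angleGridDeg <- blk$angleGridDeg
      sol <- solvePose(mesh, lm, pc)
      posePath <- file.path(outDir, "pose.json")
      jsonlite::write_json(
        list(feasible = sol@feasible, tipGapMm = sol@tipGapMm,
             objectiveValue = sol@objectiveValue,
             anglesDeg = as.list(sol@anglesDeg),
             constraints = as.list(sol@constraintsSatisfied),
             rightTransform = sol@rightTransform,
             leftTransform = sol@leftTransform),
        posePath, auto_unbox = TRUE, digits = NA, force = TRUE)
      addStage("pose", list(posePath),
               list(feasible = sol@feasible, tipGapMm = sol@tipGapMm))
    },
    guild = function(blk) {
      d <- if (!is.null(blk$maxCrownDiameterMm)) blk$maxCrownDiameterMm else 3.13
      h <- if (!is.null(blk$crownHeightMm)) blk$crownHeightMm else 1.65
      w <- if (!is.null(blk$hemiWidthMm)) blk$hemiWidthMm else 15.1
      g <- assessGuild(d, h, hemiWidthMm = w)
      guildPath <- file.path(outDir, "guild.json")
      jsonlite::write_json(
        list(crownShapeIndex = g@crownShapeIndex,
             relativeToothSize = g@relativeToothSize,
             skullWidthMm = g@skullWidthMm, guildLabel = g@guildLabel,
             criteriaTrace = g@criteriaTrace),
        guildPath, auto_unbox = TRUE, digits = NA)
      addStage("guild", list(guildPath), list(guildLabel = g@guildLabel))
    },
    asr = function(blk) {
      if (!is.null(blk$tree)) {
        tr <- readTreeFile(blk$tree)
        cmx <- readCharMatrix(blk$matrix,
                              charIndex = if (!is.null(blk$charIndex))
                                as.integer(blk$charIndex) else 1L)
      } else {
        tr <- .with_seed(seed, ape::rtree(16, rooted = TRUE))
        tr$edge.length <- rep(1, nrow(tr$edge))
        cmx <- simulateMk(tr, rate = 0.3, seed = seed)$tipStates
      }
      pars <- sankoffParsimony(tr, cmx)
      mk <- fitRate(tr, cmx)
      asrPath <- file.path(outDir, "asr.json")
      jsonlite::write_json(
        list(parsimony = list(minCost = pars@minCost,
                              originRange = pars@originRange,
                              perNode = asrTable(pars, tr)),
             likelihood = list(rateHat = mk@rateHat, logLik = mk@logLik,
                               mlOriginRange = mk@mlOriginRange,
                               perNode = asrTable(mk, tr))),
        asrPath, auto_unbox = TRUE, digits = NA, dataframe = "rows")
      addStage("asr", list(asrPath),
               list(minCost = pars@minCost,
                    parsimonyOrigins = pars@originRange,
                    mkOrigins = mk@mlOriginRange))
    }
  )

  for (s in stages) {
    blk <- if (!is.null(cfg[[s]])) cfg[[s]] else list()
    ok <- tryCatch({ runners[[s]](blk); TRUE },
                   error = function(e) {
                     manifest$status <<- list(failedStage = s,
                                              error = conditionMessage(e))
                     writeManifest()
                     stop("stage '", s, "' failed: ", conditionMessage(e),
                          call. = FALSE)
                   })
  }
  manifest$status <- "complete"
  writeManifest()
  invisible(manifest)
}
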