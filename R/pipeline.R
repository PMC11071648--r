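#' @include simulate.R preprocess.R dualreg.R group-inference.R trajectory.R io.R
NULL

#' Default pipeline configuration values
#'
#' The nested defaults reproduce the package's reference scenario: a
#' subdivision-2 icosphere cortex, a 7-network parcellation, 3 seed maps,
#' a 316-subject cohort (112 male, ages 8-83, mean 44.38 y), 200-volume
#' runs at TR 0.645 s with the [socialScenario()] planted effects, the
#' conventional preprocessing chain, joint dual regression, RFT-corrected
#' age/sex GLM contrasts, and Gaussian location-scale percentile
#' trajectories at the 10/25/50/75/90 levels.
#'
#' @return named nested list.
#' @export
defaultPipelineConfig <- function() {
  list(
    synthetic = list(
      subdivisions = 2L, radius_mm = 100, k = 7L,
      n_subjects = 316L, n_male = 112L, age_min = 8, age_max = 83,
      target_mean_age = 44.38, age_sd = 19.72,
      n_seeds = 3L, overlap_frac = 0.2, foci_per_seed = 6L,
      seed_fwhm_mm = 28, seed_amplitude = 4,
      t_points = 200L, tr = 0.645, noise_sd = 0.5, ar1 = 0.3,
      baseline = 100, tissue_weight = 0.2),
    preprocess = list(
      n_discard = 8L, grand_mean_target = 10000,
      band = c(0.01, 0.1),
      nuisance = list(friston24 = TRUE, tissue = TRUE),
      order = c("discard", "scale", "nuisance", "bandpass", "detrend")),
    dualreg = list(demean_maps = TRUE, variance_normalize = TRUE),
    glm = list(
      contrasts = c("age_c", "age_c2", "sex", "sex_age", "sex_age2"),
      correction = "rft", cluster_forming_z = 2.3, alpha = 0.05,
      n_perm = 499L, direction = "two.sided"),
    trajectory = list(
      family = "gaussian_ls", basis = "poly2",
      percentiles = c(10, 25, 50, 75, 90), sex_in_mu = FALSE,
      alpha = 0.05),
    seed = 1L,
    out_dir = NULL,
    stages = c("generate", "preprocess", "dualreg", "glm", "trajectory"))
}

# Recursive merge of user values into the default template; any key absent
# from the template is collected as an error.
.mergeConfig <- function(defaults, user, path = "") {
  if (is.null(user)) return(list(value = defaults, unknown = character(0)))
  unknown <- character(0)
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults)) {
      unknown <- c(unknown, full)
      next
    }
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      sub <- .mergeConfig(defaults[[key]], user[[key]], full)
      defaults[[key]] <- sub$value
      unknown <- c(unknown, sub$unknown)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  list(value = defaults, unknown = unknown)
}

#' Validate a pipeline configuration
#'
#' Accepts a YAML file path, a nested list, or nothing (all defaults);
#' merges the values into [defaultPipelineConfig()], rejecting unknown keys
#' and inconsistent settings (reversed band edges, more males than
#' subjects, non-contiguous stage selections, ...).
#'
#' @param x YAML path, named list of overrides, or `NULL`.
#' @return a fully-defaulted [PipelineConfig].
#' @export
validateConfig <- function(x = NULL) {
  user <- if (is.null(x)) list()
          else if (is(x, "PipelineConfig")) x@config
          else if (is.character(x)) {
            if (!file.exists(x)) stop("no such config file: ", x, call. = FALSE)
            val <- yaml::read_yaml(x)
            if (is.null(val)) list() else val
          } else if (is.list(x)) x
          else stop("config must be a YAML path or a named list", call. = FALSE)
  merged <- .mergeConfig(defaultPipelineConfig(), user)
  if (length(merged$unknown))
    stop("unknown configuration key(s): ",
         paste(merged$unknown, collapse = ", "), call. = FALSE)
  cfg <- merged$value
  syn <- cfg$synthetic
  if (syn$n_male > syn$n_subjects)
    stop("synthetic.n_male exceeds synthetic.n_subjects", call. = FALSE)
  if (syn$subdivisions > 6)
    stop("synthetic.subdivisions must be <= 6", call. = FALSE)
  band <- cfg$preprocess$band
  if (length(band) != 2L || band[1] >= band[2])
    stop("preprocess.band must be c(low, high) with low < high",
         call. = FALSE)
  stages <- cfg$stages
  allStages <- c("generate", "preprocess", "dualreg", "glm", "trajectory")
  if (!all(stages %in% allStages))
    stop("unknown stage(s): ", paste(setdiff(stages, allStages),
                                     collapse = ", "), call. = FALSE)
  if (!identical(stages, allStages[seq_along(stages)]))
    stop("stages must be a contiguous prefix of: ",
         paste(allStages, collapse = ", "), call. = FALSE)
  if (!cfg$glm$correction %in% c("rft", "perm"))
    stop("glm.correction must be 'rft' or 'perm'", call. = FALSE)
  new("PipelineConfig", config = cfg)
}

# Content hash of an arbitrary R object (via its uncompressed
# serialization), used as a stage cache key.
.hashObject <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 3L)
  close(con)
  unname(tools::md5sum(f))
}

# Per-stage RNG seeds fanned out from the global seed (kept below 2^31).
.stageSeed <- function(seed, index)
  as.integer((as.numeric(seed) * 7919 + index) %% 2147483647L) + 1L

#' Run the full synthetic trajectory pipeline
#'
#' Executes the enabled stages in order — generate, preprocess, dual
#' regression, group GLM with cluster correction, trajectory fitting —
#' writing stage outputs under `outDir` and returning a provenance log.
#' Stage results are cached on disk keyed by a hash of the stage
#' parameters and upstream cache key, so a rerun with an unchanged
#' upstream configuration reuses cached outputs while any parameter change
#' invalidates everything downstream. Identical configuration and seed
#' give byte-identical numerical outputs.
#'
#' @param config anything [validateConfig()] accepts.
#' @param outDir output directory (default: the config's `out_dir`, or a
#'   fresh temporary directory).
#' @return a [ProvenanceLog]; the log's records name every file written.
#' @export
runPipeline <- function(config = NULL, outDir = NULL) {
  cfg <- validateConfig(config)@config
  if (is.null(outDir)) outDir <- cfg$out_dir
  if (is.null(outDir)) outDir <- tempfile("socotraj-run-")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  cacheDir <- file.path(outDir, "cache")
  dir.create(cacheDir, showWarnings = FALSE)
  records <- list()

  runStage <- function(name, params, upstreamKey, fn) {
    key <- .hashObject(list(name, params, upstreamKey))
    cacheFile <- file.path(cacheDir, paste0(name, "-", key, ".rds"))
    cached <- file.exists(cacheFile)
    warns <- character(0)
    t0 <- proc.time()[["elapsed"]]
    value <- if (cached) readRDS(cacheFile) else {
      v <- withCallingHandlers(fn(), warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
      saveRDS(v, cacheFile)
      v
    }
    records[[length(records) + 1L]] <<- list(
      stage = name, parameters = params, input_hash = upstreamKey,
      cache_key = key, cached = cached,
      wall_time_s = proc.time()[["elapsed"]] - t0,
      warnings = warns, outputs = character(0))
    list(value = value, key = key)
  }
  addOutputs <- function(files)
    records[[length(records)]]$outputs <<-
      c(records[[length(records)]]$outputs, files)

  stages <- cfg$stages
  syn <- cfg$synthetic

  gen <- runStage("generate", c(syn, seed = cfg$seed), "none", function() {
    surface <- makeMesh(syn$subdivisions, syn$radius_mm)
    parcellation <- makeParcellation(surface, syn$k,
                                     seed = .stageSeed(cfg$seed, 1L))
    seedMaps <- makeSeedMaps(surface, nSeeds = syn$n_seeds,
                             overlapFrac = syn$overlap_frac,
                             seed = .stageSeed(cfg$seed, 2L),
                             fociPerSeed = syn$foci_per_seed,
                             fwhm_mm = syn$seed_fwhm_mm,
                             amplitude = syn$seed_amplitude)
    cohort <- makeCohort(syn$n_subjects, syn$n_male, syn$age_min, syn$age_max,
                         syn$target_mean_age, syn$age_sd,
                         seed = .stageSeed(cfg$seed, 3L))
    runs <- simulateBold(surface, parcellation, seedMaps, cohort,
                         effects = socialScenario(),
                         tPoints = syn$t_points, tr = syn$tr,
                         noiseSd = syn$noise_sd, ar1 = syn$ar1,
                         baseline = syn$baseline,
                         tissueWeight = syn$tissue_weight,
                         seed = .stageSeed(cfg$seed, 4L))
    list(surface = surface, parcellation = parcellation,
         seedMaps = seedMaps, cohort = cohort, runs = runs)
  })
  cohortFile <- file.path(outDir, "cohort.csv")
  writeCohortCsv(gen$value$cohort, cohortFile)
  parcFile <- file.path(outDir, "parcellation.label.gii")
  writeGiftiLabel(gen$value$parcellation, parcFile)
  seedFile <- file.path(outDir, "seed_maps.func.gii")
  writeGiftiData(seedWeights(gen$value$seedMaps), seedFile,
                 intent = "NIFTI_INTENT_NONE")
  addOutputs(c(cohortFile, parcFile, seedFile))
  if (!"preprocess" %in% stages)
    return(new("ProvenanceLog", records = records))

  pp <- cfg$preprocess
  pre <- runStage("preprocess", pp, gen$key, function() {
    lapply(gen$value$runs, preprocessRun,
           nDiscard = pp$n_discard,
           grandMeanTarget = pp$grand_mean_target, band = pp$band,
           friston = pp$nuisance$friston24, tissue = pp$nuisance$tissue,
           order = pp$order)
  })
  if (!"dualreg" %in% stages)
    return(new("ProvenanceLog", records = records))

  dr <- runStage("dualreg", cfg$dualreg, pre$key, function() {
    lapply(pre$value, dualRegress, seeds = gen$value$seedMaps,
           demeanMaps = cfg$dualreg$demean_maps,
           varianceNormalize = cfg$dualreg$variance_normalize)
  })
  if (!"glm" %in% stages)
    return(new("ProvenanceLog", records = records))

  gl <- cfg$glm
  sn <- seedNames(gen$value$seedMaps)
  glm <- runStage("glm", gl, dr$key, function() {
    design <- buildDesign(gen$value$cohort)
    out <- list()
    for (seedNm in sn) {
      maps <- t(vapply(dr$value, function(f) drMaps(f)[seedNm, ],
                       numeric(nVertices(gen$value$surface))))
      for (ct in gl$contrasts) {
        stat <- fitVertexGLM(maps, design, contrastVector(design, ct),
                             contrastName = paste(seedNm, ct, sep = ":"))
        res <- if (gl$correction == "rft") {
          sm <- estimateSmoothness(stat@residuals, gen$value$surface)
          rftClusterCorrect(stat, sm, gen$value$surface,
                            clusterFormingZ = gl$cluster_forming_z,
                            alpha = gl$alpha, direction = gl$direction)
        } else {
          permutationCorrect(maps, design, contrastVector(design, ct),
                             gen$value$surface,
                             clusterFormingZ = gl$cluster_forming_z,
                             nPerm = gl$n_perm,
                             seed = .stageSeed(cfg$seed, 5L),
                             alpha = gl$alpha, direction = gl$direction)
        }
        out[[paste(seedNm, ct, sep = ":")]] <-
          list(stat = stat, clusters = res)
      }
    }
    out
  })
  glmFiles <- character(0)
  for (nm in names(glm$value)) {
    safe <- gsub(":", "_", nm)
    tFile <- file.path(outDir, paste0("tmap_", safe, ".func.gii"))
    writeGiftiData(glm$value[[nm]]$stat@t, tFile,
                   intent = "NIFTI_INTENT_TTEST")
    cFile <- file.path(outDir, paste0("clusters_", safe, ".tsv"))
    utils::write.table(clusterTable(glm$value[[nm]]$clusters), cFile,
                       sep = "\t", row.names = FALSE, quote = FALSE)
    glmFiles <- c(glmFiles, tFile, cFile)
  }
  addOutputs(glmFiles)
  if (!"trajectory" %in% stages)
    return(new("ProvenanceLog", records = records))

  tj <- cfg$trajectory
  traj <- runStage("trajectory", tj, glm$key, function() {
    ifc <- summarizeNetworkIfc(dr$value, gen$value$parcellation,
                               gen$value$cohort)
    fits <- list()
    for (seedNm in sn) {
      for (netNm in networkNames(gen$value$parcellation)) {
        sub <- ifc[ifc$seed_name == seedNm & ifc$network_name == netNm, ]
        fit <- fitTrajectory(sub$age, sub$ifc, sex = sub$sex,
                             family = tj$family, basis = tj$basis,
                             percentiles = tj$percentiles,
                             sexInMu = tj$sex_in_mu)
        fits[[paste(seedNm, netNm, sep = ":")]] <-
          list(fit = fit, shape = classifyShape(fit, alpha = tj$alpha))
      }
    }
    list(ifc = ifc, fits = fits)
  })
  ifcFile <- file.path(outDir, "ifc_table.csv")
  utils::write.csv(traj$value$ifc, ifcFile, row.names = FALSE)
  trajDir <- file.path(outDir, "trajectories")
  dir.create(trajDir, showWarnings = FALSE)
  trajFiles <- ifcFile
  summary <- list()
  for (nm in names(traj$value$fits)) {
    entry <- traj$value$fits[[nm]]
    safe <- gsub(":", "_", nm)
    curves <- trajectoryCurves(entry$fit)
    cf <- file.path(trajDir, paste0("curves_", safe, ".csv"))
    utils::write.csv(
      data.frame(age = entry$fit@ageGrid, t(curves), check.names = FALSE),
      cf, row.names = FALSE)
    trajFiles <- c(trajFiles, cf)
    summary[[nm]] <- list(
      family = entry$fit@family,
      mu_coefficients = entry$fit@muCoefficients,
      sigma_coefficients = entry$fit@sigmaCoefficients,
      bic = entry$fit@bic, shape = entry$shape)
  }
  sumFile <- file.path(outDir, "trajectory_summary.json")
  jsonlite::write_json(summary, sumFile, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  trajFiles <- c(trajFiles, sumFile)
  addOutputs(trajFiles)

  provFile <- file.path(outDir, "provenance.json")
  log <- new("ProvenanceLog", records = records)
  jsonlite::write_json(records, provFile, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  log
}
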