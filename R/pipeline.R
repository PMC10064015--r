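.defaultPipelineConfig <- function() {
  list(
    # synthetic inputs (used unless boutons_csv is given)
    n_boutons = 1048L,
    lm_fraction = 0.18,
    # reduced stack/grid geometry for a desk-scale demonstration run
    stack_voxel_nm = c(125, 125, 500),
    grid = list(grids = 2L, cells = 6L, frame_um = 2.5,
                z_spacing = 4L),
    stack_density = 2.5,
    blob_radius = 1L,
    uts_fraction = 0.5,
    # modeling
    k_max = 9L,
    mc_iterations = 1000L,
    mc_multiplier = 5L,
    # association stage
    segment_config = list(n_x = 120L, n_y = 120L, n_int = 10L,
                          epsilon = 0.9, terminals = 15),
    filter_threshold = 0.025,
    min_terminals = 40L,
    network_min_support = 0.1,
    # optional real inputs
    boutons_csv = NULL,
    segments_csv = NULL
  )
}

#' Run the full bouton-sorting and selectivity pipeline
#'
#' Orchestrates the end-to-end analysis on synthetic (or supplied)
#' data: population generation, stack building, unbiased terminal
#' sampling, per-family mixture fitting with BIC selection, Monte
#' Carlo cutoff estimation, volume-bin classification with composition
#' summaries, segment morphometry, association-rule mining and network
#' construction for X-like and Y-like segments, and a written report.
#' Every stage logs its in/out counts; all randomness derives from
#' `seed`, so a rerun with the same configuration and seed is
#' bit-identical (same manifest hash).
#'
#' @param outputDir directory for artifacts (created if needed).
#' @param seed integer master seed.
#' @param config named list overriding entries of the default
#'   configuration (see the vignette); unknown entries error.
#' @param verbose emit per-stage messages (default TRUE).
#'
#' @return Invisibly, the result bundle: `population`, `utsSample`,
#'   `fits`, `cutoffs`, `classified`, `composition`, `segments`,
#'   `rules`, `networks`, `manifest`.
#' @export
runPipeline <- function(outputDir, seed = 1L, config = list(),
                        verbose = TRUE) {
  cfg <- .defaultPipelineConfig()
  unknown <- setdiff(names(config), names(cfg))
  if (length(unknown))
    stop("config error: unknown option(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  cfg[names(config)] <- config
  for (p in c(cfg$boutons_csv, cfg$segments_csv))
    if (!is.null(p) && !file.exists(p))
      stop("config error: input path does not exist: ", p,
           call. = FALSE)
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message("[boutonsort] ", ...)

  specs <- defaultMixtures()

  ## stage 1: population
  if (!is.null(cfg$boutons_csv)) {
    population <- utils::read.csv(cfg$boutons_csv,
                                  stringsAsFactors = FALSE)
    say("stage population: read ", nrow(population), " boutons")
  } else {
    nLM <- as.integer(round(cfg$n_boutons * cfg$lm_fraction))
    nDNM <- cfg$n_boutons - nLM
    population <- rbind(
      generateBoutonPopulation(specs$LM, nLM, seed = seed),
      generateBoutonPopulation(specs$DNM, nDNM, seed = seed + 1L))
    say("stage population: generated ", nrow(population),
        " boutons (", nLM, " LM / ", nDNM, " DNM)")
  }

  ## stage 2: stack + unbiased terminal sampling
  g <- cfg$grid
  grid <- GridSpec(gridsPerArray = g$grids, cellsPerSide = g$cells,
                   frameSide = g$frame_um, gridZSpacing = g$z_spacing,
                   sectionThickness = cfg$stack_voxel_nm[3])
  frameVox <- as.integer(round(g$frame_um * 1000 /
                                 cfg$stack_voxel_nm[1]))
  needXY <- g$cells * frameVox
  needZ <- max(grid@referenceSections) + 2L
  sspec <- StackSpec(dims = c(needXY, needXY, needZ),
                     voxelSize = cfg$stack_voxel_nm,
                     density = cfg$stack_density,
                     blobRadius = cfg$blob_radius, blobRadiusZ = 0L)
  stack <- generateStack(sspec, population, seed = seed + 2L)
  uts <- runUTS(stack, population, grid, fraction = cfg$uts_fraction,
                seed = seed + 3L)
  say("stage uts: examined ", sum(uts$tally), " locations, sampled ",
      nrow(uts$sample), " boutons (",
      paste(names(uts$tally), as.integer(uts$tally), sep = "=",
            collapse = ", "), ")")

  ## stage 3: mixture fits by family
  fam <- assignFamily(uts$sample$mito_class)
  fits <- list()
  for (f in c("LM", "DNM")) {
    v <- uts$sample$volume[fam == f]
    if (length(v) < 4L)
      stop("stage fit failed: too few ", f, " boutons sampled (",
           length(v), ")", call. = FALSE)
    fits[[f]] <- selectByBIC(v, kMax = cfg$k_max, seed = seed + 4L)
    say("stage fit (", f, "): n = ", length(v), ", selected k = ",
        fits[[f]]@k, " (", fits[[f]]@varianceModel, " variance)")
  }

  ## stage 4: Monte Carlo cutoffs
  cutoffs <- list()
  for (f in c("LM", "DNM")) {
    cutoffs[[f]] <- if (fits[[f]]@k >= 2L)
      tryCatch(
        mcCutoffs(fits[[f]], R = cfg$mc_iterations,
                  multiplier = cfg$mc_multiplier, seed = seed + 5L,
                  family = f),
        error = function(e) {
          # e.g. a fitted component too small to simulate; fall back
          # to the analytic crossing of the fitted mixture
          say("stage cutoffs (", f, "): Monte Carlo unavailable (",
              conditionMessage(e), "); using analytic crossings")
          analyticCutoffs(fits[[f]], family = f)
        })
    else
      new("CutoffSet", family = f, boundaries = numeric(),
          method = "monte_carlo", iterations = 1L, multiplier = 1L,
          boundarySD = numeric())
    say("stage cutoffs (", f, "): ",
        paste(signif(boundaries(cutoffs[[f]]), 4), collapse = "; "),
        " um^3")
  }

  ## stage 5: classification + composition
  classified <- classifyBoutons(population, cutoffs$LM, cutoffs$DNM)
  composition <- compositionSummary(classified)
  say("stage classify: ", nrow(classified), " boutons into ",
      length(unique(classified$subpop)), " subpopulations")

  ## stage 6: segments, morphometry, association networks
  if (!is.null(cfg$segments_csv)) {
    segData <- NULL
    segments <- utils::read.csv(cfg$segments_csv,
                                stringsAsFactors = FALSE)
    segBoutons <- classified[!is.na(classified$segment_id), ,
                             drop = FALSE]
  } else {
    sc <- cfg$segment_config
    segCfg <- SegmentGenConfig(
      nSegments = c(interneuron = sc$n_int, X_like = sc$n_x,
                    Y_like = sc$n_y),
      epsilon = sc$epsilon, terminalsPerSegment = sc$terminals)
    segData <- generateSegmentDataset(segCfg, seed = seed + 6L)
    segments <- segData$segments
    segBoutons <- classifyBoutons(segData$boutons, cutoffs$LM,
                                  cutoffs$DNM)
  }
  segments <- annotateSegments(segments)
  say("stage morphometry: ", nrow(segments), " segments (",
      paste(names(table(segments$cell_class)),
            table(segments$cell_class), sep = "=", collapse = ", "),
      ")")

  rules <- list(); networks <- list()
  for (cls in c("X_like", "Y_like")) {
    ids <- segments$segment_id[segments$cell_class == cls]
    b <- segBoutons[segBoutons$segment_id %in% ids, , drop = FALSE]
    if (nrow(b) == 0L) next
    tx <- buildTransactions(b, filterThreshold = cfg$filter_threshold,
                            minTerminals = cfg$min_terminals)
    rules[[cls]] <- mineRules(tx)
    networks[[cls]] <- buildNetwork(
      rules[[cls]], minSupport = cfg$network_min_support)
    say("stage association (", cls, "): ", length(tx@items),
        " transactions, ", nrow(rules[[cls]]), " rules, ",
        nrow(networkEdges(networks[[cls]])), " edges")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("boutonsort")),
    seed = seed,
    config = cfg,
    stage_counts = list(
      population = nrow(population),
      uts_examined = sum(uts$tally),
      uts_sampled = nrow(uts$sample),
      selected_k = as.list(vapply(fits, function(f) f@k, 0L))))
  manifest$hash <- rlang::hash(manifest)

  bundle <- list(population = population, utsSample = uts$sample,
                 utsTally = uts$tally, fits = fits, cutoffs = cutoffs,
                 classified = classified, composition = composition,
                 segments = segments, segmentBoutons = segBoutons,
                 rules = rules, networks = networks,
                 manifest = manifest)
  writeReport(bundle, outputDir)
  say("done: artifacts in ", outputDir, " (manifest hash ",
      substr(manifest$hash, 1, 12), ")")
  invisible(bundle)
}

#' Write a human-readable result bundle
#'
#' Writes the pipeline artifacts: classified boutons and composition
#' (CSV), fits and cutoffs and the manifest (JSON), association rule
#' tables and lift matrices (CSV) and a markdown summary report.
#'
#' @param bundle result bundle from [runPipeline()].
#' @param outputDir target directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
writeReport <- function(bundle, outputDir) {
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(outputDir, f)
  paths <- character()

  utils::write.csv(bundle$classified, pth("boutons_classified.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$composition, pth("composition.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$segments, pth("segments.csv"),
                   row.names = FALSE)
  paths <- c(pth("boutons_classified.csv"), pth("composition.csv"),
             pth("segments.csv"))

  fitJson <- lapply(bundle$fits, function(f) list(
    k = f@k, weights = f@weight, means = f@mean, sds = f@sd,
    loglik = f@loglik, bic = f@bic, variance_model = f@varianceModel,
    n = f@n, converged = f@converged, bic_table = f@bicTable))
  cutJson <- lapply(bundle$cutoffs, function(cs) list(
    family = cs@family, boundaries = cs@boundaries,
    method = cs@method, iterations = cs@iterations,
    multiplier = cs@multiplier, boundary_sd = cs@boundarySD))
  jsonlite::write_json(fitJson, pth("fits.json"), auto_unbox = TRUE,
                       digits = NA)
  jsonlite::write_json(cutJson, pth("cutoffs.json"), auto_unbox = TRUE,
                       digits = NA)
  jsonlite::write_json(bundle$manifest, pth("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  paths <- c(paths, pth("fits.json"), pth("cutoffs.json"),
             pth("manifest.json"))

  for (cls in names(bundle$rules)) {
    utils::write.csv(bundle$rules[[cls]],
                     pth(sprintf("rules_%s.csv", cls)),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(liftMatrix(bundle$rules[[cls]])),
                     pth(sprintf("lift_matrix_%s.csv", cls)))
    paths <- c(paths, pth(sprintf("rules_%s.csv", cls)),
               pth(sprintf("lift_matrix_%s.csv", cls)))
  }

  md <- c("# Bouton sorting report", "",
          sprintf("Seed: %d; manifest hash: %s", bundle$manifest$seed,
                  bundle$manifest$hash), "",
          "## Subpopulation composition (% of all boutons)", "",
          "| subpop | origin | count | percent |",
          "|---|---|---|---|",
          sprintf("| %s | %s | %d | %.1f |", bundle$composition$subpop,
                  bundle$composition$putative_origin,
                  bundle$composition$count, bundle$composition$percent),
          "")
  for (cls in names(bundle$networks)) {
    outs <- outstrength(bundle$networks[[cls]])
    md <- c(md, sprintf("## %s segments", cls), "",
            if (nrow(bundle$rules[[cls]]) == 0L)
              "no associations" else
              c("outstrength:",
                sprintf("- %s: %.3f", names(outs), outs)), "")
  }
  if (length(bundle$rules) == 0L)
    md <- c(md, "## Associations", "", "no associations", "")
  writeLines(md, pth("report.md"))
  paths <- c(paths, pth("report.md"))
  invisible(paths)
}
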