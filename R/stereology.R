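#' Build a 3-D array of unbiased counting frames over a label stack
#'
#' Lays `gridsPerArray` square grids of `cellsPerSide` x `cellsPerSide`
#' counting frames over the stack, one grid per reference section.
#' Frames tile the plane from the stack origin: adjacent frame
#' boundaries are shared lines, and each frame is the half-open region
#' `[x0, x0 + w) x [y0, y0 + w)` in voxel coordinates (0-based) on its
#' grid's reference section. Locations are numbered sequentially
#' across grids, rows, then columns.
#'
#' @param grid a [GridSpec-class].
#' @param stack a [LabelStack-class] (its voxel size converts the frame
#'   side from micrometres to voxels).
#'
#' @return list with `locations` (data.frame: `location_id`, `grid`,
#'   `row`, `col`, `x0`, `y0`, `z`, `status = "not_examined"`,
#'   `selected = FALSE`), `frameVox` (frame side in voxels) and `grid`.
#'   Errors with the required minimum dimensions if the stack cannot
#'   host the array.
#' @export
buildArray <- function(grid, stack) {
  stopifnot(is(grid, "GridSpec"), is(stack, "LabelStack"))
  dims <- dim(stackLabels(stack))
  frameVox <- as.integer(round(grid@frameSide * 1000 / stack@voxelSize[1]))
  if (frameVox < 1L)
    stop("frame side smaller than one voxel", call. = FALSE)
  need <- grid@cellsPerSide * frameVox
  needZ <- max(grid@referenceSections) + 1L
  if (dims[1] < need || dims[2] < need || dims[3] < needZ)
    stop(sprintf(
      paste0("geometry error: stack %d x %d x %d too small; ",
             "need at least %d x %d x %d voxels"),
      dims[1], dims[2], dims[3], need, need, needZ), call. = FALSE)
  cells <- grid@cellsPerSide
  g <- rep(seq_len(grid@gridsPerArray), each = cells * cells)
  row <- rep(rep(seq_len(cells), each = cells), grid@gridsPerArray)
  col <- rep(seq_len(cells), cells * grid@gridsPerArray)
  locations <- data.frame(
    location_id = seq_along(g),
    grid = g, row = row, col = col,
    x0 = (col - 1L) * frameVox,
    y0 = (row - 1L) * frameVox,
    z = grid@referenceSections[g],
    status = "not_examined",
    selected = FALSE,
    stringsAsFactors = FALSE)
  list(locations = locations, frameVox = frameVox, grid = grid)
}

#' Randomly select counting-frame locations for examination
#'
#' Uniform sampling without replacement of `round(fraction * total)`
#' locations.
#'
#' @param array result of [buildArray()].
#' @param fraction fraction of locations to examine, in (0, 1].
#' @param seed integer seed.
#' @return `array` with the chosen locations flagged in
#'   `locations$selected`.
#' @export
selectLocations <- function(array, fraction, seed = 1L) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("fraction must lie in (0, 1]", call. = FALSE)
  total <- nrow(array$locations)
  nSel <- as.integer(round(fraction * total))
  rng <- .seededRNG(seed)
  sel <- rng$sample(total, nSel)
  array$locations$selected <- array$locations$location_id %in% sel
  array
}

#' Test a synapse footprint against an unbiased counting frame
#'
#' Classical counting-frame rule with two inclusion sides (right and
#' top) and two exclusion sides (left and bottom, including their
#' infinite extensions beyond the frame corners). The footprint is the
#' synapse's voxel set on the frame's reference section, 0-based. A
#' footprint is `"included"` iff it does not cross the frame's
#' exclusion lines - it contains no voxel with `x < x0` or `y < y0` -
#' and starts inside the frame's column and row band, i.e. its
#' bounding corner `(min x, min y)` lies in the half-open frame
#' `[x0, x0 + w) x [y0, y0 + w)`. A footprint that intersects the
#' frame without that is `"excluded"`; one that does neither is
#' `"outside"`. Whenever the footprint touches the frame holding its
#' bounding corner this is exactly the textbook
#' intersects-and-does-not-cross-the-exclusion-lines rule; anchoring
#' inclusion at the bounding corner additionally covers footprints
#' that straddle a frame corner without entering the lower-left
#' quadrant, so that under a full tiling of the plane *every* blob -
#' convex or not - is included by exactly one frame.
#'
#' @param footprint two-column matrix or data.frame of 0-based voxel
#'   (x, y) coordinates; must be non-empty.
#' @param frame list with `x0`, `y0` (0-based voxel origin) and `w`
#'   (side length in voxels).
#' @return `"included"`, `"excluded"` or `"outside"`.
#' @export
testInclusion <- function(footprint, frame) {
  fp <- as.matrix(footprint)
  if (nrow(fp) == 0L)
    stop("empty footprint", call. = FALSE)
  x <- fp[, 1]; y <- fp[, 2]
  xmin <- min(x); ymin <- min(y)
  if (xmin >= frame$x0 && xmin < frame$x0 + frame$w &&
      ymin >= frame$y0 && ymin < frame$y0 + frame$w)
    return("included")
  inFrame <- any(x >= frame$x0 & x < frame$x0 + frame$w &
                   y >= frame$y0 & y < frame$y0 + frame$w)
  if (inFrame) "excluded" else "outside"
}

#' Run unbiased terminal sampling over an annotated stack
#'
#' Examines the selected counting-frame locations of the array: every
#' synapse blob whose footprint on a grid's reference section passes
#' the counting-frame rule ([testInclusion()]) is sampled, and its
#' linked bouton contributes its volume exactly once. A synapse
#' intersecting the reference sections of two grids is assigned to the
#' lower grid index only (with a warning). Location statuses partition
#' the examined locations into `empty`, `soma`, `synapse_sampled` and
#' `excluded` (synapses present but all crossing exclusion lines).
#'
#' @param stack a [LabelStack-class].
#' @param population data.frame of bouton records (ids must cover the
#'   stack's `bouton_id` links).
#' @param grid a [GridSpec-class].
#' @param fraction fraction of locations to examine.
#' @param seed integer seed for location selection.
#' @param somaMask optional logical array (stack dims); locations whose
#'   frame lies entirely within the mask on the reference section are
#'   tallied as `soma` and not sampled.
#'
#' @return list with `sample` (bouton records of sampled synapses, one
#'   row per sampled synapse, with `synapse_id` and `location_id`),
#'   `locations` (the examined-location table with final statuses) and
#'   `tally` (named counts of statuses over examined locations).
#' @export
runUTS <- function(stack, population, grid = GridSpec(), fraction = 0.5,
                   seed = 1L, somaMask = NULL) {
  array <- buildArray(grid, stack)
  array <- selectLocations(array, fraction, seed)
  loc <- array$locations
  w <- array$frameVox
  labels <- stackLabels(stack)
  syn <- synapseTable(stack)
  if (nrow(syn) > 0 && !all(syn$bouton_id %in% population$id))
    stop("data-integrity error: sampled synapse without bouton link",
         call. = FALSE)

  # per reference section: voxel lists per synapse id
  refZ <- sort(unique(loc$z))
  foot <- list()
  for (z in refZ) {
    plane <- labels[, , z + 1L]
    idx <- which(plane > 0L)
    if (length(idx)) {
      xy <- arrayInd(idx, dim(plane)) - 1L # 0-based
      foot[[as.character(z)]] <- split.data.frame(
        cbind(x = xy[, 1], y = xy[, 2]), plane[idx])
    } else foot[[as.character(z)]] <- list()
  }

  sampled <- list()
  seen <- data.frame(synapse_id = integer(), grid = integer())
  examined <- which(loc$selected)
  for (i in examined) {
    z <- loc$z[i]
    frame <- list(x0 = loc$x0[i], y0 = loc$y0[i], w = w)
    fps <- foot[[as.character(z)]]
    if (!is.null(somaMask)) {
      xs <- frame$x0 + seq_len(w)
      ys <- frame$y0 + seq_len(w)
      if (all(somaMask[xs, ys, z + 1L])) {
        loc$status[i] <- "soma"
        next
      }
    }
    if (length(fps) == 0L) { loc$status[i] <- "empty"; next }
    res <- vapply(fps, testInclusion, "", frame = frame)
    hit <- names(fps)[res == "included"]
    if (length(hit) == 0L) {
      loc$status[i] <-
        if (any(res == "excluded")) "excluded" else "empty"
      next
    }
    loc$status[i] <- "synapse_sampled"
    for (id in as.integer(hit)) {
      prev <- seen$grid[seen$synapse_id == id]
      if (length(prev)) {
        if (prev != loc$grid[i])
          warning(sprintf(
            "synapse %d intersects reference sections of grids %d and %d; keeping grid %d",
            id, prev, loc$grid[i], min(prev, loc$grid[i])))
        next # keep first (lower grid index: grids examined in order)
      }
      seen <- rbind(seen,
                    data.frame(synapse_id = id, grid = loc$grid[i]))
      sampled[[length(sampled) + 1L]] <-
        data.frame(synapse_id = id, location_id = loc$location_id[i])
    }
  }
  sampleTab <- if (length(sampled)) do.call(rbind, sampled)
    else data.frame(synapse_id = integer(), location_id = integer())
  if (nrow(sampleTab)) {
    sampleTab$bouton_id <-
      syn$bouton_id[match(sampleTab$synapse_id, syn$synapse_id)]
    bout <- population[match(sampleTab$bouton_id, population$id), ,
                       drop = FALSE]
    rownames(bout) <- NULL
    out <- cbind(sampleTab, bout[setdiff(names(bout), "id")])
  } else {
    out <- cbind(sampleTab,
                 population[0, setdiff(names(population), "id"),
                            drop = FALSE])
  }
  tally <- table(factor(loc$status[loc$selected],
                        levels = c("empty", "soma", "synapse_sampled",
                                   "excluded")))
  list(sample = out, locations = loc[loc$selected, , drop = FALSE],
       tally = tally)
}
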