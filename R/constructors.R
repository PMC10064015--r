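#' Construct a MixtureSpec
#'
#' @param label character vector of component names.
#' @param weight strictly positive mixing fractions summing to 1.
#' @param mean component means (um^3), strictly increasing.
#' @param sd component standard deviations (um^3), strictly positive.
#' @param family `"LM"` or `"DNM"`.
#' @param mitoClass mitochondria class per component; defaults to `"LM"`
#'   for the LM family and `"DM"` for the DNM family.
#' @param origin putative origin per component; defaults to
#'   `"unassigned"`.
#'
#' @return A validated [MixtureSpec-class] object.
#' @examples
#' MixtureSpec(label = c("A", "B"), weight = c(0.4, 0.6),
#'             mean = c(1, 3), sd = c(0.3, 0.5), family = "LM")
#' @export
MixtureSpec <- function(label, weight, mean, sd, family,
                        mitoClass = NULL, origin = NULL) {
  k <- length(label)
  if (is.null(mitoClass))
    mitoClass <- rep(if (identical(family, "LM")) "LM" else "DM", k)
  if (is.null(origin))
    origin <- rep("unassigned", k)
  obj <- new("MixtureSpec", label = as.character(label),
             origin = as.character(origin),
             mitoClass = as.character(mitoClass),
             weight = as.numeric(weight), mean = as.numeric(mean),
             sd = as.numeric(sd), family = as.character(family))
  v <- validObject(obj, test = TRUE)
  if (!isTRUE(v))
    stop("invalid MixtureSpec: ", paste(v, collapse = "; "), call. = FALSE)
  obj
}

#' Construct a GridSpec
#'
#' The defaults reproduce the unbiased-terminal-sampling design: six
#' 15 x 15 grids of 2.5-um counting frames with reference sections 33
#' sections (2.475 um at 75 nm) apart, i.e. 1,350 numbered locations.
#'
#' @param gridsPerArray number of grids (default 6).
#' @param cellsPerSide frames per grid side (default 15).
#' @param frameSide frame side length in micrometres (default 2.5).
#' @param gridZSpacing sections between consecutive grid reference
#'   sections (default 33).
#' @param sectionThickness section thickness in nanometres (default 75).
#' @param referenceSections 0-based z indices of the grid reference
#'   sections; defaults to `0, gridZSpacing, 2 * gridZSpacing, ...`.
#'
#' @return A validated [GridSpec-class].
#' @examples
#' totalLocations(GridSpec())          # 1350
#' totalLocations(GridSpec(1, 2))      # 4
#' @export
GridSpec <- function(gridsPerArray = 6, cellsPerSide = 15,
                     frameSide = 2.5, gridZSpacing = 33,
                     sectionThickness = 75, referenceSections = NULL) {
  if (is.null(referenceSections))
    referenceSections <- as.integer(gridZSpacing) *
      (seq_len(gridsPerArray) - 1L)
  obj <- new("GridSpec", gridsPerArray = as.integer(gridsPerArray),
             cellsPerSide = as.integer(cellsPerSide),
             frameSide = as.numeric(frameSide),
             gridZSpacing = as.integer(gridZSpacing),
             sectionThickness = as.numeric(sectionThickness),
             referenceSections = as.integer(referenceSections))
  v <- validObject(obj, test = TRUE)
  if (!isTRUE(v))
    stop("invalid GridSpec: ", paste(v, collapse = "; "), call. = FALSE)
  obj
}

#' Construct a StackSpec
#'
#' @param dims stack dimensions in voxels, length-3 (x, y, z).
#' @param voxelSize voxel edge lengths in nanometres; default
#'   `c(5, 5, 75)`, the serial-blockface acquisition anisotropy.
#' @param density expected synapses per cubic micrometre.
#' @param blobRadius in-plane synapse blob radius in voxels.
#' @param blobRadiusZ axial blob radius in sections.
#'
#' @return A validated [StackSpec-class].
#' @export
StackSpec <- function(dims, voxelSize = c(5, 5, 75), density = 0.5,
                      blobRadius = 2, blobRadiusZ = 1) {
  obj <- new("StackSpec", dims = as.integer(dims),
             voxelSize = as.numeric(voxelSize),
             density = as.numeric(density),
             blobRadius = as.integer(blobRadius),
             blobRadiusZ = as.integer(blobRadiusZ))
  v <- validObject(obj, test = TRUE)
  if (!isTRUE(v))
    stop("invalid StackSpec: ", paste(v, collapse = "; "), call. = FALSE)
  obj
}

#' Construct a SegmentGenConfig
#'
#' Default compositions give every class a broad mix of input types,
#' with X-like segments rich in retinal (LM) and corticothalamic (DM1)
#' terminals so that the `epsilon` segregation dial has material to act
#' on, and interneuron segments dominated by retinal and inhibitory
#' input.
#'
#' @param nSegments named integer vector, segments per cell class;
#'   names among `interneuron`, `X_like`, `Y_like`.
#' @param composition numeric matrix (classes x item types over
#'   `LM, DM1..DM5`), rows summing to 1; `NULL` for the documented
#'   default.
#' @param epsilon LM/DM1 segregation strength on X-like segments in
#'   \[0, 1\]; 1 means the two types never share a segment.
#' @param terminalsPerSegment Poisson mean of terminals per segment
#'   (at least one terminal is always placed).
#' @param branchOrderProbs probabilities over primary, secondary,
#'   tertiary, quaternary branch order.
#'
#' @return A validated [SegmentGenConfig-class].
#' @export
SegmentGenConfig <- function(nSegments = c(interneuron = 10, X_like = 40,
                                           Y_like = 40),
                             composition = NULL, epsilon = 0,
                             terminalsPerSegment = 15,
                             branchOrderProbs = c(0.2, 0.4, 0.3, 0.1)) {
  items <- c("LM", "DM1", "DM2", "DM3", "DM4", "DM5")
  if (is.null(composition)) {
    composition <- rbind(
      interneuron = c(0.45, 0.05, 0.10, 0.25, 0.10, 0.05),
      X_like      = c(0.27, 0.24, 0.15, 0.20, 0.10, 0.04),
      Y_like      = c(0.10, 0.30, 0.20, 0.25, 0.10, 0.05)
    )
    colnames(composition) <- items
    composition <- composition[intersect(rownames(composition),
                                         names(nSegments)), , drop = FALSE]
  }
  ns <- nSegments
  storage.mode(ns) <- "integer"
  obj <- new("SegmentGenConfig", nSegments = ns,
             composition = composition, epsilon = as.numeric(epsilon),
             terminalsPerSegment = as.numeric(terminalsPerSegment),
             branchOrderProbs = as.numeric(branchOrderProbs))
  v <- validObject(obj, test = TRUE)
  if (!isTRUE(v))
    stop("invalid SegmentGenConfig: ", paste(v, collapse = "; "),
         call. = FALSE)
  obj
}
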