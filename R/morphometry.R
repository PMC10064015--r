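#' Dendrite caliber from volume and length
#'
#' Under the assumption that a dendrite segment is roughly cylindrical,
#' its caliber (diameter) is `d = 2 * sqrt(volume / (length * pi))`.
#' For an exact cylinder of radius `r` this returns `2 r`.
#'
#' @param volume segment volume in um^3, positive.
#' @param length segment length in um, positive.
#' @return caliber in um.
#' @examples
#' caliber(pi * 0.5^2 * 10, 10)  # 1: cylinder of radius 0.5
#' @export
caliber <- function(volume, length) {
  if (any(!is.finite(volume)) || any(volume <= 0))
    stop("volume must be positive", call. = FALSE)
  if (any(!is.finite(length)) || any(length <= 0))
    stop("length must be positive", call. = FALSE)
  2 * sqrt(volume / (length * pi))
}

#' Classify a dendrite segment's cell type from morphological flags
#'
#' A segment with any presynaptic zone is an interneuron dendrite
#' (takes precedence: relay subtyping applies only to dendrites without
#' presynaptic zones). Among relay dendrites, triad/F2 input without
#' dendrodendritic puncta adherentia marks the X-like relay type, PA
#' without triads the Y-like type, and neither leaves the segment
#' unclassified. Triad and PA on the same relay segment is flagged as a
#' data inconsistency (the two features never co-occur on one segment).
#'
#' @param hasPresynapticZone,hasTriadOrF2,hasPA logical vectors
#'   (recycled to a common length).
#' @return character vector over `interneuron`, `X_like`, `Y_like`,
#'   `unclassified`.
#' @examples
#' classifyCellType(FALSE, TRUE, FALSE)  # "X_like"
#' @export
classifyCellType <- function(hasPresynapticZone, hasTriadOrF2, hasPA) {
  n <- max(length(hasPresynapticZone), length(hasTriadOrF2),
           length(hasPA))
  pre <- rep_len(as.logical(hasPresynapticZone), n)
  tri <- rep_len(as.logical(hasTriadOrF2), n)
  pa <- rep_len(as.logical(hasPA), n)
  bad <- !pre & tri & pa
  if (any(bad))
    stop("inconsistency error: triad and dendrodendritic PA flagged on ",
         "the same relay segment (rows ",
         paste(which(bad), collapse = ", "), ")", call. = FALSE)
  out <- rep("unclassified", n)
  out[pre] <- "interneuron"
  out[!pre & tri] <- "X_like"
  out[!pre & !tri & pa] <- "Y_like"
  out
}

#' Synapse density along a dendrite segment
#'
#' @param synapseCount number of synapses on the segment.
#' @param length segment length in um, positive.
#' @return synapses per um.
#' @examples
#' synapseDensity(3, 2.5)  # 1.2
#' @export
synapseDensity <- function(synapseCount, length) {
  if (any(!is.finite(length)) || any(length <= 0))
    stop("length must be positive", call. = FALSE)
  synapseCount / length
}

#' Append derived morphometry columns to a segment table
#'
#' Adds `caliber_um` (from `volume_um3` and `length_um`), `cell_class`
#' (from the morphological flags) and `synapses_per_um`.
#'
#' @param segments data.frame with columns `length_um`, `volume_um3`,
#'   `has_presynaptic_zone`, `has_triad_or_f2_input`,
#'   `has_dendrodendritic_pa` and `synapse_count`.
#' @return `segments` with derived columns appended (existing derived
#'   columns are recomputed).
#' @export
annotateSegments <- function(segments) {
  need <- c("length_um", "volume_um3", "has_presynaptic_zone",
            "has_triad_or_f2_input", "has_dendrodendritic_pa",
            "synapse_count")
  miss <- setdiff(need, names(segments))
  if (length(miss))
    stop("segment table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  segments$caliber_um <- caliber(segments$volume_um3, segments$length_um)
  segments$cell_class <- classifyCellType(
    segments$has_presynaptic_zone, segments$has_triad_or_f2_input,
    segments$has_dendrodendritic_pa)
  segments$synapses_per_um <-
    synapseDensity(segments$synapse_count, segments$length_um)
  segments
}
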