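#' Map mitochondria class to bouton family
#'
#' Light-mitochondria boutons form the LM (putative retinal) family;
#' dark- and no-mitochondria boutons are combined into the DNM family
#' (every no-mitochondria bouton connects to an axon with dark
#' mitochondria).
#'
#' @param mitoClass character vector over `"LM"`, `"DM"`, `"NM"`.
#' @return character vector over `"LM"`, `"DNM"`.
#' @examples
#' assignFamily(c("LM", "DM", "NM"))
#' @export
assignFamily <- function(mitoClass) {
  bad <- !mitoClass %in% c("LM", "DM", "NM")
  if (any(bad))
    stop("parse error: unknown mitochondria class token(s): ",
         paste(unique(mitoClass[bad]), collapse = ", "), call. = FALSE)
  ifelse(mitoClass == "LM", "LM", "DNM")
}

#' Assign volume-sorted subpopulation labels
#'
#' Bins volumes into the `k` subpopulations delimited by a family's
#' `k - 1` cutoffs. Bins are half-open `[low, high)`: a volume exactly
#' equal to a cutoff belongs to the upper bin.
#'
#' @param volume positive numeric vector (um^3).
#' @param family `"LM"` or `"DNM"` (scalar or vector).
#' @param cutoffs a [CutoffSet-class] or a strictly increasing numeric
#'   vector of boundaries for that family.
#' @return character vector of labels (`LM1..LMk` or `DM1..DMk`).
#' @examples
#' assignSubpopulation(c(0.15, 0.22, 2.5), "DNM",
#'                     c(0.22, 0.39, 0.75, 1.95))
#' @export
assignSubpopulation <- function(volume, family, cutoffs) {
  b <- if (is(cutoffs, "CutoffSet")) boundaries(cutoffs) else
    as.numeric(cutoffs)
  if (length(b) >= 2L && any(diff(b) <= 0))
    stop("cutoffs must be strictly increasing", call. = FALSE)
  if (any(volume <= 0))
    stop("volumes must be positive", call. = FALSE)
  idx <- findInterval(volume, b) + 1L # count of boundaries <= v
  prefix <- ifelse(family == "LM", "LM", "DM")
  paste0(prefix, idx)
}

.DEFAULT_ORIGIN_MAP <- c(
  LM1 = "retinal", LM2 = "retinal", LM3 = "retinal", LM4 = "retinal",
  DM1 = "corticothalamic", DM2 = "brainstem",
  DM3 = "inhibitory", DM4 = "inhibitory", DM5 = "RLD")

#' Map subpopulation labels to putative origins
#'
#' Default attributions: all LM subpopulations retinal; DM1
#' corticothalamic; DM2 brainstem; DM3-DM4 inhibitory; DM5 RLD
#' (round-vesicle large dark-mitochondria terminals of unknown,
#' possibly relay-collateral, origin). The map is configurable because
#' these origins are putative.
#'
#' @param subpop character vector of subpopulation labels.
#' @param originMap named character vector overriding the default map.
#' @return character vector of putative origins.
#' @examples
#' mapOrigin(c("LM2", "DM1", "DM5"))
#' @export
mapOrigin <- function(subpop, originMap = .DEFAULT_ORIGIN_MAP) {
  out <- unname(originMap[subpop])
  out[is.na(out) & !is.na(subpop)] <- "unknown"
  out
}

#' Classify a bouton table into families, subpopulations and origins
#'
#' @param boutons data.frame with columns `volume` and `mito_class`.
#' @param cutoffsLM,cutoffsDNM [CutoffSet-class] (or numeric
#'   boundaries) for the two families.
#' @param originMap optional override for [mapOrigin()].
#' @return `boutons` with `family`, `subpop`, `putative_origin`
#'   appended.
#' @export
classifyBoutons <- function(boutons, cutoffsLM, cutoffsDNM,
                            originMap = .DEFAULT_ORIGIN_MAP) {
  stopifnot(all(c("volume", "mito_class") %in% names(boutons)))
  fam <- assignFamily(boutons$mito_class)
  sub <- character(nrow(boutons))
  isLM <- fam == "LM"
  if (any(isLM))
    sub[isLM] <- assignSubpopulation(boutons$volume[isLM], "LM",
                                     cutoffsLM)
  if (any(!isLM))
    sub[!isLM] <- assignSubpopulation(boutons$volume[!isLM], "DNM",
                                      cutoffsDNM)
  boutons$family <- fam
  boutons$subpop <- sub
  boutons$putative_origin <- mapOrigin(sub, originMap)
  boutons
}

#' Summarise subpopulation composition
#'
#' Percent contribution of each subpopulation (and putative origin)
#' among classified boutons, optionally grouped by host cell class or
#' segment. Percentages within each group sum to 100.
#'
#' @param boutons classified bouton table (needs `subpop` and
#'   `putative_origin`; `segment_id` when grouping).
#' @param groupBy `"none"`, `"cell_class"` or `"segment"`.
#' @param segments segment table mapping `segment_id` to `cell_class`
#'   (required for `groupBy = "cell_class"`).
#' @return data.frame with columns `group`, `subpop`,
#'   `putative_origin`, `count`, `percent`.
#' @export
compositionSummary <- function(boutons,
                               groupBy = c("none", "cell_class",
                                           "segment"),
                               segments = NULL) {
  groupBy <- match.arg(groupBy)
  if (!all(c("subpop", "putative_origin") %in% names(boutons)))
    stop("boutons must be classified first (see classifyBoutons)",
         call. = FALSE)
  grp <- switch(groupBy,
    none = rep("all", nrow(boutons)),
    segment = as.character(boutons$segment_id),
    cell_class = {
      if (is.null(segments))
        stop("segments table required for groupBy = \"cell_class\"",
             call. = FALSE)
      as.character(
        segments$cell_class[match(boutons$segment_id,
                                  segments$segment_id)])
    })
  keep <- !is.na(grp)
  if (any(!keep)) {
    warning(sum(!keep), " bouton(s) without group dropped")
    boutons <- boutons[keep, , drop = FALSE]
    grp <- grp[keep]
  }
  if (nrow(boutons) == 0L)
    stop("no boutons to summarise", call. = FALSE)
  pieces <- split(boutons, grp)
  out <- do.call(rbind, lapply(names(pieces), function(g) {
    b <- pieces[[g]]
    tab <- table(b$subpop)
    data.frame(group = g, subpop = names(tab),
               putative_origin = mapOrigin(names(tab)),
               count = as.integer(tab),
               percent = 100 * as.integer(tab) / nrow(b),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[, c("group", "subpop", "putative_origin", "count", "percent")]
}
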