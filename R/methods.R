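#' @rdname accessors
#' @export
setGeneric("nComponents", function(x) standardGeneric("nComponents"))
#' @rdname accessors
#' @export
setGeneric("componentTable", function(x) standardGeneric("componentTable"))
#' @rdname accessors
#' @export
setGeneric("mixtureFamily", function(x) standardGeneric("mixtureFamily"))
#' @rdname accessors
#' @export
setGeneric("boundaries", function(x) standardGeneric("boundaries"))
#' @rdname accessors
#' @export
setGeneric("bicTable", function(x) standardGeneric("bicTable"))
#' @rdname accessors
#' @export
setGeneric("outstrength", function(x) standardGeneric("outstrength"))
#' @rdname accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))
#' @rdname accessors
#' @export
setGeneric("stackLabels", function(x) standardGeneric("stackLabels"))
#' @rdname accessors
#' @export
setGeneric("synapseTable", function(x) standardGeneric("synapseTable"))
#' @rdname accessors
#' @export
setGeneric("totalLocations", function(x) standardGeneric("totalLocations"))
#' @rdname accessors
#' @export
setGeneric("transactionItems", function(x) standardGeneric("transactionItems"))

#' Accessors for boutonsort S4 classes
#'
#' Small read-only accessors; user code should use these rather than
#' reaching into slots.
#'
#' @param x an object of the documented class.
#' @return `nComponents`: integer. `componentTable`: data.frame of
#'   per-component parameters. `mixtureFamily`: character scalar.
#'   `boundaries`: numeric vector of cutoff volumes. `bicTable`:
#'   data.frame of the (k, variance model) BIC scan. `outstrength`:
#'   named numeric. `networkEdges`: data.frame of retained directed
#'   edges. `stackLabels`: 3-D integer array. `synapseTable`:
#'   data.frame. `totalLocations`: integer count of counting-frame
#'   locations. `transactionItems`: list of character itemsets.
#' @name accessors
NULL

#' @rdname accessors
setMethod("nComponents", "MixtureSpec", function(x) length(x@label))
#' @rdname accessors
setMethod("nComponents", "MixtureFit", function(x) x@k)

#' @rdname accessors
setMethod("componentTable", "MixtureSpec", function(x)
  data.frame(label = x@label, origin = x@origin, mito_class = x@mitoClass,
             weight = x@weight, mean = x@mean, sd = x@sd,
             stringsAsFactors = FALSE))
#' @rdname accessors
setMethod("componentTable", "MixtureFit", function(x)
  data.frame(component = seq_len(x@k), weight = x@weight, mean = x@mean,
             sd = x@sd, stringsAsFactors = FALSE))

#' @rdname accessors
setMethod("mixtureFamily", "MixtureSpec", function(x) x@family)
#' @rdname accessors
setMethod("mixtureFamily", "CutoffSet", function(x) x@family)

#' @rdname accessors
setMethod("boundaries", "CutoffSet", function(x) x@boundaries)

#' @rdname accessors
setMethod("bicTable", "MixtureFit", function(x) x@bicTable)

#' @rdname accessors
setMethod("outstrength", "NetworkModel", function(x) x@outstrength)
#' @rdname accessors
setMethod("networkEdges", "NetworkModel", function(x) x@edges)

#' @rdname accessors
setMethod("stackLabels", "LabelStack", function(x) x@labels)
#' @rdname accessors
setMethod("synapseTable", "LabelStack", function(x) x@synapses)

#' @rdname accessors
setMethod("totalLocations", "GridSpec", function(x)
  x@gridsPerArray * x@cellsPerSide * x@cellsPerSide)

#' @rdname accessors
setMethod("transactionItems", "TransactionSet", function(x) x@items)

setMethod("show", "MixtureSpec", function(object) {
  cat(sprintf("MixtureSpec (%s family, %d components)\n",
              object@family, length(object@label)))
  print(componentTable(object), row.names = FALSE, digits = 4)
})

setMethod("show", "MixtureFit", function(object) {
  cat(sprintf(
    "MixtureFit: k = %d (%s variance), n = %d\n  loglik = %.3f, BIC = %.3f%s\n",
    object@k, object@varianceModel, object@n, object@loglik, object@bic,
    if (object@converged) "" else "  [not converged]"))
  print(componentTable(object), row.names = FALSE, digits = 4)
})

setMethod("show", "CutoffSet", function(object) {
  cat(sprintf("CutoffSet (%s, %s): %s um^3\n", object@family,
              object@method,
              paste(formatC(object@boundaries, digits = 3, format = "fg"),
                    collapse = "; ")))
  if (object@method == "monte_carlo")
    cat(sprintf("  %d iterations, size multiplier %d\n",
                object@iterations, object@multiplier))
})

setMethod("show", "GridSpec", function(object) {
  cat(sprintf(
    "GridSpec: %d grids of %dx%d frames (%.2f um side) -> %d locations\n",
    object@gridsPerArray, object@cellsPerSide, object@cellsPerSide,
    object@frameSide, totalLocations(object)))
  cat(sprintf("  reference sections %s (%d sections apart, %.0f nm thick)\n",
              paste(object@referenceSections, collapse = ", "),
              object@gridZSpacing, object@sectionThickness))
})

setMethod("show", "LabelStack", function(object) {
  d <- dim(object@labels)
  cat(sprintf(
    "LabelStack: %d x %d x %d voxels at (%g, %g, %g) nm, %d synapses\n",
    d[1], d[2], d[3], object@voxelSize[1], object@voxelSize[2],
    object@voxelSize[3], nrow(object@synapses)))
})

setMethod("show", "TransactionSet", function(object) {
  cat(sprintf(
    "TransactionSet: %d segments over alphabet {%s}\n",
    length(object@items), paste(object@alphabet, collapse = ", ")))
})

setMethod("show", "NetworkModel", function(object) {
  cat(sprintf("NetworkModel: %d nodes, %d retained edges\n",
              length(object@nodes), nrow(object@edges)))
  cat("  outstrength:\n")
  print(round(object@outstrength, 3))
})
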