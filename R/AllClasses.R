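#' @import methods
NULL

#' MixtureSpec: a finite mixture of positive-support normal components
#'
#' Describes one bouton-volume family (light-mitochondria `LM` or
#' dark/no-mitochondria `DNM`) as an ordered finite mixture of normal
#' components truncated at zero. Component order follows the component
#' means (ascending).
#'
#' @slot label character, one name per component (e.g. `"DM1"`).
#' @slot origin character, putative anatomical origin per component.
#' @slot mitoClass character, mitochondria class per component
#'   (`"LM"`, `"DM"` or `"NM"`).
#' @slot weight numeric, strictly positive mixing fractions summing to 1.
#' @slot mean numeric, component means in cubic micrometres, strictly
#'   increasing.
#' @slot sd numeric, component standard deviations in cubic micrometres,
#'   strictly positive.
#' @slot family character scalar, `"LM"` or `"DNM"`.
#'
#' @seealso [MixtureSpec()], [defaultMixtures()]
#' @exportClass MixtureSpec
setClass("MixtureSpec",
  representation(
    label = "character",
    origin = "character",
    mitoClass = "character",
    weight = "numeric",
    mean = "numeric",
    sd = "numeric",
    family = "character"
  )
)

setValidity("MixtureSpec", function(object) {
  k <- length(object@label)
  msg <- character()
  lens <- c(length(object@origin), length(object@mitoClass),
            length(object@weight), length(object@mean), length(object@sd))
  if (any(lens != k))
    msg <- c(msg, "component slots must all have the same length")
  if (k == 0L)
    msg <- c(msg, "at least one component required")
  if (length(msg) == 0L) {
    if (any(object@weight <= 0))
      msg <- c(msg, "component weights must be strictly positive")
    if (abs(sum(object@weight) - 1) > 1e-9)
      msg <- c(msg, "component weights must sum to 1 (within 1e-9)")
    if (k > 1L && any(diff(object@mean) <= 0))
      msg <- c(msg, "component means must be strictly increasing")
    if (any(object@sd <= 0))
      msg <- c(msg, "component sds must be strictly positive")
    if (!length(object@family) == 1L || !object@family %in% c("LM", "DNM"))
      msg <- c(msg, "family must be \"LM\" or \"DNM\"")
    if (!all(object@mitoClass %in% c("LM", "DM", "NM")))
      msg <- c(msg, "mitoClass entries must be LM, DM or NM")
  }
  if (length(msg)) msg else TRUE
})

#' MixtureFit: a fitted one-dimensional Gaussian mixture
#'
#' Result of [fitEM()] or [selectByBIC()]. Components are reported
#' sorted by ascending mean. The BIC convention is the model-based
#' clustering one, `2 * loglik - p * log(n)`, selected by *highest* BIC.
#' The free-parameter count `p` is `(k - 1) + k + k` for the free-variance
#' model and `(k - 1) + k + 1` for the equal-variance model.
#'
#' @slot k integer, number of components.
#' @slot weight,mean,sd numeric, component parameters (means ascending).
#' @slot loglik numeric, maximised log-likelihood (nats).
#' @slot bic numeric, `2 * loglik - p * log(n)`.
#' @slot varianceModel character, `"equal"` or `"free"`.
#' @slot n integer, sample size the model was fitted to.
#' @slot converged logical, whether EM met the relative-change tolerance.
#' @slot bicTable data.frame, per (k, variance model) BIC scan when the
#'   fit came from [selectByBIC()]; zero-row otherwise.
#'
#' @exportClass MixtureFit
setClass("MixtureFit",
  representation(
    k = "integer",
    weight = "numeric",
    mean = "numeric",
    sd = "numeric",
    loglik = "numeric",
    bic = "numeric",
    varianceModel = "character",
    n = "integer",
    converged = "logical",
    bicTable = "data.frame"
  )
)

setValidity("MixtureFit", function(object) {
  msg <- character()
  k <- object@k
  if (length(object@weight) != k || length(object@mean) != k ||
      length(object@sd) != k)
    msg <- c(msg, "weight/mean/sd must have length k")
  else {
    if (abs(sum(object@weight) - 1) > 1e-9)
      msg <- c(msg, "weights must sum to 1 (within 1e-9)")
    if (k > 1L && any(diff(object@mean) < 0))
      msg <- c(msg, "means must be sorted ascending")
    if (any(object@sd < sqrt(.varianceFloor())))
      msg <- c(msg, "sds fell below the variance floor")
  }
  if (!object@varianceModel %in% c("equal", "free"))
    msg <- c(msg, "varianceModel must be \"equal\" or \"free\"")
  if (length(msg)) msg else TRUE
})

#' CutoffSet: volume boundaries between adjacent subpopulations
#'
#' Ordered classification thresholds (cubic micrometres) between the
#' `k` volume-sorted subpopulations of one family; `k - 1` boundaries,
#' strictly increasing, each lying between the adjacent component means.
#'
#' @slot family character, `"LM"` or `"DNM"`.
#' @slot boundaries numeric, strictly increasing cutoff volumes.
#' @slot method character, `"analytic"` or `"monte_carlo"`.
#' @slot iterations integer, Monte Carlo iteration count (1 for analytic).
#' @slot multiplier integer, simulated-size multiplier (Monte Carlo).
#' @slot boundarySD numeric, per-boundary SD across iterations (`NA` for
#'   analytic).
#'
#' @exportClass CutoffSet
setClass("CutoffSet",
  representation(
    family = "character",
    boundaries = "numeric",
    method = "character",
    iterations = "integer",
    multiplier = "integer",
    boundarySD = "numeric"
  )
)

setValidity("CutoffSet", function(object) {
  msg <- character()
  b <- object@boundaries
  if (length(b) >= 2L && any(diff(b) <= 0))
    msg <- c(msg, "boundaries must be strictly increasing")
  if (!object@method %in% c("analytic", "monte_carlo"))
    msg <- c(msg, "method must be \"analytic\" or \"monte_carlo\"")
  if (object@iterations < 1L)
    msg <- c(msg, "iterations must be >= 1")
  if (length(object@boundarySD) != length(b))
    msg <- c(msg, "boundarySD must match boundaries in length")
  if (length(msg)) msg else TRUE
})

#' GridSpec: geometry of a stereological counting-frame array
#'
#' Defines a 3-D array of unbiased counting frames: `gridsPerArray`
#' square grids of `cellsPerSide` x `cellsPerSide` frames, each frame
#' `frameSide` micrometres on a side, with grid reference sections
#' `gridZSpacing` sections apart at `sectionThickness` nanometres per
#' section. The default geometry (6 grids of 15 x 15 frames of 2.5 um,
#' 33 sections apart at 75 nm) yields 1,350 numbered locations.
#'
#' @slot gridsPerArray integer.
#' @slot cellsPerSide integer.
#' @slot frameSide numeric, micrometres.
#' @slot gridZSpacing integer, sections between consecutive reference
#'   sections.
#' @slot sectionThickness numeric, nanometres.
#' @slot referenceSections integer, 0-based z index of each grid's
#'   reference section.
#'
#' @exportClass GridSpec
setClass("GridSpec",
  representation(
    gridsPerArray = "integer",
    cellsPerSide = "integer",
    frameSide = "numeric",
    gridZSpacing = "integer",
    sectionThickness = "numeric",
    referenceSections = "integer"
  )
)

setValidity("GridSpec", function(object) {
  msg <- character()
  if (object@gridsPerArray < 1L || object@cellsPerSide < 1L)
    msg <- c(msg, "gridsPerArray and cellsPerSide must be >= 1")
  if (object@frameSide <= 0)
    msg <- c(msg, "frameSide must be positive")
  if (object@gridZSpacing < 1L)
    msg <- c(msg, "gridZSpacing must be >= 1")
  if (object@sectionThickness <= 0)
    msg <- c(msg, "sectionThickness must be positive")
  if (length(object@referenceSections) != object@gridsPerArray)
    msg <- c(msg, "one reference section required per grid")
  if (length(msg)) msg else TRUE
})

#' StackSpec: geometry and content parameters of a synthetic label stack
#'
#' @slot dims integer, stack size in voxels (x, y, z).
#' @slot voxelSize numeric, voxel edge lengths in nanometres (x, y, z);
#'   the serial-blockface default is (5, 5, 75).
#' @slot density numeric, expected synapses per cubic micrometre.
#' @slot blobRadius integer, in-plane blob radius in voxels.
#' @slot blobRadiusZ integer, axial blob radius in sections.
#'
#' @exportClass StackSpec
setClass("StackSpec",
  representation(
    dims = "integer",
    voxelSize = "numeric",
    density = "numeric",
    blobRadius = "integer",
    blobRadiusZ = "integer"
  )
)

setValidity("StackSpec", function(object) {
  msg <- character()
  if (length(object@dims) != 3L || any(object@dims < 1L))
    msg <- c(msg, "dims must be three positive voxel counts")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be three positive lengths (nm)")
  if (object@density < 0)
    msg <- c(msg, "density must be non-negative")
  if (object@blobRadius < 0L || object@blobRadiusZ < 0L)
    msg <- c(msg, "blob radii must be non-negative")
  if (length(msg)) msg else TRUE
})

#' LabelStack: an annotated 3-D label volume plus its synapse table
#'
#' Voxel labels are non-negative integers: 0 is background, each synapse
#' blob carries a unique positive id. The synapse table maps ids to the
#' generating bouton record and the blob centroid (0-based voxel
#' coordinates).
#'
#' @slot labels integer array, dim (x, y, z).
#' @slot voxelSize numeric, nanometres (x, y, z).
#' @slot synapses data.frame with columns `synapse_id`, `bouton_id`,
#'   `cx`, `cy`, `cz` (0-based centroid voxel coordinates).
#'
#' @exportClass LabelStack
setClass("LabelStack",
  representation(
    labels = "array",
    voxelSize = "numeric",
    synapses = "data.frame"
  )
)

setValidity("LabelStack", function(object) {
  msg <- character()
  if (length(dim(object@labels)) != 3L)
    msg <- c(msg, "labels must be a 3-D array")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be three positive lengths (nm)")
  need <- c("synapse_id", "bouton_id", "cx", "cy", "cz")
  if (!all(need %in% names(object@synapses)))
    msg <- c(msg, paste("synapse table needs columns:",
                        paste(need, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' SegmentGenConfig: generator settings for synthetic dendrite segments
#'
#' Controls the per-segment co-occurrence generator: how many segments
#' of each cell class, the per-class probability of each item type
#' appearing among a segment's terminals, how strongly retinal (LM) and
#' corticothalamic (DM1) items are segregated on X-like segments
#' (`epsilon`, 1 = never co-occur), and the terminals-per-segment
#' Poisson mean.
#'
#' @slot nSegments named integer, segments per cell class
#'   (`interneuron`, `X_like`, `Y_like`).
#' @slot composition numeric matrix, rows = cell classes, columns = item
#'   types over `c("LM", "DM1".."DM5")`; each entry is the relative
#'   frequency of that item among the class's terminals (rows sum to 1).
#' @slot epsilon numeric in \[0, 1\], LM/DM1 segregation strength on
#'   X-like segments.
#' @slot terminalsPerSegment numeric, Poisson mean of the per-segment
#'   terminal count (minimum 1 enforced).
#' @slot branchOrderProbs numeric, probabilities over
#'   primary/secondary/tertiary/quaternary.
#'
#' @exportClass SegmentGenConfig
setClass("SegmentGenConfig",
  representation(
    nSegments = "integer",
    composition = "matrix",
    epsilon = "numeric",
    terminalsPerSegment = "numeric",
    branchOrderProbs = "numeric"
  )
)

setValidity("SegmentGenConfig", function(object) {
  msg <- character()
  if (is.null(names(object@nSegments)) ||
      !all(names(object@nSegments) %in% c("interneuron", "X_like", "Y_like")))
    msg <- c(msg, "nSegments must be named with known cell classes")
  if (any(object@nSegments < 0L))
    msg <- c(msg, "segment counts must be non-negative")
  comp <- object@composition
  if (any(comp < 0) || any(comp > 1))
    msg <- c(msg, "composition probabilities must lie in [0, 1]")
  if (nrow(comp) > 0 && any(abs(rowSums(comp) - 1) > 1e-9))
    msg <- c(msg, "composition rows must sum to 1")
  if (object@epsilon < 0 || object@epsilon > 1)
    msg <- c(msg, "epsilon must lie in [0, 1]")
  if (object@terminalsPerSegment <= 0)
    msg <- c(msg, "terminalsPerSegment must be positive")
  if (abs(sum(object@branchOrderProbs) - 1) > 1e-9)
    msg <- c(msg, "branchOrderProbs must sum to 1")
  if (length(msg)) msg else TRUE
})

#' TransactionSet: per-segment itemsets over the bouton-type alphabet
#'
#' One itemset per dendrite segment; items are unique within an itemset
#' and drawn from a fixed alphabet (by default `LM`, `DM1`..`DM5` after
#' grouping the four retinal subpopulations into one `LM` item).
#'
#' @slot items list of character vectors, one per segment.
#' @slot segmentIds character, segment identifiers.
#' @slot alphabet character, full item alphabet.
#' @slot filterThreshold numeric, per-segment share below which an item
#'   type was dropped on large segments.
#' @slot minTerminals integer, segment size at and above which the
#'   rare-occurrence filter applies.
#'
#' @exportClass TransactionSet
setClass("TransactionSet",
  representation(
    items = "list",
    segmentIds = "character",
    alphabet = "character",
    filterThreshold = "numeric",
    minTerminals = "integer"
  )
)

setValidity("TransactionSet", function(object) {
  msg <- character()
  if (length(object@items) != length(object@segmentIds))
    msg <- c(msg, "one segment id per itemset required")
  if (any(vapply(object@items, anyDuplicated, 0L) > 0L))
    msg <- c(msg, "items must be unique within an itemset")
  bad <- !vapply(object@items,
                 function(x) all(x %in% object@alphabet), TRUE)
  if (any(bad))
    msg <- c(msg, "itemsets contain items outside the alphabet")
  if (length(msg)) msg else TRUE
})

#' NetworkModel: confidence-weighted directed network of bouton types
#'
#' Nodes are bouton types; a directed edge A -> B carries the rule
#' confidence of "if A occurs on a segment, B occurs too". Outstrength
#' (the outflow centrality) is the sum of a node's outgoing edge
#' weights over retained edges.
#'
#' @slot nodes character, item alphabet.
#' @slot edges data.frame with columns `from`, `to`, `confidence`,
#'   `support`, `lift`.
#' @slot outstrength named numeric, one value per node.
#' @slot minSupport,minConfidence numeric, edge retention thresholds.
#'
#' @exportClass NetworkModel
setClass("NetworkModel",
  representation(
    nodes = "character",
    edges = "data.frame",
    outstrength = "numeric",
    minSupport = "numeric",
    minConfidence = "numeric"
  )
)

setValidity("NetworkModel", function(object) {
  msg <- character()
  if (length(object@outstrength) != length(object@nodes))
    msg <- c(msg, "one outstrength value per node required")
  if (any(object@outstrength < 0))
    msg <- c(msg, "outstrength must be non-negative")
  n <- length(object@nodes)
  if (nrow(object@edges) > n * (n - 1))
    msg <- c(msg, "more edges than ordered node pairs")
  if (length(msg)) msg else TRUE
})
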