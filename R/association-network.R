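#' Build per-segment transactions from classified boutons
#'
#' Turns a classified bouton table into one itemset per dendrite
#' segment over the item alphabet. By default the four retinal
#' subpopulations are grouped into a single `LM` item (all retinal
#' boutons grouped), giving the alphabet `LM, DM1..DM5`. On segments
#' carrying at least `minTerminals` terminals, an item type whose share
#' of that segment's terminals is below `filterThreshold` is dropped
#' from the segment's itemset - the rare-occurrence filter that
#' excludes incidental single contacts on heavily innervated segments.
#' Segments left with no items are dropped with a warning. Transactions
#' are binary presence sets; multiplicity is used only by the filter.
#'
#' @param boutons classified bouton table with `subpop` and
#'   `segment_id` columns.
#' @param groupLM collapse `LM1..LM4` into one `LM` item (default
#'   TRUE).
#' @param filterThreshold minimum per-segment share for an item type on
#'   large segments (default 0.025).
#' @param minTerminals segment size at and above which the filter
#'   applies (default 40).
#'
#' @return A [TransactionSet-class].
#' @export
buildTransactions <- function(boutons, groupLM = TRUE,
                              filterThreshold = 0.025,
                              minTerminals = 40L) {
  if (!all(c("subpop", "segment_id") %in% names(boutons)))
    stop("boutons must carry subpop labels and segment ids",
         call. = FALSE)
  if (any(is.na(boutons$subpop)) || any(is.na(boutons$segment_id)))
    stop("unlabeled bouton (missing subpop or segment id)",
         call. = FALSE)
  item <- boutons$subpop
  if (groupLM) item[grepl("^LM", item)] <- "LM"
  alphabet <- if (groupLM) c("LM", "DM1", "DM2", "DM3", "DM4", "DM5")
    else c(paste0("LM", 1:4), paste0("DM", 1:5))
  pieces <- split(item, as.character(boutons$segment_id))
  itemsets <- lapply(pieces, function(it) {
    nTot <- length(it)
    tab <- table(it)
    if (nTot >= minTerminals)
      tab <- tab[tab / nTot >= filterThreshold]
    names(tab)
  })
  empty <- lengths(itemsets) == 0L
  if (any(empty)) {
    warning(sum(empty),
            " segment(s) with no surviving items dropped")
    itemsets <- itemsets[!empty]
  }
  new("TransactionSet",
      items = unname(lapply(itemsets, as.character)),
      segmentIds = names(itemsets),
      alphabet = alphabet,
      filterThreshold = filterThreshold,
      minTerminals = as.integer(minTerminals))
}

#' Mine pairwise association rules from a transaction set
#'
#' Exact counting over the transactions (no sampling): for every
#' ordered pair (A, B) of alphabet items with `support(A) > 0`,
#' computes `support(A)`, `support(A, B)` (fraction of transactions
#' containing both), `confidence = support(A, B) / support(A)` and
#' `lift = support(A, B) / (support(A) * support(B))`. Lift is
#' symmetric in A and B; a lift of 1 means co-occurrence at chance,
#' below 1 avoidance, 0 never co-occurring.
#'
#' @param tx a [TransactionSet-class] with at least one transaction.
#' @return data.frame with columns `antecedent`, `consequent`,
#'   `support_a`, `support_b`, `support_ab`, `confidence`, `lift`.
#' @examples
#' tx <- new("TransactionSet",
#'           items = list(c("A", "B"), c("A", "B"), "A", "B"),
#'           segmentIds = as.character(1:4), alphabet = c("A", "B"),
#'           filterThreshold = 0, minTerminals = 0L)
#' mineRules(tx)  # confidence(A->B) = 2/3, lift = 8/9
#' @export
mineRules <- function(tx) {
  items <- transactionItems(tx)
  N <- length(items)
  if (N == 0L)
    stop("empty transaction set", call. = FALSE)
  alpha <- tx@alphabet
  inc <- vapply(alpha, function(a)
    vapply(items, function(s) a %in% s, TRUE), logical(N))
  inc <- matrix(inc, nrow = N) # N x |alphabet|
  colnames(inc) <- alpha
  supp <- colSums(inc) / N
  co <- crossprod(inc) / N # support(A union B)
  rows <- list()
  for (a in alpha) {
    if (supp[a] == 0) next
    for (b in setdiff(alpha, a)) {
      sab <- co[a, b]
      lift <- if (supp[b] > 0) sab / (supp[a] * supp[b]) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        antecedent = a, consequent = b,
        support_a = supp[[a]], support_b = supp[[b]],
        support_ab = sab, confidence = sab / supp[[a]], lift = lift,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build the confidence-weighted directed network from a rule table
#'
#' Retains rules with `support_ab >= minSupport` and
#' `confidence >= minConfidence` as directed edges A -> B weighted by
#' confidence, and computes each node's outstrength (the outflow
#' centrality): the sum of its outgoing retained edge weights.
#'
#' @param rules rule table from [mineRules()].
#' @param minSupport minimum pair support for an edge (default 0.1).
#' @param minConfidence minimum confidence for an edge (default 0).
#' @param nodes node alphabet; defaults to the items appearing in
#'   `rules`.
#' @return A [NetworkModel-class].
#' @export
buildNetwork <- function(rules, minSupport = 0.1, minConfidence = 0,
                         nodes = NULL) {
  if (is.null(nodes))
    nodes <- sort(unique(c(rules$antecedent, rules$consequent)))
  keep <- rules$support_ab >= minSupport &
    rules$confidence >= minConfidence
  edges <- rules[keep, c("antecedent", "consequent", "confidence",
                         "support_ab", "lift")]
  names(edges) <- c("from", "to", "confidence", "support", "lift")
  rownames(edges) <- NULL
  outs <- vapply(nodes, function(a)
    sum(edges$confidence[edges$from == a]), 0)
  new("NetworkModel", nodes = nodes, edges = edges,
      outstrength = outs, minSupport = minSupport,
      minConfidence = minConfidence)
}

#' Lift matrix for heat-map display
#'
#' Square matrix of lift values, rows = IF (antecedent) item, columns =
#' THEN (consequent) item; diagonal is NA.
#'
#' @param rules rule table from [mineRules()].
#' @param nodes optional node order.
#' @return numeric matrix.
#' @export
liftMatrix <- function(rules, nodes = NULL) {
  if (is.null(nodes))
    nodes <- sort(unique(c(rules$antecedent, rules$consequent)))
  m <- matrix(NA_real_, length(nodes), length(nodes),
              dimnames = list(IF = nodes, THEN = nodes))
  idx <- cbind(match(rules$antecedent, nodes),
               match(rules$consequent, nodes))
  m[idx] <- rules$lift
  m
}
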