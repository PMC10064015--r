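# Shared fixtures, built in code.

# A TransactionSet from a plain list of character itemsets.
makeTx <- function(itemsets, alphabet = NULL) {
  if (is.null(alphabet))
    alphabet <- as.character(sort(unique(unlist(itemsets))))
  new("TransactionSet",
      items = lapply(itemsets, as.character),
      segmentIds = as.character(seq_along(itemsets)),
      alphabet = alphabet,
      filterThreshold = 0, minTerminals = 0L)
}

# Brute-force association oracle: direct double loop over transactions
# and ordered item pairs. Independent of the package's counting path.
bruteForceRules <- function(itemsets, alphabet) {
  N <- length(itemsets)
  rows <- list()
  for (a in alphabet) {
    nA <- sum(vapply(itemsets, function(s) a %in% s, TRUE))
    if (nA == 0) next
    for (b in setdiff(alphabet, a)) {
      nB <- sum(vapply(itemsets, function(s) b %in% s, TRUE))
      nAB <- sum(vapply(itemsets, function(s) a %in% s && b %in% s, TRUE))
      rows[[length(rows) + 1L]] <- data.frame(
        antecedent = a, consequent = b,
        support_a = nA / N, support_b = nB / N, support_ab = nAB / N,
        confidence = (nAB / N) / (nA / N),
        lift = if (nB > 0) (nAB / N) / ((nA / N) * (nB / N)) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Random transaction sets over a small alphabet.
randomItemsets <- function(nTx, alphabet, seed) {
  set.seed(seed)
  lapply(seq_len(nTx), function(i) {
    sz <- sample.int(length(alphabet), 1L)
    sort(sample(alphabet, sz))
  })
}

# A small bouton population + label stack pair for sampling tests.
makeStackFixture <- function(seed = 1L, nBoutons = 400L, density = 2,
                             dimsXY = 120L, nz = 12L,
                             voxel = c(125, 125, 500)) {
  specs <- defaultMixtures()
  nLM <- round(0.18 * nBoutons)
  pop <- rbind(
    generateBoutonPopulation(specs$LM, nLM, seed = seed),
    generateBoutonPopulation(specs$DNM, nBoutons - nLM, seed = seed + 1L))
  sspec <- StackSpec(dims = c(dimsXY, dimsXY, nz), voxelSize = voxel,
                     density = density, blobRadius = 1L, blobRadiusZ = 0L)
  stack <- generateStack(sspec, pop, seed = seed + 2L)
  list(population = pop, stack = stack, spec = sspec)
}
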