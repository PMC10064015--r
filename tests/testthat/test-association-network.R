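test_that("rule statistics match hand enumeration", {
  tx <- makeTx(list(c("A", "B"), c("A", "B"), "A", "B"))
  rules <- mineRules(tx)
  ab <- rules[rules$antecedent == "A" & rules$consequent == "B", ]
  expect_equal(ab$confidence, 2 / 3)
  expect_equal(ab$lift, 8 / 9)
  expect_equal(ab$support_a, 3 / 4)
  expect_equal(ab$support_ab, 1 / 2)
})

test_that("saturated and disjoint pairs give lift 1 and 0", {
  tx <- makeTx(list(c("A", "B"), c("A", "B"), c("A", "B")))
  rules <- mineRules(tx)
  expect_equal(rules$lift, c(1, 1))
  expect_equal(rules$confidence, c(1, 1))

  tx <- makeTx(list("A", "B", "A", "B"))
  rules <- mineRules(tx)
  expect_equal(rules$lift, c(0, 0))
})

test_that("mining agrees exactly with the brute-force oracle and lift
           is symmetric", {
  alphabet <- c("LM", "DM1", "DM2", "DM3", "DM4", "DM5")
  for (seed in 1:20) {
    sets <- randomItemsets(sample(c(5, 50, 200), 1), alphabet, seed)
    got <- mineRules(makeTx(sets, alphabet))
    want <- bruteForceRules(sets, alphabet)
    got <- got[order(got$antecedent, got$consequent), ]
    want <- want[order(want$antecedent, want$consequent), ]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
    # lift(A->B) == lift(B->A)
    key <- paste(pmin(got$antecedent, got$consequent),
                 pmax(got$antecedent, got$consequent))
    for (kk in unique(key)) {
      lifts <- got$lift[key == kk]
      if (anyNA(lifts)) next # undefined when one item never occurs
      expect_equal(diff(range(lifts)), 0)
    }
  }
})

test_that("empty transaction sets and unlabeled boutons are rejected", {
  expect_error(mineRules(makeTx(list())), "empty")
  b <- data.frame(subpop = c("LM1", NA), segment_id = c("s1", "s1"))
  expect_error(buildTransactions(b), "unlabeled")
})

test_that("transactions group retinal items and apply the
           rare-occurrence filter on large segments only", {
  # 3 LM + 2 DM1 terminals on one segment -> itemset {LM, DM1}
  b <- data.frame(subpop = c("LM1", "LM2", "LM3", "DM1", "DM1"),
                  segment_id = "s1")
  tx <- buildTransactions(b)
  expect_setequal(tx@items[[1]], c("LM", "DM1"))

  # 50 terminals, one DM5 (2% < 2.5%): DM5 dropped
  b <- data.frame(subpop = c(rep("DM1", 49), "DM5"), segment_id = "big")
  tx <- buildTransactions(b)
  expect_equal(tx@items[[1]], "DM1")

  # 5 terminals, one DM5: below min_terminals, DM5 retained
  b <- data.frame(subpop = c(rep("DM1", 4), "DM5"), segment_id = "small")
  tx <- buildTransactions(b)
  expect_setequal(tx@items[[1]], c("DM1", "DM5"))
})

test_that("network edges honour thresholds and outstrength sums
           retained confidences", {
  rules <- data.frame(
    antecedent = c("A", "A", "B", "C"),
    consequent = c("B", "C", "A", "A"),
    support_a = 0.5, support_b = 0.5,
    support_ab = c(0.3, 0.05, 0.3, 0.05),
    confidence = c(0.5, 0.3, 0.6, 0.1),
    lift = 1)
  net <- buildNetwork(rules, minSupport = 0.1)
  expect_equal(nrow(networkEdges(net)), 2L)
  expect_equal(unname(outstrength(net)[c("A", "B", "C")]),
               c(0.5, 0.6, 0))

  # all rules filtered out -> empty edges, zero outstrength
  net0 <- buildNetwork(rules, minSupport = 1)
  expect_equal(nrow(networkEdges(net0)), 0L)
  expect_true(all(outstrength(net0) == 0))
})

test_that("outstrength matches igraph's strength on retained edges", {
  skip_if_not_installed("igraph")
  alphabet <- c("LM", "DM1", "DM2", "DM3")
  sets <- randomItemsets(80, alphabet, seed = 13)
  net <- buildNetwork(mineRules(makeTx(sets, alphabet)),
                      minSupport = 0.05)
  e <- networkEdges(net)
  g <- igraph::graph_from_data_frame(
    e[, c("from", "to")], directed = TRUE,
    vertices = data.frame(name = net@nodes))
  s <- igraph::strength(g, mode = "out", weights = e$confidence)
  expect_equal(unname(s[net@nodes]), unname(outstrength(net)))
})

test_that("hard segregation removes the LM-DM1 association on X-like
           segments while independence leaves it at chance", {
  cfg1 <- SegmentGenConfig(nSegments = c(X_like = 150L), epsilon = 1)
  dat <- generateSegmentDataset(cfg1, seed = 21)
  both <- vapply(split(dat$boutons$gt_item, dat$boutons$segment_id),
                 function(it) all(c("LM", "DM1") %in% it), TRUE)
  expect_equal(sum(both), 0L)
  b <- dat$boutons
  b$subpop <- b$gt_item # ground-truth item types
  rules <- mineRules(buildTransactions(b))
  lm_dm1 <- rules$lift[rules$antecedent == "LM" &
                         rules$consequent == "DM1"]
  expect_equal(lm_dm1, 0)
  net <- buildNetwork(rules, minSupport = 0.1)
  e <- networkEdges(net)
  expect_false(any(e$from == "LM" & e$to == "DM1"))

  cfg0 <- SegmentGenConfig(nSegments = c(Y_like = 400L), epsilon = 0)
  dat0 <- generateSegmentDataset(cfg0, seed = 22)
  b0 <- dat0$boutons
  b0$subpop <- b0$gt_item
  rules0 <- mineRules(buildTransactions(b0))
  l0 <- rules0$lift[rules0$antecedent == "LM" &
                      rules0$consequent == "DM1"]
  expect_gt(l0, 0.8)
  expect_lt(l0, 1.2)
})

test_that("lift matrix is square with symmetric off-diagonal values", {
  sets <- randomItemsets(60, c("A", "B", "C"), seed = 5)
  m <- liftMatrix(mineRules(makeTx(sets, c("A", "B", "C"))))
  expect_equal(dim(m), c(3L, 3L))
  expect_true(all(is.na(diag(m))))
  expect_equal(m[upper.tri(m)], t(m)[upper.tri(m)])
})
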