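test_that("frozen default mixtures are valid and carry the documented
           structure", {
  specs <- defaultMixtures()
  expect_equal(nComponents(specs$LM), 4L)
  expect_equal(nComponents(specs$DNM), 5L)
  expect_equal(mixtureFamily(specs$LM), "LM")
  # DNM component-1 weight = 37 / (37+21+12+9+2)
  expect_equal(specs$DNM@weight[1], 37 / 81, tolerance = 1e-9)
  expect_equal(sum(specs$LM@weight), 1)
  expect_true(all(diff(specs$LM@mean) > 0))
  expect_true(all(diff(specs$DNM@mean) > 0))
})

test_that("degenerate-variance component produces near-constant
           volumes with its ground-truth label", {
  spec <- MixtureSpec(label = "only", weight = 1, mean = 1.0, sd = 1e-6,
                      family = "LM")
  pop <- generateBoutonPopulation(spec, 10, seed = 1)
  expect_equal(pop$volume, rep(1.0, 10), tolerance = 1e-4)
  expect_equal(pop$gt_component, rep("only", 10))
})

test_that("empty or invalid generation requests fail loudly", {
  spec <- defaultMixtures()$LM
  expect_error(generateBoutonPopulation(spec, 0, seed = 1), "n must be")
  bad <- spec
  bad@weight <- c(0.5, 0.5, 0.5, 0.5)
  expect_error(generateBoutonPopulation(bad, 10, seed = 1),
               "sum to 1")
  bad2 <- spec
  bad2@mean <- rev(bad2@mean)
  expect_error(generateBoutonPopulation(bad2, 10, seed = 1),
               "increasing")
})

test_that("component proportions converge to the spec weights", {
  spec <- defaultMixtures()$DNM
  pop <- generateBoutonPopulation(spec, 1e5, seed = 2)
  frac <- table(factor(pop$gt_component, levels = spec@label)) / 1e5
  expect_true(all(abs(as.numeric(frac) - spec@weight) < 0.01))
  # chi-squared goodness of fit against the weights: at alpha = 0.01
  # a correct generator still rejects occasionally, so require at
  # least 9 of 10 seeds to pass
  pass <- 0L
  for (s in 1:10) {
    p <- generateBoutonPopulation(spec, 1e5, seed = 100 + s)
    counts <- table(factor(p$gt_component, levels = spec@label))
    gof <- chisq.test(counts, p = spec@weight)
    pass <- pass + (gof$p.value > 0.01)
  }
  expect_gte(pass, 9L)
})

test_that("zero-truncation bias is bounded for every default
           component", {
  for (spec in defaultMixtures()) {
    pNeg <- pnorm(0, spec@mean, spec@sd)
    expect_true(all(pNeg < 0.01))
    # truncated mean shift relative to the spec mean stays below 2%
    a <- -spec@mean / spec@sd
    truncMean <- spec@mean + spec@sd * dnorm(a) / (1 - pnorm(a))
    expect_true(all(abs(truncMean - spec@mean) / spec@mean < 0.02))
  }
})

test_that("generation is deterministic under a fixed seed", {
  spec <- defaultMixtures()$LM
  expect_identical(generateBoutonPopulation(spec, 500, seed = 42),
                   generateBoutonPopulation(spec, 500, seed = 42))
  cfg <- SegmentGenConfig(nSegments = c(X_like = 20L, Y_like = 20L))
  expect_identical(generateSegmentDataset(cfg, seed = 42),
                   generateSegmentDataset(cfg, seed = 42))
})

test_that("segment generator honours class flags and segregation", {
  cfg <- SegmentGenConfig(
    nSegments = c(interneuron = 10L, X_like = 100L, Y_like = 20L),
    epsilon = 1)
  dat <- generateSegmentDataset(cfg, seed = 8)
  seg <- dat$segments
  expect_true(all(seg$has_presynaptic_zone[
    seg$cell_class == "interneuron"]))
  # X-like segments never carry both triad and PA flags
  expect_false(any(seg$has_triad_or_f2_input &
                     seg$has_dendrodendritic_pa))
  # hard exclusion: no X-like segment hosts both LM and DM1
  xb <- dat$boutons[dat$boutons$segment_id %in%
                      seg$segment_id[seg$cell_class == "X_like"], ]
  both <- vapply(split(xb$gt_item, xb$segment_id),
                 function(it) all(c("LM", "DM1") %in% it), TRUE)
  expect_equal(sum(both), 0L)
})

test_that("invalid segment configurations are rejected", {
  expect_error(SegmentGenConfig(epsilon = 1.5), "epsilon")
  comp <- rbind(X_like = c(0.5, 0.2, 0.1, 0.1, 0.05, 0.05) * 2)
  colnames(comp) <- c("LM", "DM1", "DM2", "DM3", "DM4", "DM5")
  expect_error(SegmentGenConfig(nSegments = c(X_like = 5L),
                                composition = comp), "sum to 1")
})

test_that("stacks place non-overlapping labelled blobs with linked
           centroids", {
  pop <- generateBoutonPopulation(defaultMixtures()$DNM, 100, seed = 1)
  spec <- StackSpec(dims = c(60, 60, 8), voxelSize = c(125, 125, 500),
                    density = 3, blobRadius = 1, blobRadiusZ = 0)
  stack <- generateStack(spec, pop, seed = 3)
  syn <- synapseTable(stack)
  labels <- stackLabels(stack)
  expect_gt(nrow(syn), 0L)
  # unique positive ids; centroid voxel carries its own id
  expect_equal(anyDuplicated(syn$synapse_id), 0L)
  for (i in seq_len(nrow(syn)))
    expect_equal(labels[syn$cx[i] + 1L, syn$cy[i] + 1L, syn$cz[i] + 1L],
                 syn$synapse_id[i])
  expect_true(all(syn$bouton_id %in% pop$id))
})

test_that("zero density yields an empty stack", {
  pop <- generateBoutonPopulation(defaultMixtures()$LM, 5, seed = 1)
  spec <- StackSpec(dims = c(20, 20, 4), voxelSize = c(125, 125, 500),
                    density = 0)
  stack <- generateStack(spec, pop, seed = 1)
  expect_equal(nrow(synapseTable(stack)), 0L)
  expect_true(all(stackLabels(stack) == 0L))
})

test_that("Poisson placement matches the expected synapse count", {
  pop <- generateBoutonPopulation(defaultMixtures()$DNM, 200, seed = 1)
  spec <- StackSpec(dims = c(80, 80, 10), voxelSize = c(125, 125, 500),
                    density = 2, blobRadius = 1, blobRadiusZ = 0)
  vol <- prod(spec@dims) * prod(spec@voxelSize) / 1e9
  lambda <- spec@density * vol
  for (s in 1:5) {
    stack <- generateStack(spec, pop, seed = 20 + s)
    expect_lt(abs(nrow(synapseTable(stack)) - lambda),
              4 * sqrt(lambda))
  }
})

test_that("impossible blob packing suggests lowering the density", {
  pop <- generateBoutonPopulation(defaultMixtures()$DNM, 50, seed = 1)
  spec <- StackSpec(dims = c(12, 12, 3), voxelSize = c(125, 125, 500),
                    density = 4000, blobRadius = 2, blobRadiusZ = 1)
  expect_error(generateStack(spec, pop, seed = 1), "lower the density")
})

test_that("label stacks round-trip through TIFF plus sidecar", {
  pop <- generateBoutonPopulation(defaultMixtures()$DNM, 50, seed = 4)
  spec <- StackSpec(dims = c(30, 30, 4), voxelSize = c(125, 125, 500),
                    density = 2, blobRadius = 1, blobRadiusZ = 0)
  stack <- generateStack(spec, pop, seed = 5)
  path <- file.path(withr::local_tempdir(), "stack.tif")
  writeLabelStack(stack, path)
  back <- readLabelStack(path)
  expect_identical(stackLabels(back), stackLabels(stack))
  expect_equal(back@voxelSize, stack@voxelSize)
  expect_equal(synapseTable(back)$synapse_id,
               synapseTable(stack)$synapse_id)
  expect_equal(synapseTable(back)$cx, synapseTable(stack)$cx)
})
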