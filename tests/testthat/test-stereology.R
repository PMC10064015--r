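test_that("the default grid geometry yields the designed location
           counts", {
  g <- GridSpec()
  expect_identical(totalLocations(g), 1350L)
  expect_identical(totalLocations(GridSpec(1, 2)), 4L)
  # reference sections 33 sections apart at 75 nm: 2.475 um
  expect_equal(diff(g@referenceSections)[1] * g@sectionThickness / 1000,
               2.475)
})

test_that("arrays are built over a stack or rejected with the required
           minimum size", {
  fx <- makeStackFixture(seed = 1, nBoutons = 50, density = 0.5,
                         dimsXY = 120, nz = 12)
  g <- GridSpec(gridsPerArray = 2, cellsPerSide = 6, frameSide = 2.5,
                gridZSpacing = 4)
  arr <- buildArray(g, fx$stack)
  expect_equal(nrow(arr$locations), 72L)
  expect_equal(arr$frameVox, 20L) # 2.5 um at 125 nm voxels
  expect_equal(unique(arr$locations$status), "not_examined")
  # adjacent frames share boundary lines
  loc <- arr$locations
  expect_equal(sort(unique(loc$x0)), (0:5) * 20L)
  big <- GridSpec(gridsPerArray = 2, cellsPerSide = 40,
                  frameSide = 2.5, gridZSpacing = 4)
  expect_error(buildArray(big, fx$stack), "need at least")
})

test_that("location selection is exact, uniform and reproducible", {
  fx <- makeStackFixture(seed = 2, nBoutons = 50, density = 0.2,
                         dimsXY = 120, nz = 12)
  g <- GridSpec(gridsPerArray = 2, cellsPerSide = 6, gridZSpacing = 4)
  arr <- buildArray(g, fx$stack)
  half <- selectLocations(arr, 0.5, seed = 4)
  expect_equal(sum(half$locations$selected), 36L)
  all_ <- selectLocations(arr, 1.0, seed = 4)
  expect_true(all(all_$locations$selected))
  again <- selectLocations(arr, 0.5, seed = 4)
  expect_identical(half$locations$selected, again$locations$selected)
  expect_error(selectLocations(arr, 0), "fraction")
  expect_error(selectLocations(arr, 1.2), "fraction")
})

test_that("the counting-frame rule includes, excludes and ignores
           footprints correctly", {
  frame <- list(x0 = 10, y0 = 10, w = 5)
  # entirely inside
  expect_equal(testInclusion(cbind(12, 12), frame), "included")
  # crossing the left (exclusion) edge
  expect_equal(testInclusion(cbind(c(9, 10, 11), c(12, 12, 12)), frame),
               "excluded")
  # crossing the bottom (exclusion) edge
  expect_equal(testInclusion(cbind(c(12, 12), c(9, 10)), frame),
               "excluded")
  # crossing only the top (inclusion) edge
  expect_equal(testInclusion(cbind(c(12, 12, 12), c(13, 14, 15)), frame),
               "included")
  # crossing only the right (inclusion) edge
  expect_equal(testInclusion(cbind(c(14, 15), c(12, 12)), frame),
               "included")
  # exclusion-line extension: crosses x = x0 outside the frame,
  # intersecting the frame via the top edge region
  expect_equal(testInclusion(cbind(c(9, 10, 11), c(14, 14, 14)), frame),
               "excluded")
  # fully outside
  expect_equal(testInclusion(cbind(2, 2), frame), "outside")
  expect_error(testInclusion(cbind(numeric(0), numeric(0)), frame),
               "empty")
})

test_that("a full tiling counts every blob exactly once", {
  # one reference section tiled completely by frames
  fx <- makeStackFixture(seed = 3, nBoutons = 200, density = 8,
                         dimsXY = 120, nz = 3)
  labels <- stackLabels(fx$stack)
  plane <- labels[, , 2] # 0-based z = 1
  ids <- setdiff(unique(as.vector(plane)), 0L)
  expect_gt(length(ids), 20L)
  w <- 20L
  counts <- setNames(integer(length(ids)), ids)
  for (cx in 0:5) for (cy in 0:5) {
    frame <- list(x0 = cx * w, y0 = cy * w, w = w)
    for (id in ids) {
      vox <- which(plane == id, arr.ind = TRUE) - 1L
      if (testInclusion(vox, frame) == "included")
        counts[as.character(id)] <- counts[as.character(id)] + 1L
    }
  }
  expect_true(all(counts == 1L))
})

test_that("a planted synapse inside a selected frame is sampled
           exactly once", {
  pop <- generateBoutonPopulation(defaultMixtures()$LM, 5, seed = 1)
  labels <- array(0L, dim = c(40, 40, 3))
  labels[12:13, 12:13, 2] <- 1L
  stack <- new("LabelStack", labels = labels,
               voxelSize = c(125, 125, 500),
               synapses = data.frame(synapse_id = 1L,
                                     bouton_id = pop$id[3],
                                     cx = 11L, cy = 11L, cz = 1L))
  g <- GridSpec(gridsPerArray = 1, cellsPerSide = 2, frameSide = 2.5,
                gridZSpacing = 1, referenceSections = 1L)
  res <- runUTS(stack, pop, g, fraction = 1.0, seed = 1)
  expect_equal(nrow(res$sample), 1L)
  expect_equal(res$sample$bouton_id, pop$id[3])
  expect_equal(res$sample$volume, pop$volume[3])
  expect_equal(sum(res$locations$status == "synapse_sampled"), 1L)
})

test_that("an empty stack yields zero samples and all-empty statuses", {
  pop <- generateBoutonPopulation(defaultMixtures()$LM, 5, seed = 1)
  stack <- new("LabelStack", labels = array(0L, dim = c(40, 40, 3)),
               voxelSize = c(125, 125, 500),
               synapses = data.frame(synapse_id = integer(),
                                     bouton_id = character(),
                                     cx = integer(), cy = integer(),
                                     cz = integer()))
  g <- GridSpec(gridsPerArray = 1, cellsPerSide = 2, frameSide = 2.5,
                gridZSpacing = 1, referenceSections = 1L)
  res <- runUTS(stack, pop, g, fraction = 1.0, seed = 1)
  expect_equal(nrow(res$sample), 0L)
  expect_true(all(res$locations$status == "empty"))
})

test_that("a missing bouton link is a data-integrity error", {
  pop <- generateBoutonPopulation(defaultMixtures()$LM, 5, seed = 1)
  labels <- array(0L, dim = c(40, 40, 3))
  labels[5, 5, 2] <- 1L
  stack <- new("LabelStack", labels = labels,
               voxelSize = c(125, 125, 500),
               synapses = data.frame(synapse_id = 1L,
                                     bouton_id = "nonexistent",
                                     cx = 4L, cy = 4L, cz = 1L))
  g <- GridSpec(gridsPerArray = 1, cellsPerSide = 2, frameSide = 2.5,
                gridZSpacing = 1, referenceSections = 1L)
  expect_error(runUTS(stack, pop, g, 1.0, 1), "data-integrity")
})

test_that("sampling is reproducible and unbiased for the bouton-volume
           distribution", {
  fx <- makeStackFixture(seed = 11, nBoutons = 400, density = 3,
                         dimsXY = 120, nz = 10)
  g <- GridSpec(gridsPerArray = 2, cellsPerSide = 6, gridZSpacing = 4)
  r1 <- runUTS(fx$stack, fx$population, g, 0.5, seed = 5)
  r2 <- runUTS(fx$stack, fx$population, g, 0.5, seed = 5)
  expect_identical(r1$sample, r2$sample)
  expect_gt(nrow(r1$sample), 30L)
  ks <- suppressWarnings(
    ks.test(r1$sample$volume, fx$population$volume))
  expect_gt(ks$p.value, 0.01)
})

test_that("two independent array placements sample indistinguishable
           volume distributions", {
  fx <- makeStackFixture(seed = 12, nBoutons = 400, density = 3,
                         dimsXY = 120, nz = 12)
  gA <- GridSpec(gridsPerArray = 2, cellsPerSide = 6, gridZSpacing = 4,
                 referenceSections = c(1L, 5L))
  gB <- GridSpec(gridsPerArray = 2, cellsPerSide = 6, gridZSpacing = 4,
                 referenceSections = c(3L, 7L))
  pass <- 0L
  for (s in 1:10) {
    a <- runUTS(fx$stack, fx$population, gA, 0.5, seed = s)
    b <- runUTS(fx$stack, fx$population, gB, 0.5, seed = s + 100L)
    p <- suppressWarnings(
      wilcox.test(a$sample$volume, b$sample$volume))$p.value
    pass <- pass + (p > 0.05)
  }
  expect_gte(pass, 9L)
})

test_that("locations inside a soma are tallied as soma and skipped", {
  fx <- makeStackFixture(seed = 13, nBoutons = 50, density = 0.5,
                         dimsXY = 120, nz = 12)
  mask <- array(FALSE, dim = dim(stackLabels(fx$stack)))
  mask[1:20, 1:20, ] <- TRUE # first frame fully inside a soma
  g <- GridSpec(gridsPerArray = 2, cellsPerSide = 6, gridZSpacing = 4)
  res <- runUTS(fx$stack, fx$population, g, 1.0, seed = 1,
                somaMask = mask)
  loc <- res$locations
  somaLoc <- loc$status[loc$row == 1 & loc$col == 1]
  expect_true(all(somaLoc == "soma"))
})
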