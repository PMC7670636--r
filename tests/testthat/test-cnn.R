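# Patch extraction, augmentation, classifier training, refinement.

test_that("patch extraction centres, pads and counts correctly", {
  dm <- c(96L, 96L, 96L)
  vals <- array(stats::rnorm(prod(dm)), dm)
  img <- imageVolume(vals, 0.7)
  # one component exactly at the grid centre: 0-based centroid (48, 48, 48)
  cs <- new("CandidateSet", coords = matrix(c(48L, 48L, 48L), 1, 3),
            component = 1L, region = "WM", dim = dm,
            spacing = rep(0.7, 3))
  b <- extractPatches(img, cs)
  expect_equal(dim(b$patches), c(24L^3, 1L))
  central <- vals[37:60, 37:60, 37:60]
  expect_equal(array(b$patches[, 1], rep(24L, 3)), central)
  # component at the corner voxel: patch half zero-padded
  cs0 <- new("CandidateSet", coords = matrix(0L, 1, 3), component = 1L,
             region = "WM", dim = dm, spacing = rep(0.7, 3))
  b0 <- extractPatches(img, cs0)
  p0 <- array(b0$patches[, 1], rep(24L, 3))
  expect_true(all(p0[1:12, , ] == 0))
  expect_equal(p0[13:24, 13:24, 13:24], vals[1:12, 1:12, 1:12])
  # k components -> batch of k
  csk <- new("CandidateSet",
             coords = rbind(c(10L, 10L, 10L), c(50L, 50L, 50L),
                            c(80L, 20L, 40L)),
             component = 1:3, region = c("WM", "WM", "BG"), dim = dm,
             spacing = rep(0.7, 3))
  expect_equal(ncol(extractPatches(img, csk)$patches), 3L)
})

test_that("augmentation: identity config, flip involution, seeded determinism", {
  set.seed(1)
  batch <- structure(list(patches = matrix(stats::rnorm(8^3 * 3), 8^3, 3),
                          component_id = 1:3, centers = matrix(0L, 3, 3),
                          side = 8L, labels = c(1L, 2L, 3L)),
                     class = "PatchBatch")
  ident <- augmentPatches(batch, seed = 2, flip_prob = 0, noise_sd = 0,
                          bias_range = 0, scale_range = 0)
  expect_equal(ident$patches, batch$patches)
  expect_equal(ident$labels, batch$labels)
  # flipping along every axis twice returns the original patch
  f1 <- augmentPatches(batch, seed = 3, flip_prob = 1, noise_sd = 0,
                       bias_range = 0, scale_range = 0)
  f2 <- augmentPatches(f1, seed = 99, flip_prob = 1, noise_sd = 0,
                       bias_range = 0, scale_range = 0)
  expect_equal(f2$patches, batch$patches)
  # same seed, same result
  a1 <- augmentPatches(batch, seed = 7)
  a2 <- augmentPatches(batch, seed = 7)
  expect_identical(a1$patches, a2$patches)
})

test_that("network shape trace: 24 -> 12 -> 6, flattened 6912 -> 128 -> 3", {
  spec <- networkSpec()
  m <- initNetwork(spec, seed = 1)
  expect_equal(dim(m$convs[[1]]$W), c(27L, 8L))
  expect_equal(dim(m$convs[[2]]$W), c(27L * 8L, 16L))
  expect_equal(dim(m$convs[[3]]$W), c(27L * 16L, 32L))
  expect_equal(dim(m$convs[[4]]$W), c(27L * 32L, 32L))
  expect_equal(dim(m$fc$W), c(6L^3 * 32L, 128L))
  expect_equal(dim(m$out$W), c(128L, 3L))
  bt <- pvstwin:::batchTables(m, 1L)
  fw <- pvstwin:::forwardBatch(m, matrix(stats::rnorm(24^3), ncol = 1), bt)
  expect_equal(dim(fw$logits), c(1L, 3L))
})

test_that("softmax probabilities sum to one per patch", {
  m <- initNetwork(networkSpec(input_side = 8L), seed = 2)
  batch <- structure(list(patches = matrix(stats::rnorm(8^3 * 5), 8^3, 5),
                          component_id = 1:5, centers = matrix(0L, 5, 3),
                          side = 8L, labels = NULL), class = "PatchBatch")
  pred <- predictClasses(m, batch)
  expect_equal(rowSums(pred$prob), rep(1, 5), tolerance = 1e-12)
})

test_that("balanced sampling trains all classes on imbalanced toy patches", {
  # linearly separable 8^3 toy classes with imbalanced counts
  set.seed(10)
  n_per <- c(40L, 8L, 6L)
  side <- 8L
  mk <- function(cls, n) {
    base <- array(0, c(side, side, side))
    if (cls == 1L) base[4:5, 4:5, ] <- 2       # tube along z
    if (cls == 2L) base[, , 1:2] <- 2          # slab
    if (cls == 3L) base[4:5, 4:5, 4:5] <- 3    # blob
    vapply(seq_len(n), function(i)
      as.vector(base + array(stats::rnorm(side^3, 0, 0.3),
                             c(side, side, side))),
      numeric(side^3))
  }
  patches <- cbind(mk(1L, n_per[1]), mk(2L, n_per[2]), mk(3L, n_per[3]))
  labels <- rep(1:3, n_per)
  batch <- structure(list(patches = patches, component_id = seq_along(labels),
                          centers = matrix(0L, length(labels), 3),
                          side = side, labels = labels),
                     class = "PatchBatch")
  model <- trainClassifier(batch, networkSpec(input_side = side),
                           epochs = 15L, seed = 3)
  # cross-entropy decreases over training
  expect_gt(mean(head(model$loss_history, 3)),
            mean(tail(model$loss_history, 3)))
  pred <- predictClasses(model, batch)
  # no class collapse: every class recalled on its own patches
  for (cl in 1:3)
    expect_gt(mean(pred$class[labels == cl] == cl), 0)
  expect_gt(mean(pred$class == labels), 0.9)
})

test_that("training errors when a class is absent, naming it", {
  batch <- structure(list(patches = matrix(stats::rnorm(8^3 * 4), 8^3, 4),
                          component_id = 1:4, centers = matrix(0L, 4, 3),
                          side = 8L, labels = c(1L, 1L, 2L, 2L)),
                     class = "PatchBatch")
  expect_error(trainClassifier(batch, networkSpec(input_side = 8L)),
               "class 3")
})

test_that("refinement keeps class-1 components, removes others, never adds voxels", {
  dm <- c(20L, 20L, 20L)
  img <- imageVolume(array(stats::rnorm(prod(dm)), dm), 0.7)
  cs <- new("CandidateSet",
            coords = rbind(c(5L, 5L, 5L), c(6L, 5L, 5L), c(14L, 14L, 14L)),
            component = c(1L, 1L, 2L), region = c("WM", "BG"), dim = dm,
            spacing = rep(0.7, 3))
  keep_all <- refineCandidates(cs, constantClassifier(1L), img)
  expect_equal(keep_all@coords, cs@coords)
  expect_equal(keep_all@region, cs@region)
  drop_all <- refineCandidates(cs, constantClassifier(2L), img)
  expect_equal(nVoxels(drop_all), 0L)
  # subset invariant under any model
  m <- initNetwork(networkSpec(input_side = 8L), seed = 4)
  ref <- refineCandidates(cs, m, img)
  have <- paste(ref@coords[, 1], ref@coords[, 2], ref@coords[, 3])
  all_ <- paste(cs@coords[, 1], cs@coords[, 2], cs@coords[, 3])
  expect_true(all(have %in% all_))
})

test_that("classifier serialization embeds the spec and validates patch size", {
  m <- constantClassifier(1L)
  tmp <- tempfile(fileext = ".rds")
  saveClassifier(m, tmp)
  m2 <- loadClassifier(tmp)
  expect_equal(m2$spec$input_side, 8L)
  batch24 <- structure(list(patches = matrix(0, 24^3, 1), component_id = 1L,
                            centers = matrix(0L, 1, 3), side = 24L,
                            labels = NULL), class = "PatchBatch")
  expect_error(predictClasses(m2, batch24), "side")
  unlink(tmp)
})

test_that("phantom-trained classifier separates dPVS from CSF confounders", {
  # pooled training patches from three phantoms, evaluated on a fourth
  batches <- list(); truths <- list()
  for (i in 1:3) {
    tr <- generatePhantom(phantomSpec(grid_shape = 64L, n_tubes_wm = 5L,
                                      n_tubes_bg = 2L, seed = i))
    lm <- looseRegionMasks(tr)
    seg <- segmentPVS(tr$image, lm$wm, lm$bg, lm$brain)
    b <- extractPatches(seg$normalized, seg$candidates)
    b$labels <- makeTrainingLabels(seg$candidates, tr)
    batches[[i]] <- b
  }
  train <- mergePatchBatches(batches)
  expect_setequal(unique(train$labels), 1:3)
  model <- trainClassifier(train, epochs = 15L, seed = 5)
  pred <- predictClasses(model, train)
  expect_gt(mean(pred$class == train$labels), 0.9)

  tr <- generatePhantom(phantomSpec(grid_shape = 64L, n_tubes_wm = 5L,
                                    n_tubes_bg = 2L, seed = 99))
  lm <- looseRegionMasks(tr)
  seg <- segmentPVS(tr$image, lm$wm, lm$bg, lm$brain)
  fin <- refineCandidates(seg$candidates, model, seg$normalized)
  fr0 <- validityFractions(seg$candidates, tr$labels)
  fr1 <- validityFractions(fin, tr$labels)
  # refinement lowers the false-positive volume fraction and keeps
  # most true dPVS volume
  expect_lt(fr1["fp_fraction"], fr0["fp_fraction"])
  expect_lt(fr1["fn_fraction"], 0.5)
})
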