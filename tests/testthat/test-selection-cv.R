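test_that("method selection ties resolve by the fixed priority order", {
  # all four methods separate this data perfectly, so PLS (the cheapest)
  # must win by priority
  tg <- twoGaussians(n = 20, d = 10, sep = 8, seed = 1)
  sel <- selectNodeMethod(tg$X, tg$y, cvConfig(seed = 4))
  expect_equal(sel$method, "PLS")
  expect_equal(sel$meanAccuracy, 1)
  expect_equal(rownames(sel$table), c("PLS", "MMC-LDA", "PCA-LDA", "SVM"))
})

test_that("inner folds shrink to the smallest class size", {
  set.seed(2)
  X <- rbind(matrix(rnorm(30), 10, 3), matrix(rnorm(9, 5), 3, 3))
  y <- c(rep("big", 10), rep("small", 3))
  sel <- selectNodeMethod(X, y, cvConfig(kInner = 5, seed = 1))
  expect_equal(ncol(sel$table), 3L)  # effective folds = 3
  expect_error(selectNodeMethod(X[1:11, ], y[1:11], cvConfig(seed = 1)),
               "fewer than 2")
})

test_that("the method map has one entry per populated internal node", {
  # depth-2 tree with 3 + 4 leaves: 1 root + 2 internal = 3 entries
  lin <- c(paste0("A;a", 1:3), paste0("B;b", 1:4))
  set.seed(3)
  X <- do.call(rbind, lapply(1:7, function(i) {
    sweep(matrix(rnorm(12 * 15), 12, 15), 2, rnorm(15, 0, 4), "+")
  }))
  labels <- rep(lin, each = 12)
  tree <- buildTree(lin)
  cfg <- cvConfig(seed = 11)
  mm <- deriveMethodMap(tree, X, labels, cfg)
  expect_equal(nrow(mm@map), 3L)
  expect_setequal(mm@map$node, c("<root>", "A", "B"))
  expect_false(any(mm@map$singleOffspring))

  # determinism: identical inputs and seed give identical maps
  mm2 <- deriveMethodMap(tree, X, labels, cfg)
  expect_identical(mm@map, mm2@map)
  expect_identical(mm@tables, mm2@tables)
})

test_that("method selection is per node, not global", {
  # node A's children overlap heavily; node B's are well separated;
  # selection must run independently at each node
  lin <- c("A;a1", "A;a2", "B;b1", "B;b2")
  set.seed(4)
  XA <- matrix(rnorm(40 * 10), 40, 10)                      # a1/a2 overlap
  XB <- rbind(matrix(rnorm(20 * 10), 20, 10),
              matrix(rnorm(20 * 10, 4), 20, 10))            # b1/b2 split
  X <- rbind(XA, sweep(XB, 2, rep(30, 10), "+"))             # A vs B split
  labels <- rep(lin, each = 20)
  mm <- deriveMethodMap(buildTree(lin), X, labels, cvConfig(seed = 5))
  accA <- mm@map$meanAccuracy[mm@map$node == "A"]
  accB <- mm@map$meanAccuracy[mm@map$node == "B"]
  expect_lt(accA, 0.8)
  expect_equal(accB, 1)
})

test_that("cross-validation recovers a separated hierarchy exactly", {
  g <- genHierarchicalGaussians(c(2, 2), samplesPerLeaf = 15, nFeatures = 20,
                                separation = 6, seed = 21)
  cfg <- cvConfig(reps = 2, seed = 22)
  rep <- crossValidate(g$tree, g$X, g$labels, cfg)
  expect_true(all(rep@accuracy == 100))
  s <- accuracySummary(rep)
  expect_equal(s$meanAccuracy, c(100, 100))
  # confusion row sums equal per-class test counts over all reps
  expect_true(all(rowSums(rep@confusion[[2]]) == 15 * cfg@reps))
  expect_true(all(rowSums(rep@confusion[[1]]) == 30 * cfg@reps))
})

test_that("per-level accuracy never increases with depth", {
  g <- genHierarchicalGaussians(c(2, 3), samplesPerLeaf = 10, nFeatures = 10,
                                separation = c(4, 1), seed = 31)
  rep <- crossValidate(g$tree, g$X, g$labels, cvConfig(reps = 2, seed = 32))
  for (r in seq_len(nrow(rep@accuracy))) {
    expect_true(all(diff(rep@accuracy[r, ]) <= 1e-9))
  }
})

test_that("identical seeds reproduce the confusion report bitwise", {
  g <- genHierarchicalGaussians(c(2, 2), samplesPerLeaf = 10, nFeatures = 10,
                                separation = 5, seed = 41)
  cfg <- cvConfig(reps = 2, seed = 42)
  r1 <- crossValidate(g$tree, g$X, g$labels, cfg)
  r2 <- crossValidate(g$tree, g$X, g$labels, cfg)
  expect_identical(r1@accuracy, r2@accuracy)
  expect_identical(r1@confusion, r2@confusion)
  expect_identical(r1@nodeAccuracy, r2@nodeAccuracy)
})

test_that("outer test samples never leak into training", {
  g <- genHierarchicalGaussians(c(2, 2), samplesPerLeaf = 12, nFeatures = 8,
                                separation = 5, seed = 51)
  ids <- g$labels
  folds <- rep(rep(1:3, length.out = 12), 4)  # deterministic split by leaf
  tr <- folds != 1
  cfg <- cvConfig(seed = 52)
  mm1 <- deriveMethodMap(g$tree, g$X[tr, ], g$labels[tr], cfg)
  m1 <- trainHCModel(g$tree, g$X[tr, ], g$labels[tr], mm1, cfg)
  # corrupt the held-out rows; map and model must be unchanged
  Xc <- g$X
  Xc[!tr, ] <- 1e6
  mm2 <- deriveMethodMap(g$tree, Xc[tr, ], g$labels[tr], cfg)
  m2 <- trainHCModel(g$tree, Xc[tr, ], g$labels[tr], mm2, cfg)
  expect_identical(mm1@map, mm2@map)
  expect_identical(lapply(m1@nodeModels, function(n) n@reducer@W),
                   lapply(m2@nodeModels, function(n) n@reducer@W))
})

test_that("confusion reports export cleanly", {
  g <- genHierarchicalGaussians(c(2, 2), samplesPerLeaf = 8, nFeatures = 6,
                                separation = 5, seed = 61)
  rep <- crossValidate(g$tree, g$X, g$labels, cvConfig(reps = 1, seed = 62))
  dir <- tempfile()
  writeConfusionReport(rep, dir)
  expect_true(file.exists(file.path(dir, "confusion_level1.csv")))
  expect_true(file.exists(file.path(dir, "confusion_level2.csv")))
  js <- jsonlite::read_json(file.path(dir, "accuracy_summary.json"))
  expect_length(js, 2L)
  expect_equal(js[[1]]$level, 1L)
})
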