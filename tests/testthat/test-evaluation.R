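test_that("per-class scores reproduce the closed-form confusion numbers", {
  # one class with TP=3, FP=1, FN=1: Re = Pr = 0.75, IoU = 0.6
  gt <- c(rep("a", 4), rep("b", 4))
  pred <- c("a", "a", "a", "b", "a", "b", "b", "b")
  sc <- semantic_scores(pred, gt)
  a <- sc$per_class[sc$per_class$class == "a", ]
  expect_equal(a$recall, 0.75)
  expect_equal(a$precision, 0.75)
  expect_equal(a$iou, 0.6)

  # TP=8, FP=2, FN=2 gives F1 = 0.8
  gt2 <- c(rep("x", 10), rep("y", 4))
  pr2 <- c(rep("x", 8), "y", "y", "x", "x", "y", "y")
  x <- semantic_scores(pr2, gt2)$per_class
  expect_equal(x$f1[x$class == "x"], 0.8)

  # perfect prediction scores 1 everywhere
  sc1 <- semantic_scores(gt, gt)
  expect_true(all(unlist(sc1$per_class[c("recall", "precision", "iou", "f1")]) == 1))
  expect_equal(sc1$macro_f1, 1)

  expect_error(semantic_scores(c("a"), c("a", "b")), "length")
})

test_that("class maps merge labels before scoring and relabelling is neutral", {
  gt <- c("apex", "leaf_blade", "branch", "main_stem", "petiole")
  pred <- c("leaf_blade", "leaf_blade", "main_stem", "main_stem", "branch")
  map <- c(apex = "leaf", leaf_blade = "leaf", branch = "stem",
           main_stem = "stem", petiole = "stem")
  sc <- semantic_scores(pred, gt, class_map = map)
  expect_setequal(sc$per_class$class, c("leaf", "stem"))
  expect_equal(sc$per_class$recall[sc$per_class$class == "leaf"], 1)

  # consistent relabelling of both vectors leaves every score unchanged
  ren <- c(a = "z", b = "y", c = "x")
  gt3 <- sample(letters[1:3], 50, TRUE)
  pr3 <- sample(letters[1:3], 50, TRUE)
  s1 <- semantic_scores(pr3, gt3)
  s2 <- semantic_scores(unname(ren[pr3]), unname(ren[gt3]))
  expect_equal(sort(s1$per_class$f1), sort(s2$per_class$f1))
  expect_equal(s1$macro_f1, s2$macro_f1)
})

test_that("Rand and adjusted Rand match pair enumeration on all small partitions", {
  worst <- max_dev_vs_pair_oracle(5L)  # every partition pair of 1..5 points
  expect_lt(worst, 1e-12)
})

test_that("instance indices agree with an independent ARI implementation", {
  skip_if_not_installed("mclust")
  set.seed(42)
  for (r in 1:5) {
    x <- sample(1:6, 200, TRUE)
    y <- sample(1:4, 200, TRUE)
    expect_equal(instance_scores(x, y)$adjusted_rand,
                 mclust::adjustedRandIndex(x, y), tolerance = 1e-10)
  }
})

test_that("degenerate and perfect partitions hit the known bounds", {
  x <- rep(1L, 10); y <- rep(c(1L, 2L), 5)
  sc <- instance_scores(x, y)
  expect_equal(sc$completeness, 1)
  expect_equal(sc$homogeneity, 0)

  idm <- instance_scores(y, y)
  expect_equal(unlist(idm), c(rand = 1, adjusted_rand = 1,
                              adjusted_mutual_information = 1,
                              completeness = 1, homogeneity = 1))
  expect_error(instance_scores(1:3, 1:4), "length")
})

test_that("chance-level labellings average near zero adjusted Rand", {
  set.seed(9)
  vals <- replicate(1000, {
    x <- sample(rep(1:4, each = 10))
    y <- sample(rep(1:4, each = 10))
    instance_scores(x, y)$adjusted_rand
  })
  expect_lt(abs(mean(vals)), 0.02)
  # bounded indices
  x <- sample(1:5, 60, TRUE); y <- sample(1:3, 60, TRUE)
  sc <- instance_scores(x, y)
  expect_true(sc$rand >= 0 && sc$rand <= 1)
  expect_true(sc$completeness >= 0 && sc$completeness <= 1)
  expect_true(sc$homogeneity >= 0 && sc$homogeneity <= 1)
})
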