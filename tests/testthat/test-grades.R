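test_that("best-k scoring matches the tariff and a brute-force subset oracle", {
  al <- default_tariff("A-level")
  expect_equal(score_best_k(c("A", "A", "A"), al)$points, 30)
  expect_equal(score_best_k(c("C", "C", "C"), al)$points, 18)
  # brute force: maximum over all 3-subsets
  grades <- c("A", "B", "C", "D")
  combos <- combn(grades, 3)
  oracle <- max(apply(combos, 2, function(g) sum(al$mapping[g])))
  expect_equal(score_best_k(grades, al)$points, oracle)
  expect_equal(oracle, 24)
  # permutation invariance and monotonicity under added grades
  set.seed(5)
  for (i in 1:20) {
    g <- sample(names(al$mapping), sample(2:6, 1), replace = TRUE)
    expect_equal(score_best_k(sample(g), al)$points,
                 score_best_k(g, al)$points)
    expect_gte(score_best_k(c(g, sample(names(al$mapping), 1)), al)$points,
               score_best_k(g, al)$points)
  }
})

test_that("short profiles are flagged, unknown letters rejected by name", {
  al <- default_tariff("A-level")
  s <- score_best_k(c("A", "B"), al)
  expect_equal(s$points, 18)
  expect_equal(s$n_graded, 2)
  expect_true(s$short)
  expect_error(score_best_k(c("A", "Q"), al), "Q")
})

test_that("tariff constructor enforces its invariants; defaults are self-consistent", {
  expect_error(tariff("x", c(A = 10, B = 10), 1), "strictly decreasing")
  expect_error(tariff("x", c(A = 10, B = -1), 1), "positive")
  expect_error(tariff("x", c(A = 10, B = 8), 0), "k must be")
  # the A* extension scores A*A*A* = 36 and leaves AAA = 30
  ast <- default_tariff("A-level-Astar")
  expect_equal(score_best_k(rep("A*", 3), ast)$points, 36)
  expect_equal(score_best_k(rep("A", 3), ast)$points, 30)
})

test_that("tariffs round-trip through JSON config", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(qualification = "A-level-Astar",
                            mapping = list("A*" = 12, A = 10, B = 8,
                                           C = 6, D = 4, E = 2),
                            k = 3), path, auto_unbox = TRUE)
  trf <- read_tariff(path)
  expect_equal(score_best_k(c("A*", "A", "B"), trf)$points, 30)
})

test_that("group z-scoring centers and scales within groups (sample SD)", {
  expect_equal(zscore_by_group(c(10, 20), c("g1", "g1")),
               c(-1, 1) / sqrt(2), tolerance = 1e-12)
  set.seed(2)
  v <- rnorm(1000, 5, 2)
  z <- zscore_by_group(v, rep("a", 1000))
  expect_equal(mean(z), 0, tolerance = 1e-10)
  expect_equal(sd(z), 1, tolerance = 1e-10)
  # two groups with different means each get mean-zero z
  v2 <- c(rnorm(50, 0), rnorm(50, 100))
  g2 <- rep(c("lo", "hi"), each = 50)
  z2 <- zscore_by_group(v2, g2)
  expect_equal(as.numeric(tapply(z2, g2, mean)), c(0, 0), tolerance = 1e-10)
  expect_error(zscore_by_group(c(1, 1, 2), c("a", "a", "b")), "a")
  expect_error(zscore_by_group(1, "solo"), "solo")
})

test_that("composite of a complete table equals the first principal component", {
  set.seed(11)
  x <- matrix(rnorm(300), 100, 3) %*% matrix(c(1, .5, .3, 0, 1, .4, 0, 0, 1), 3)
  comp <- composite_attainment(x)
  ev <- eigen(cor(scale(x)), symmetric = TRUE)   # independent eigen route
  ref <- drop(scale(scale(x) %*% ev$vectors[, 1]))
  expect_equal(abs(cor(comp, ref)), 1, tolerance = 1e-10)
  # single complete column: the standardized column itself
  x1 <- matrix(rnorm(40), ncol = 1)
  expect_equal(composite_attainment(x1), drop(scale(x1)),
               tolerance = 1e-10, ignore_attr = TRUE)
  # rank-1 table: composite reproduces the common factor exactly
  v <- rnorm(60)
  r1 <- composite_attainment(cbind(v, 2 * v, 3 * v))
  expect_equal(abs(cor(r1, v)), 1, tolerance = 1e-10)
})

test_that("EM-imputed composite recovers a simulated common factor", {
  set.seed(21)
  n <- 2000; p <- 6
  f <- rnorm(n)
  x <- sapply(seq_len(p), function(j) 0.8 * f + 0.6 * rnorm(n))
  x[sample(length(x), round(0.1 * length(x)))] <- NA
  comp <- composite_attainment(x)
  expect_gte(abs(cor(comp, f)), 0.90)
  expect_error(composite_attainment(x, max_iter = 1L), "1 iterations")
})

test_that("columns with too much missing data are rejected", {
  x <- cbind(a = rnorm(20), b = c(rep(NA, 11), rnorm(9)))
  expect_error(composite_attainment(x), "50%")
})
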