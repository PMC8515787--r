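test_that("node entropy and the leaf formulas match direct evaluation", {
  expect_equal(node_entropy(5, 5), 1.0)
  expect_equal(node_entropy(7, 0), 0)
  expect_equal(node_entropy(3, 5), -(3 / 8 * log2(3 / 8) + 5 / 8 * log2(5 / 8)))

  # main-path score and leaf probability over an enumerated grid of counts
  for (nr in 0:12) {
    for (nu in 0:12) {
      if (nr + nu == 0) next
      expect_equal(main_path_score(nr, nu), nr * nr / (nr + nu))
      node <- reactree:::.tree_node(NULL, NULL, nu, nr)
      expect_equal(leaf_reactive_probability(node), nr / (nr + nu))
    }
  }
  expect_equal(main_path_score(10, 0), 10)
  expect_equal(main_path_score(0, 9), 0)
  expect_error(leaf_reactive_probability(reactree:::.tree_node(NULL, NULL, 0, 0)),
               "no samples")
})

test_that("a perfectly separating feature is chosen as the root split", {
  set.seed(101)
  for (rep in 1:5) {
    n <- 60
    x <- matrix(rnorm(n * 8), n)
    y <- rep(0:1, each = n / 2)
    j <- sample(8, 1)
    x[, j] <- ifelse(y == 1, runif(n, 0, 1), runif(n, 2, 3))
    data <- make_dataset(x, y, sprintf("O%d-H0'", 0:7))
    tree <- fit_tree(data)
    expect_identical(tree$feature, sprintf("O%d-H0'", j - 1))
    expect_gt(tree$threshold, max(x[y == 1, j]))
    expect_lt(tree$threshold, min(x[y == 0, j]))
    # left child is the 'feature < threshold' branch
    expect_identical(tree$left$n_reactive, sum(y == 1L))
    expect_identical(tree$left$n_unreactive, 0L)
  }
})

test_that("the root split matches exhaustive entropy-gain enumeration", {
  set.seed(103)
  for (rep in 1:5) {
    n <- 40
    x <- matrix(rnorm(n * 5), n)
    y <- as.integer(x[, 2] + 0.5 * rnorm(n) > 0)
    if (length(unique(y)) < 2) next
    data <- make_dataset(x, y, sprintf("O%d-H0'", 0:4))
    tree <- fit_tree(data, max_depth = 1L)
    oracle <- brute_best_split(x, y)
    expect_identical(match(tree$feature, data$feature_labels), oracle$feature)
    expect_equal(tree$threshold, oracle$threshold, tolerance = 1e-8)
  }
})

test_that("child class counts sum to the parent's throughout the tree", {
  set.seed(107)
  x <- matrix(rnorm(80 * 6), 80)
  y <- as.integer(x[, 1] + x[, 3] + rnorm(80) > 0)
  tree <- fit_tree(make_dataset(x, y, sprintf("O%d-H0'", 0:5)))
  check <- function(node) {
    if (is.null(node$left)) return(invisible())
    expect_identical(node$n_unreactive,
                     node$left$n_unreactive + node$right$n_unreactive)
    expect_identical(node$n_reactive,
                     node$left$n_reactive + node$right$n_reactive)
    check(node$left); check(node$right)
  }
  check(tree)
  expect_identical(tree$n_unreactive + tree$n_reactive, 80L)
})

test_that("single-class input degenerates to one leaf with a warning", {
  x <- matrix(rnorm(20), 10)
  data <- make_dataset(x, rep(1L, 10), c("O0-H0'", "O1-H0'"))
  expect_warning(tree <- fit_tree(data), "single-class")
  expect_null(tree$left)
  expect_identical(tree$n_reactive, 10L)
  expect_equal(leaf_reactive_probability(tree), 1.0)
})

test_that("the main decision path maximizes the reactive-weighted score", {
  tn <- reactree:::.tree_node
  # leaves scoring 10*10/10 = 10 versus 12*12/24 = 6: the pure one wins
  root <- tn("O0-H0'", 1.0, 22, 22,
             left = tn(NULL, NULL, 0, 10, depth = 1L),
             right = tn(NULL, NULL, 22, 12, depth = 1L))
  dp <- main_decision_path(root)
  expect_equal(dp$leaf$score, 10)
  expect_identical(dp$leaf$n_reactive, 10)
  expect_identical(dp$steps[[1]]$direction, "<")
  expect_equal(dp$leaf$reactive_probability, 1.0)

  # scores invariant to leaf enumeration order: mirror the tree
  mirror <- tn("O0-H0'", 1.0, 22, 22,
               left = tn(NULL, NULL, 22, 12, depth = 1L),
               right = tn(NULL, NULL, 0, 10, depth = 1L))
  dm <- main_decision_path(mirror)
  expect_equal(dm$leaf$score, 10)
  expect_identical(dm$steps[[1]]$direction, ">=")

  # end to end: on planted data the main path isolates the reactive leaf
  recs <- generate_paths(fixture_spec(n_paths = 60L, seed = 15L))
  cfg <- cluster_colvar_config(4)
  data <- build_dataset(window_select(recs, cfg, selection_window(seed = 2L)))
  dp <- main_decision_path(fit_tree(data))
  expect_identical(dp$steps[[1]]$feature, "C0-O5'")
  expect_gte(dp$leaf$reactive_probability, 0.9)
})

test_that("stump-forest importances are normalized and find a planted feature", {
  set.seed(109)
  n <- 80
  x <- matrix(rnorm(n * 12), n)
  y <- rep(0:1, n / 2)
  x[, 5] <- ifelse(y == 1, rnorm(n, -1, 0.3), rnorm(n, 1, 0.3))
  data <- make_dataset(x, y, sprintf("O%d-H0'", 0:11))
  hits <- 0L
  for (sd in 1:20) {
    imp <- rf_first_split_importance(data, n_trees = 150L, seed = sd)
    expect_equal(sum(imp), 1.0)
    expect_true(all(imp >= 0))
    if (which.max(imp) == 5L) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("pure-noise features get spread-out importance", {
  set.seed(113)
  x <- matrix(rnorm(100 * 20), 100)
  y <- rep(0:1, 50)
  data <- make_dataset(x, y, sprintf("O%d-H0'", 0:19))
  imp <- rf_first_split_importance(data, n_trees = 400L, seed = 7L)
  expect_true(all(imp < 5 / 20))
})

test_that("the stump forest agrees with an independent forest implementation", {
  set.seed(127)
  n <- 100
  x <- matrix(rnorm(n * 10), n)
  y <- rep(0:1, n / 2)
  x[, 3] <- ifelse(y == 1, rnorm(n, -1, 0.4), rnorm(n, 1, 0.4))
  data <- make_dataset(x, y, sprintf("O%d-H0'", 0:9))
  imp <- rf_first_split_importance(data, n_trees = 500L, seed = 5L)
  rf <- randomForest::randomForest(x, factor(y), maxnodes = 2, ntree = 500)
  expect_identical(unname(which.max(imp)),
                   unname(which.max(rf$importance[, 1])))
})

test_that("blocks partition rows near-equally in generation order", {
  b <- reactree:::.block_bounds(25L, 10L)
  expect_identical(b$sizes, c(3L, 3L, 3L, 3L, 3L, 2L, 2L, 2L, 2L, 2L))
  expect_identical(b$stops[10], 25L)
  b2 <- reactree:::.block_bounds(40L, 10L)
  expect_true(all(b2$sizes == 4L))
})

test_that("identical blocks produce zero sigma for every feature", {
  set.seed(131)
  block <- matrix(rnorm(10 * 6), 10)
  yblk <- rep(0:1, 5)
  x <- block[rep(1:10, times = 10), ]
  y <- rep(yblk, times = 10)
  data <- make_dataset(x, y, sprintf("O%d-H0'", 0:5))
  est <- blocked_importance(data, n_blocks = 10L, n_trees = 60L, seed = 3L)
  expect_true(all(est$sigma == 0))
  est <- prob_most_important(est, seed = 4L)
  expect_equal(sum(est$p_most_important), 1.0)
  expect_identical(unname(which.max(est$p_most_important)),
                   unname(which.max(est$mean)))
})

test_that("too few rows for the requested blocks is an error", {
  x <- matrix(rnorm(12), 6)
  data <- make_dataset(x, rep(0:1, 3), c("O0-H0'", "O1-H0'"))
  expect_error(blocked_importance(data, n_blocks = 10L), "fewer")
})

test_that("argmax probabilities follow the closed-form Gaussian comparison", {
  mk_est <- function(mu, sg) structure(
    list(labels = sprintf("O%d-H0'", seq_along(mu) - 1L), mean = mu,
         sigma = sg, block_importances = NULL, p_most_important = NULL),
    class = "importance_estimate")

  est <- prob_most_important(mk_est(0.7, 0.1), seed = 1L)
  expect_equal(unname(est$p_most_important), 1.0)

  est <- prob_most_important(mk_est(c(0.5, 0.5), c(0.05, 0.05)),
                             n_mc = 1e5L, seed = 2L)
  expect_equal(unname(est$p_most_important[1]), 0.5, tolerance = 0.04)

  est <- prob_most_important(mk_est(c(0.6, 0.4), c(0.05, 0.05)),
                             n_mc = 1e5L, seed = 3L)
  expect_equal(unname(est$p_most_important[1]),
               pnorm(0.2 / (0.05 * sqrt(2))), tolerance = 0.002)

  # degenerate: all sigmas zero, tied maxima split uniformly
  est <- prob_most_important(mk_est(c(0.4, 0.4, 0.2), c(0, 0, 0)), seed = 4L)
  expect_equal(unname(est$p_most_important), c(0.5, 0.5, 0))
})

test_that("DOT rendering reports inequalities, counts and classes", {
  tn <- reactree:::.tree_node
  f <- withr::local_tempfile(fileext = ".dot")
  render_tree(tn(NULL, NULL, 3, 9), f)
  txt <- readLines(f)
  expect_length(grep("label=", txt), 1L)
  expect_length(grep("->", txt), 0L)

  recs <- generate_paths(fixture_spec(n_paths = 40L, seed = 18L))
  cfg <- cluster_colvar_config(4)
  data <- build_dataset(window_select(recs, cfg, selection_window(seed = 2L)))
  tree <- fit_tree(data)
  render_tree(tree, f, header_comment = "hash=abc")
  txt <- readLines(f)
  expect_lte(length(grep("label=.*<=", txt)), 15L)
  expect_true(any(grepl("C0-O5' <= ", txt, fixed = TRUE)))
  expect_true(any(grepl("class = reactive", txt)))
  expect_identical(txt[1], "// hash=abc")
})
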