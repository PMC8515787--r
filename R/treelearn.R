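#' Shannon entropy of a two-class node (bits)
#'
#' @param n_unreactive,n_reactive class counts entering the node.
#' @return Entropy in bits; 0 for a pure or empty node.
#' @export
node_entropy <- function(n_unreactive, n_reactive) {
  n <- n_unreactive + n_reactive
  if (n == 0) return(0)
  p <- c(n_unreactive, n_reactive) / n
  p <- p[p > 0]
  -sum(p * log2(p))
}

.tree_node <- function(feature, threshold, n_unreactive, n_reactive,
                       left = NULL, right = NULL, depth = 0L) {
  structure(list(feature = feature, threshold = threshold,
                 n_unreactive = n_unreactive, n_reactive = n_reactive,
                 left = left, right = right, depth = depth),
            class = "tree_node")
}

is_leaf <- function(node) is.null(node$left) && is.null(node$right)

#' Fit the entropy decision tree
#'
#' Trains a binary classification tree on the flattened invariant features
#' using the information-gain (Shannon entropy) criterion with a maximum
#' depth of three by default, and exports it into a plain recursive node
#' structure. Each node records the split feature (as a rendered feature
#' label), the threshold (the midpoint between the adjacent sorted values, as
#' produced by the split search), and the (unreactive, reactive) counts of
#' samples entering it. The left child always holds the samples satisfying
#' `feature < threshold`. The fit is exact and deterministic; `rpart` does
#' the split search with pruning disabled (`cp = 0`, `minsplit = 2`,
#' `minbucket = 1`).
#'
#' A single-class input cannot be split and yields a degenerate single-leaf
#' tree with a warning.
#'
#' @param data an `"rt_dataset"` from [build_dataset()].
#' @param max_depth maximum tree depth, default 3.
#' @return The root `"tree_node"`.
#' @export
fit_tree <- function(data, max_depth = 3L) {
  stopifnot(inherits(data, "rt_dataset"))
  n1 <- sum(data$labels == 1L)
  n0 <- sum(data$labels == 0L)
  if (n0 == 0L || n1 == 0L) {
    warning("single-class input: returning a degenerate single-leaf tree")
    return(.tree_node(NULL, NULL, n0, n1))
  }
  df <- as.data.frame(data$features)
  names(df) <- paste0("F", seq_len(ncol(data$features)))
  df$.y <- factor(ifelse(data$labels == 1L, "reactive", "unreactive"),
                  levels = c("unreactive", "reactive"))
  fit <- rpart::rpart(
    .y ~ ., data = df, method = "class",
    parms = list(split = "information"),
    control = rpart::rpart.control(minsplit = 2L, minbucket = 1L, cp = 0,
                                   maxdepth = max_depth, xval = 0L,
                                   maxcompete = 0L, maxsurrogate = 0L))
  fr <- fit$frame
  node_ids <- as.integer(rownames(fr))
  internal_rows <- which(fr$var != "<leaf>")
  # one split row per internal node, in frame (preorder) sequence
  split_of_row <- rep(NA_integer_, nrow(fr))
  split_of_row[internal_rows] <- seq_along(internal_rows)
  counts <- round(fr$yval2[, 2:3, drop = FALSE])  # unreactive, reactive
  storage.mode(counts) <- "integer"

  build <- function(id, depth) {
    row <- match(id, node_ids)
    nu <- unname(counts[row, 1L])
    nr <- unname(counts[row, 2L])
    if (fr$var[row] == "<leaf>")
      return(.tree_node(NULL, NULL, nu, nr, depth = depth))
    srow <- split_of_row[row]
    cut <- unname(fit$splits[srow, "index"])
    ncat <- fit$splits[srow, "ncat"]
    fidx <- as.integer(sub("^F", "", as.character(fr$var[row])))
    kids <- lapply(c(2L * id, 2L * id + 1L), build, depth = depth + 1L)
    # rpart's left child holds x < cut when ncat == -1, x >= cut when +1;
    # normalize so our left child is always the 'feature < threshold' branch
    if (ncat == 1) kids <- rev(kids)
    .tree_node(data$feature_labels[fidx], cut, nu, nr,
               left = kids[[1L]], right = kids[[2L]], depth = depth)
  }
  build(1L, 0L)
}

#' @export
print.tree_node <- function(x, ...) {
  rec <- function(node, prefix) {
    if (is_leaf(node)) {
      cat(sprintf("%sleaf (%d unreactive, %d reactive), p_reactive = %.3f\n",
                  prefix, node$n_unreactive, node$n_reactive,
                  leaf_reactive_probability(node)))
    } else {
      cat(sprintf("%s%s <= %.4g  (%d unreactive, %d reactive)\n",
                  prefix, node$feature, node$threshold,
                  node$n_unreactive, node$n_reactive))
      rec(node$left, paste0(prefix, "  [T] "))
      rec(node$right, paste0(prefix, "  [F] "))
    }
  }
  rec(x, "")
  invisible(x)
}

#' Reactive probability of a node
#'
#' The fraction of samples entering the node that belong to reactive paths,
#' `n_r / (n_r + n_u)`.
#'
#' @param node a `"tree_node"`.
#' @return A probability in `[0, 1]`.
#' @export
leaf_reactive_probability <- function(node) {
  n <- node$n_unreactive + node$n_reactive
  if (n == 0) stop("node has no samples")
  node$n_reactive / n
}

#' Score of a leaf for main-path selection
#'
#' The number of reactive samples weighted by the reactive fraction,
#' `n_r * n_r / (n_r + n_u)`.
#'
#' @param n_reactive,n_unreactive class counts of the leaf.
#' @return The score (0 if the leaf is empty).
#' @export
main_path_score <- function(n_reactive, n_unreactive) {
  n <- n_reactive + n_unreactive
  ifelse(n == 0, 0, n_reactive^2 / n)
}

#' Extract the main decision path
#'
#' Finds the leaf maximizing `n_r^2 / (n_r + n_u)` -- the leaf with the most
#' reactive samples weighted by its reactive fraction -- and returns the
#' root-to-leaf sequence of split conditions leading to it. Ties are broken
#' toward the shallower leaf, then toward the leaf reached first in preorder
#' (which follows the lowest-feature-index convention of the split search).
#'
#' @param root a fitted `"tree_node"`.
#' @return An object of class `"decision_path"`: a list with `steps` (one
#'   entry per internal node on the path: feature, threshold, direction
#'   `"<"`/`">="`, counts), `leaf` (counts, `score`,
#'   `reactive_probability`).
#' @export
main_decision_path <- function(root) {
  best <- NULL
  walk <- function(node, steps) {
    if (is_leaf(node)) {
      cand <- list(steps = steps, leaf = node,
                   score = main_path_score(node$n_reactive, node$n_unreactive))
      if (is.null(best) || cand$score > best$score ||
          (cand$score == best$score && node$depth < best$leaf$depth))
        best <<- cand
      return(invisible())
    }
    step <- function(dir) list(feature = node$feature,
                               threshold = node$threshold, direction = dir,
                               n_unreactive = node$n_unreactive,
                               n_reactive = node$n_reactive)
    walk(node$left, c(steps, list(step("<"))))
    walk(node$right, c(steps, list(step(">="))))
  }
  walk(root, list())
  structure(list(steps = best$steps,
                 leaf = list(n_unreactive = best$leaf$n_unreactive,
                             n_reactive = best$leaf$n_reactive,
                             score = best$score,
                             reactive_probability =
                               leaf_reactive_probability(best$leaf))),
            class = "decision_path")
}

#' @export
print.decision_path <- function(x, ...) {
  cat("<decision_path>\n")
  for (st in x$steps)
    cat(sprintf("  %s %s %.4g  (%d unreactive, %d reactive)\n",
                st$feature, st$direction, st$threshold,
                st$n_unreactive, st$n_reactive))
  cat(sprintf("  leaf: (%d unreactive, %d reactive), score = %.3f, p_reactive = %.1f%%\n",
              x$leaf$n_unreactive, x$leaf$n_reactive, x$leaf$score,
              100 * x$leaf$reactive_probability))
  invisible(x)
}

# ---- depth-1 entropy stump forest ------------------------------------------

.xlog2 <- function(p) {
  out <- numeric(length(p))
  pos <- p > 0
  out[pos] <- p[pos] * log2(p[pos])
  out
}

# two-class entropy from count vectors; empty nodes contribute 0
.h2 <- function(c0, c1) {
  tot <- pmax(c0 + c1, 1)
  -(.xlog2(c1 / tot) + .xlog2(c0 / tot))
}

# Best entropy split over the given feature columns of x (n x F) against
# binary y, with per-row multiplicities w (a bootstrap count vector).
# Candidate thresholds are midpoints between adjacent distinct sorted values;
# equal-gain ties are broken toward the lowest feature index, then the lowest
# threshold. `pre` carries per-dataset precomputations from .stump_precompute
# so repeated bootstrap calls avoid re-sorting. Returns NULL when no split
# improves on the parent.
.best_stump <- function(x, y, feat_idx, w = NULL, pre = NULL) {
  n <- length(y)
  if (is.null(w)) w <- rep(1L, n)
  if (is.null(pre)) pre <- .stump_precompute(x, y)
  ntot <- sum(w)
  tot1 <- sum(w * y)
  h_parent <- node_entropy(ntot - tot1, tot1)
  if (h_parent == 0) return(NULL)
  best <- NULL
  for (f in feat_idx) {
    k <- pre$cuts[[f]]                 # distinct-value boundary positions
    if (!length(k)) next
    wo <- w[pre$ord[, f]]
    cumn <- cumsum(wo)
    cum1 <- cumsum(wo * pre$ysort[, f])
    nl <- cumn[k]
    n1l <- cum1[k]
    n1r <- tot1 - n1l
    n0r <- (ntot - nl) - n1r
    gain <- h_parent -
      (nl * .h2(nl - n1l, n1l) + (ntot - nl) * .h2(n0r, n1r)) / ntot
    i <- which.max(gain)
    if (is.null(best) || gain[i] > best$gain + 1e-12) {
      xs <- pre$xsort[, f]
      best <- list(feature = f, gain = gain[i],
                   threshold = (xs[k[i]] + xs[k[i] + 1L]) / 2)
    }
  }
  if (!is.null(best) && best$gain <= 1e-12) best <- NULL
  best
}

# per-dataset sort structures shared by all bootstrap stumps of a forest
.stump_precompute <- function(x, y) {
  n <- nrow(x)
  ord <- apply(x, 2L, order)
  xsort <- matrix(x[cbind(as.vector(ord), rep(seq_len(ncol(x)), each = n))],
                  n, ncol(x))
  ysort <- matrix(y[ord], n, ncol(x))
  cuts <- lapply(seq_len(ncol(x)), function(f)
    which(xsort[-n, f] < xsort[-1L, f]))
  list(ord = ord, xsort = xsort, ysort = ysort, cuts = cuts)
}

#' First-split importance from a depth-one random forest
#'
#' Grows a forest of decision stumps (depth-one trees): each stump is fit on
#' a bootstrap sample of the rows with the entropy criterion restricted to a
#' random subset of `mtry` features. Because every tree contains exactly one
#' split, the forest's normalized impurity importance reduces to the
#' frequency with which each feature is chosen as the first split, which is
#' precisely the reliability of the first split of a full tree. Importances
#' are normalized to sum to 1.
#'
#' @param data an `"rt_dataset"`.
#' @param n_trees number of stumps, default 1000.
#' @param mtry features sampled per stump; default `floor(F / 3)`. The usual
#'   `sqrt(F)` heuristic is a poor default here because the invariant matrix
#'   carries every distance twice (entry and mirrored entry) and neighboring
#'   entries are strongly correlated, which under small subsets dilutes the
#'   win frequency of the true first split across its proxies.
#' @param seed integer seed.
#' @return Named numeric vector of importances (names are feature labels).
#' @export
rf_first_split_importance <- function(data, n_trees = 1000L, mtry = NULL,
                                      seed = 1L) {
  stopifnot(inherits(data, "rt_dataset"))
  y <- data$labels
  if (length(unique(y)) < 2L)
    stop("both classes must be present to grow a forest")
  x <- data$features
  nf <- ncol(x)
  n <- nrow(x)
  if (is.null(mtry)) mtry <- max(1L, nf %/% 3L)
  pre <- .stump_precompute(x, y)
  wins <- numeric(nf)
  with_local_seed(seed, {
    for (t in seq_len(n_trees)) {
      w <- tabulate(sample.int(n, n, replace = TRUE), nbins = n)
      feats <- sort(sample.int(nf, mtry))
      st <- .best_stump(x, y, feats, w = w, pre = pre)
      if (!is.null(st)) wins[st$feature] <- wins[st$feature] + 1
    }
  })
  if (sum(wins) == 0)
    stop("no stump found an improving split; importances undefined")
  setNames(wins / sum(wins), data$feature_labels)
}

# contiguous near-equal partition of 1..n into b blocks; the remainder is
# spread over the leading blocks (n = 25, b = 10 gives sizes 3,3,3,3,3,2,...)
.block_bounds <- function(n, b) {
  sizes <- rep(n %/% b, b) + c(rep(1L, n %% b), rep(0L, b - n %% b))
  stops <- cumsum(sizes)
  list(sizes = sizes, starts = c(1L, head(stops, -1L) + 1L), stops = stops)
}

#' Blocked first-split importance with Gaussian error model
#'
#' Estimates the reliability of each feature's claim to the first split.
#' Rows (already in sampling-generation order) are cut into `n_blocks`
#' contiguous, near-equal blocks; row order is randomized within each block;
#' one depth-one forest is grown per block, giving a per-feature importance
#' series from which a standard deviation `sigma` is computed. The mean
#' importance comes from a forest on the whole dataset.
#'
#' @param data an `"rt_dataset"` with rows in generation order.
#' @param n_blocks number of contiguous blocks, default 10.
#' @param n_trees stumps per forest, default 1000.
#' @param mtry features per stump; default `floor(F / 3)`, see
#'   [rf_first_split_importance()].
#' @param seed integer seed.
#' @return An object of class `"importance_estimate"`: `labels`, `mean`,
#'   `sigma`, `block_importances` (n_blocks x F matrix) and
#'   `p_most_important` (NULL until [prob_most_important()] is run).
#' @export
blocked_importance <- function(data, n_blocks = 10L, n_trees = 1000L,
                               mtry = NULL, seed = 1L) {
  stopifnot(inherits(data, "rt_dataset"))
  n <- nrow(data$features)
  if (n < n_blocks)
    stop("fewer rows (", n, ") than blocks (", n_blocks,
         "); use fewer blocks")
  if (is.unsorted(data$generation_orders))
    stop("dataset rows must be ordered by generation_order")
  bounds <- .block_bounds(n, n_blocks)
  starts <- bounds$starts
  stops <- bounds$stops
  nf <- ncol(data$features)
  block_imp <- matrix(0, n_blocks, nf)
  with_local_seed(seed, {
    sub_seeds <- sample.int(.Machine$integer.max - 1L, 3L)
    for (b in seq_len(n_blocks)) {
      # randomized within the block; the shuffle and the forest share seeds
      # across blocks (common random numbers), so the block-to-block spread
      # reflects data variation, not sampling noise of the estimator itself
      perm <- with_local_seed(sub_seeds[1L],
                              sample.int(stops[b] - starts[b] + 1L))
      rows <- starts[b] - 1L + perm
      sub <- structure(list(features = data$features[rows, , drop = FALSE],
                            labels = data$labels[rows],
                            feature_labels = data$feature_labels),
                       class = "rt_dataset")
      block_imp[b, ] <- rf_first_split_importance(
        sub, n_trees = n_trees, mtry = mtry, seed = sub_seeds[2L])
    }
    mean_imp <- rf_first_split_importance(
      data, n_trees = n_trees, mtry = mtry, seed = sub_seeds[3L])
    structure(list(labels = data$feature_labels,
                   mean = unname(mean_imp),
                   sigma = apply(block_imp, 2L, sd),
                   block_importances = block_imp,
                   p_most_important = NULL),
              class = "importance_estimate")
  })
}

#' Probability that each feature is the true first split
#'
#' Models each feature's importance as an independent Gaussian with the
#' blocked mean and sigma, and estimates by Monte Carlo the probability that
#' each feature draws the largest importance. With all sigmas zero the
#' estimate degenerates to probability 1 on the maximum-mean feature (split
#' uniformly over exact ties).
#'
#' @param est an `"importance_estimate"` from [blocked_importance()].
#' @param n_mc Monte Carlo draws, default 1e5.
#' @param seed integer seed.
#' @return The estimate with `p_most_important` filled in (sums to 1).
#' @export
prob_most_important <- function(est, n_mc = 1e5L, seed = 1L) {
  stopifnot(inherits(est, "importance_estimate"))
  nf <- length(est$mean)
  sigma <- pmax(est$sigma, 0)
  p <- numeric(nf)
  if (all(sigma == 0)) {
    top <- which(est$mean == max(est$mean))
    p[top] <- 1 / length(top)
    est$p_most_important <- setNames(p, est$labels)
    return(est)
  }
  # only features that could ever win need simulating
  active <- which(est$mean > 0 | sigma > 0)
  mu_a <- est$mean[active]
  sd_a <- sigma[active]
  counts <- numeric(length(active))
  with_local_seed(seed, {
    left <- as.integer(n_mc)
    chunk <- max(1L, min(left, as.integer(ceiling(2e6 / length(active)))))
    while (left > 0L) {
      k <- min(chunk, left)
      draws <- matrix(rnorm(k * length(active), mean = rep(mu_a, each = k),
                            sd = rep(sd_a, each = k)), nrow = k)
      w <- max.col(draws, ties.method = "random")
      tab <- tabulate(w, nbins = length(active))
      counts <- counts + tab
      left <- left - k
    }
  })
  p[active] <- counts / n_mc
  est$p_most_important <- setNames(p, est$labels)
  est
}

#' @export
print.importance_estimate <- function(x, n = 5L, ...) {
  ord <- order(-x$mean)[seq_len(min(n, length(x$mean)))]
  cat("<importance_estimate> top features:\n")
  for (i in ord)
    cat(sprintf("  %-10s mean = %.4f  sigma = %.4f  p_first = %s\n",
                x$labels[i], x$mean[i], x$sigma[i],
                if (is.null(x$p_most_important)) "NA"
                else sprintf("%.3f", x$p_most_important[i])))
  invisible(x)
}

#' Write an importance table as TSV
#'
#' Columns: feature label, mean importance, sigma, p_most_important; sorted
#' by descending mean importance.
#'
#' @param est an `"importance_estimate"`.
#' @param file destination path.
#' @param header_comment optional comment line.
#' @return Invisibly, `file`.
#' @export
write_importance_tsv <- function(est, file, header_comment = NULL) {
  ord <- order(-est$mean)
  p <- if (is.null(est$p_most_important)) rep(NA_real_, length(est$mean))
       else est$p_most_important
  con <- file(file, "wt")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  writeLines("feature\tmean_importance\tsigma\tp_most_important", con)
  for (i in ord)
    writeLines(sprintf("%s\t%.6g\t%.6g\t%.6g", est$labels[i], est$mean[i],
                       est$sigma[i], p[i]), con)
  invisible(file)
}

#' Render a decision tree as a DOT graph
#'
#' Each node box reports the split inequality (with the primed feature
#' notation), the number of samples entering, the (unreactive, reactive)
#' counts and the majority class; the true branch is drawn on the left.
#'
#' @param root a `"tree_node"`.
#' @param out destination path for the DOT text.
#' @param header_comment optional comment line written at the top.
#' @return Invisibly, `out`.
#' @export
render_tree <- function(root, out, header_comment = NULL) {
  lines <- character(0L)
  counter <- 0L
  emit <- function(node) {
    counter <<- counter + 1L
    id <- counter
    n <- node$n_unreactive + node$n_reactive
    cls <- if (node$n_reactive > node$n_unreactive) "reactive" else "unreactive"
    lab <- if (is_leaf(node))
      sprintf("samples = %d\\n(%d, %d)\\nclass = %s",
              n, node$n_unreactive, node$n_reactive, cls)
    else
      sprintf("%s <= %.6g\\nsamples = %d\\n(%d, %d)\\nclass = %s",
              node$feature, node$threshold, n,
              node$n_unreactive, node$n_reactive, cls)
    lines <<- c(lines, sprintf("  n%d [label=\"%s\", shape=box];", id, lab))
    if (!is_leaf(node)) {
      lid <- emit(node$left)
      rid <- emit(node$right)
      lines <<- c(lines,
                  sprintf("  n%d -> n%d [label=\"True\"];", id, lid),
                  sprintf("  n%d -> n%d [label=\"False\"];", id, rid))
    }
    id
  }
  emit(root)
  txt <- c(if (!is.null(header_comment)) paste0("// ", header_comment),
           "digraph decision_tree {", "  ordering=out;", lines, "}")
  writeLines(txt, out)
  invisible(out)
}
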