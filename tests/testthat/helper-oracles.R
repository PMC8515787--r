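# Independent oracles and fixture builders used across the suite.
# Everything here is deliberately brute-force and free of package internals.

# random frame with a C/O/H composition and non-degenerate geometry
rand_frame <- function(m, include_velocities = FALSE) {
  el <- sample(c("C", "O", "H"), m, replace = TRUE)
  fr <- frame(el, matrix(runif(3 * m, -5, 5), ncol = 3),
              velocities = if (include_velocities)
                matrix(rnorm(3 * m), ncol = 3),
              time_index = 0L)
  fr
}

# O(M^2) pairwise-distance loop
brute_pairwise <- function(coords) {
  m <- nrow(coords)
  d <- matrix(0, m, m)
  for (i in seq_len(m))
    for (j in seq_len(m))
      d[i, j] <- sqrt(sum((coords[i, ] - coords[j, ])^2))
  d
}

# direct re-derivation of the order parameter by exhaustive enumeration
brute_s <- function(fr, cfg) {
  d <- brute_pairwise(fr$coords)
  r_min <- min(d[cfg$acid_oxygen_indices, cfg$reactive_hydrogen_indices])
  if (r_min < cfg$protonation_threshold) return(r_min)
  ox <- which(fr$elements == "O")
  nearest <- vapply(cfg$reactive_hydrogen_indices, function(h)
    ox[which.min(d[h, ox])], 0L)
  water_ox <- setdiff(ox, cfg$acid_oxygen_indices)
  triply <- water_ox[vapply(water_ox, function(o) sum(nearest == o), 0L) == 3L]
  if (!length(triply)) return(r_min)
  hs <- cfg$reactive_hydrogen_indices[nearest %in% triply]
  min(d[cfg$acid_oxygen_indices, hs])
}

# optimal rigid superposition RMSD (Kabsch, reflection allowed because the
# spectral reconstruction is chirality-blind)
kabsch_rmsd <- function(a, b) {
  a <- sweep(a, 2, colMeans(a))
  b <- sweep(b, 2, colMeans(b))
  s <- svd(crossprod(b, a))
  rot <- s$v %*% t(s$u)
  sqrt(mean(rowSums((a - b %*% t(rot))^2)))
}

# exhaustive best entropy split over all features and midpoints
brute_best_split <- function(x, y) {
  ent <- function(c0, c1) {
    n <- c0 + c1
    if (n == 0) return(0)
    p <- c(c0, c1) / n
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  n <- length(y)
  h0 <- ent(sum(y == 0), sum(y == 1))
  best <- list(gain = 0, feature = NA_integer_, threshold = NA_real_)
  for (f in seq_len(ncol(x))) {
    xs <- sort(unique(x[, f]))
    if (length(xs) < 2) next
    for (t in (xs[-1] + xs[-length(xs)]) / 2) {
      l <- x[, f] < t
      g <- h0 - (sum(l) * ent(sum(y[l] == 0), sum(y[l] == 1)) +
                   sum(!l) * ent(sum(y[!l] == 0), sum(y[!l] == 1))) / n
      if (g > best$gain + 1e-12)
        best <- list(gain = g, feature = f, threshold = t)
    }
  }
  best
}

# minimal rt_dataset built directly from a feature matrix
make_dataset <- function(x, y, labels = NULL) {
  structure(
    list(features = x, labels = as.integer(y),
         path_ids = sprintf("p%03d", seq_len(nrow(x))),
         generation_orders = seq_len(nrow(x)) - 1L,
         feature_labels = labels %||%
           sprintf("H%d-H%d'", seq_len(ncol(x)) - 1L, 0L)),
    class = "rt_dataset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# two-atom frames whose order parameter equals a prescribed value: a single
# acid oxygen and one reactive hydrogen at the requested separation (both the
# protonated branch and the no-hydronium fallback return that distance)
frames_with_s <- function(s_values) {
  lapply(seq_along(s_values), function(i)
    frame(c("O", "H"), rbind(c(0, 0, 0), c(s_values[i], 0, 0)),
          time_index = i - 1L))
}

two_atom_cfg <- function() colvar_config(1L, 2L)

# random proper rotation + translation applied to a frame
rigid_transform_frame <- function(fr) {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  shift <- matrix(rnorm(3, sd = 5), nrow(fr$coords), 3, byrow = TRUE)
  frame(fr$elements, fr$coords %*% q + shift, time_index = fr$time_index)
}

permute_frame <- function(fr, perm) {
  frame(fr$elements[perm], fr$coords[perm, , drop = FALSE],
        time_index = fr$time_index)
}
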