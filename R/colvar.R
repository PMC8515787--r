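#' Configuration for the proton-transfer order parameter
#'
#' Identifies which atoms play which role in the discontinuous O-H transfer
#' collective variable, and the thresholds that define the protonated and
#' product states. Atom roles are explicit configuration, not inferred from
#' bonding heuristics: `acid_oxygen_indices` are the two carboxyl oxygens of
#' the acid, `reactive_hydrogen_indices` are every hydrogen that can take part
#' in the transfer (all hydrogens except the acid's C-bound hydrogen).
#'
#' @param acid_oxygen_indices integer indices (1-based) of the acid oxygens.
#' @param reactive_hydrogen_indices integer indices of the reactive hydrogens.
#' @param protonation_threshold distance (Angstrom) below which the acid is
#'   considered protonated; default 1.4.
#' @param stateA_bound upper bound (Angstrom) of the initial, protonated
#'   state A; default 1.05.
#' @param stateB_bound lower bound (Angstrom) of the product state B
#'   (separated, hydronium-like structure); default 3.0.
#' @return An object of class `"colvar_config"`.
#' @export
colvar_config <- function(acid_oxygen_indices, reactive_hydrogen_indices,
                          protonation_threshold = 1.4,
                          stateA_bound = 1.05, stateB_bound = 3.0) {
  acid_oxygen_indices <- as.integer(acid_oxygen_indices)
  reactive_hydrogen_indices <- as.integer(reactive_hydrogen_indices)
  if (!length(acid_oxygen_indices) || !length(reactive_hydrogen_indices))
    stop("acid_oxygen_indices and reactive_hydrogen_indices must be nonempty")
  if (length(intersect(acid_oxygen_indices, reactive_hydrogen_indices)))
    stop("acid oxygen and reactive hydrogen index sets must be disjoint")
  if (!(stateA_bound > 0 && stateA_bound < stateB_bound))
    stop("need 0 < stateA_bound < stateB_bound")
  if (!(protonation_threshold > stateA_bound &&
        protonation_threshold < stateB_bound))
    stop("protonation_threshold must lie between the state bounds")
  structure(
    list(acid_oxygen_indices = acid_oxygen_indices,
         reactive_hydrogen_indices = reactive_hydrogen_indices,
         protonation_threshold = protonation_threshold,
         stateA_bound = stateA_bound, stateB_bound = stateB_bound),
    class = "colvar_config"
  )
}

.check_cfg_indices <- function(fr, cfg) {
  m <- n_atoms(fr)
  idx <- c(cfg$acid_oxygen_indices, cfg$reactive_hydrogen_indices)
  if (any(idx < 1L | idx > m))
    stop("colvar_config indices out of range for this frame (M = ", m, ")")
}

# Euclidean distances between two coordinate row-sets: |A| x |B| matrix.
.cross_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

#' Minimum acid-oxygen / reactive-hydrogen distance
#'
#' The smallest Euclidean distance between any acid oxygen and any reactive
#' hydrogen in the frame. This is the quantity the protonation test is based
#' on: while it stays below `protonation_threshold` the acid still holds its
#' proton.
#'
#' @param fr a [frame()].
#' @param cfg a [colvar_config()].
#' @return The minimum distance in Angstrom.
#' @export
min_acid_OH_distance <- function(fr, cfg) {
  .check_cfg_indices(fr, cfg)
  min(.cross_dist(fr$coords[cfg$acid_oxygen_indices, , drop = FALSE],
                  fr$coords[cfg$reactive_hydrogen_indices, , drop = FALSE]))
}

#' Assign each reactive hydrogen to its nearest oxygen
#'
#' Every reactive hydrogen is mapped to the closest oxygen in the frame (acid
#' or water) by Euclidean distance. Exact ties are broken toward the lowest
#' oxygen atom index, deterministically.
#'
#' @param fr a [frame()].
#' @param cfg a [colvar_config()].
#' @return A named integer vector: names are reactive-hydrogen indices,
#'   values the assigned oxygen indices.
#' @export
assign_hydrogens <- function(fr, cfg) {
  .check_cfg_indices(fr, cfg)
  ox <- which(fr$elements == "O")
  if (!length(ox)) stop("frame contains no oxygen atoms")
  h <- cfg$reactive_hydrogen_indices
  d <- .cross_dist(fr$coords[h, , drop = FALSE], fr$coords[ox, , drop = FALSE])
  # max.col on -d returns the first (lowest oxygen index) among tied minima
  nearest <- ox[max.col(-d, ties.method = "first")]
  setNames(nearest, h)
}

#' Proton-transfer order parameter s(r)
#'
#' A discontinuous collective variable for acid deprotonation. While the
#' smallest acid-O / reactive-H distance is below `protonation_threshold`
#' (1.4 Angstrom by default) the acid is protonated and `s` equals that
#' distance. Beyond the threshold, charge separation is quantified: hydrogens
#' are assigned to their nearest oxygen, water oxygens holding exactly three
#' hydrogens (hydronium-like) are located, and `s` is the minimum distance
#' between any acid oxygen and any hydrogen belonging to such a triply
#' coordinated oxygen. A change in the identity of the triply coordinated
#' oxygen makes `s` jump discontinuously, which is what marks the formation
#' of a separated, Zundel-like product.
#'
#' If no oxygen is triply coordinated while the threshold is exceeded (a
#' situation the state definitions leave open), `s` falls back to the minimum
#' acid-O/H distance, which keeps the series defined and continuous.
#'
#' @param fr a [frame()].
#' @param cfg a [colvar_config()].
#' @return The order parameter in Angstrom.
#' @export
order_parameter <- function(fr, cfg) {
  r_min <- min_acid_OH_distance(fr, cfg)
  if (r_min < cfg$protonation_threshold) return(r_min)
  assignment <- assign_hydrogens(fr, cfg)
  water_ox <- setdiff(which(fr$elements == "O"), cfg$acid_oxygen_indices)
  counts <- table(factor(assignment, levels = water_ox))
  triply <- as.integer(names(counts)[counts == 3L])
  if (!length(triply)) return(r_min)  # fallback: no hydronium found
  h_idx <- as.integer(names(assignment)[assignment %in% triply])
  min(.cross_dist(fr$coords[cfg$acid_oxygen_indices, , drop = FALSE],
                  fr$coords[h_idx, , drop = FALSE]))
}

#' Classify an order-parameter value into a state
#'
#' @param s order-parameter value (Angstrom), nonnegative.
#' @param cfg a [colvar_config()].
#' @return `"A"` if `s < stateA_bound`, `"B"` if `s > stateB_bound`,
#'   otherwise `"intermediate"`.
#' @export
classify_state <- function(s, cfg) {
  stopifnot(all(s >= 0))
  ifelse(s < cfg$stateA_bound, "A",
         ifelse(s > cfg$stateB_bound, "B", "intermediate"))
}

#' Order-parameter series for a trajectory
#'
#' @param frames list of [frame()] objects.
#' @param cfg a [colvar_config()].
#' @return Numeric vector of `s` values, one per frame.
#' @export
order_parameter_series <- function(frames, cfg) {
  vapply(frames, order_parameter, numeric(1L), cfg = cfg)
}

#' Segment a long trajectory into reactive and unreactive paths
#'
#' Cuts a single time-ordered trajectory into labeled excursions from the
#' initial state: a segment that leaves state A and next returns to A without
#' reaching B is unreactive; one that reaches B first is reactive. Each
#' segment carries one boundary frame inside each terminal state (its first
#' frame classifies A, its last frame classifies A or B). Leading or trailing
#' stretches that never complete an excursion are discarded. By default only
#' A-to-X excursions are emitted; `from_state = "B"` applies the symmetric
#' rule starting from the product state.
#'
#' @param frames list of [frame()] objects, time ordered.
#' @param cfg a [colvar_config()].
#' @param from_state state the excursions start from, `"A"` (default) or `"B"`.
#' @return A list of [path_record()] objects with labels
#'   `"reactive"`/`"unreactive"` and sequential `generation_order`.
#' @export
segment_trajectory <- function(frames, cfg, from_state = c("A", "B")) {
  from_state <- match.arg(from_state)
  to_state <- if (from_state == "A") "B" else "A"
  s <- order_parameter_series(frames, cfg)
  st <- classify_state(s, cfg)
  if (!any(st %in% c("A", "B"))) {
    warning("trajectory never enters state A or B; no segments produced")
    return(list())
  }
  segments <- list()
  n <- length(st)
  i <- match(from_state, st)  # first frame in the source state (NA if none)
  k <- 0L
  while (!is.na(i) && i < n) {
    # advance over consecutive source-state frames; excursion starts at the
    # last one before leaving
    while (i < n && st[i + 1L] == from_state) i <- i + 1L
    if (i >= n) break
    j <- i + 1L
    while (j <= n && !st[j] %in% c(from_state, to_state)) j <- j + 1L
    if (j > n) break  # trailing incomplete excursion: discarded
    label <- if (st[j] == to_state) "reactive" else "unreactive"
    seg <- frames[i:j]
    segments[[k + 1L]] <- path_record(
      seg, label, sprintf("seg%04d", k), generation_order = k)
    k <- k + 1L
    i <- if (st[j] == from_state) j else {
      nxt <- which(st[(j + 1L):n] == from_state)
      if (length(nxt)) j + nxt[1L] else NA_integer_
    }
  }
  segments
}
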