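#' Atom-atom distance matrix of a frame
#'
#' @param fr a [frame()].
#' @return An object of class `"distance_matrix"`: a list with `values`
#'   (symmetric M x M matrix, Angstrom) and `elements` (per-row symbols in
#'   the original atom order).
#' @export
distance_matrix <- function(fr) {
  v <- as.matrix(stats::dist(fr$coords))
  dimnames(v) <- NULL
  structure(list(values = v, elements = fr$elements),
            class = "distance_matrix")
}

#' Select the reference atom for the invariant representation
#'
#' The reference atom anchors the row sorting of the index-invariant matrix.
#' For a formic-acid/water cluster the single carbon is the natural choice
#' (it is the only atom of its element, hence trivially identifiable). An
#' element rule is only accepted when it matches exactly one atom; otherwise
#' an explicit index must be given.
#'
#' @param fr a [frame()].
#' @param rule an element symbol (e.g. `"C"`) or an explicit integer index.
#' @return The 1-based atom index of the reference atom.
#' @export
select_reference_atom <- function(fr, rule = "C") {
  if (is.numeric(rule)) {
    idx <- as.integer(rule)
    if (length(idx) != 1L || idx < 1L || idx > n_atoms(fr))
      stop("explicit reference index out of range")
    return(idx)
  }
  hits <- which(fr$elements == rule)
  if (length(hits) != 1L)
    stop(sprintf(paste0("element rule '%s' matches %d atoms; give an ",
                        "explicit atom index instead"), rule, length(hits)))
  hits
}

#' Default element-group order
#'
#' The reference atom's element first, then the remaining elements present in
#' descending atomic number. For a C/O/H system with a carbon reference this
#' yields C, O, H.
#'
#' @param elements character vector of element symbols present.
#' @param ref_element element symbol of the reference atom.
#' @return Ordered character vector of unique elements.
#' @export
default_group_order <- function(elements, ref_element) {
  rest <- setdiff(unique(elements), ref_element)
  z <- .periodic_table[rest]
  z[is.na(z)] <- -Inf  # dummy atoms sort last
  c(ref_element, rest[order(-z, rest)])
}

# Order atom indices `idx` by (element group, distance, original index).
.group_sort <- function(idx, elements, dists, group_order) {
  unlist(lapply(group_order, function(el) {
    g <- idx[elements[idx] == el]
    g[order(dists[g], g)]
  }), use.names = FALSE)
}

#' Index-invariant distance matrix
#'
#' Reorders a distance matrix so that the result no longer depends on the
#' input atom order. Rows are grouped per element (in `group_order`) and
#' sorted within each group by distance to the reference atom; each row's
#' columns are grouped and sorted the same way but by distance to that row's
#' own atom. Entry (i, j) is therefore the distance from the i-th row atom to
#' its j-th neighbor under the element-grouped ranking, and the column rank
#' can name a different physical atom in every row. Self-distances (the zero
#' diagonal) are retained, so every row's first entry within its own element
#' group is 0 and the flattened vector has length M^2. All permutations are
#' recorded so the sorting can be undone exactly.
#'
#' Exact distance ties are broken by original atom index (a stable, documented
#' choice); tied geometries make the representation formally non-unique.
#'
#' @param dmat a [distance_matrix()].
#' @param ref 1-based reference atom index.
#' @param group_order ordered element list covering every element present;
#'   default [default_group_order()].
#' @return An object of class `"invariant_matrix"`: `values` (M x M),
#'   `row_order` (atom indices by row), `col_order` (list of M atom-index
#'   permutations), `ref_atom`, `element_group_order`.
#' @export
index_invariant_matrix <- function(dmat, ref,
                                   group_order = NULL) {
  stopifnot(inherits(dmat, "distance_matrix"))
  m <- length(dmat$elements)
  if (ref < 1L || ref > m) stop("reference atom index out of range")
  if (is.null(group_order))
    group_order <- default_group_order(dmat$elements, dmat$elements[ref])
  missing_el <- setdiff(unique(dmat$elements), group_order)
  if (length(missing_el))
    stop("group_order is missing element(s): ",
         paste(missing_el, collapse = ", "))
  idx <- seq_len(m)
  row_order <- .group_sort(idx, dmat$elements, dmat$values[ref, ], group_order)
  col_order <- lapply(row_order, function(a)
    .group_sort(idx, dmat$elements, dmat$values[a, ], group_order))
  values <- matrix(0, m, m)
  for (i in idx)
    values[i, ] <- dmat$values[row_order[i], col_order[[i]]]
  structure(
    list(values = values, row_order = row_order, col_order = col_order,
         ref_atom = as.integer(ref), element_group_order = group_order,
         elements = dmat$elements),
    class = "invariant_matrix"
  )
}

#' Featurize a frame in one step
#'
#' Convenience wrapper: distance matrix, reference-atom selection and
#' index-invariant sorting.
#'
#' @param fr a [frame()].
#' @param ref_rule element symbol or explicit index for
#'   [select_reference_atom()].
#' @param group_order optional element-group order.
#' @return An `"invariant_matrix"`.
#' @export
featurize_frame <- function(fr, ref_rule = "C", group_order = NULL) {
  index_invariant_matrix(distance_matrix(fr),
                         select_reference_atom(fr, ref_rule),
                         group_order = group_order)
}

#' Feature labels for the invariant matrix
#'
#' Each atom is named by its element and its 0-based rank within the element
#' group: row atoms are ranked by distance from the reference atom, column
#' atoms by distance from the row atom, with a prime marking the column
#' (secondary) index. `"O2-H5'"` is thus the distance from the third-closest
#' oxygen to the reference to that oxygen's sixth-closest hydrogen. Because
#' the element-count layout is the same in every row, the grid depends only
#' on the element multiset and the group order.
#'
#' @param elements element symbols of the frame (any order).
#' @param group_order ordered element list.
#' @return An M x M character matrix of rendered labels, aligned
#'   entry-for-entry with `invariant_matrix$values`.
#' @export
feature_labels <- function(elements, group_order) {
  counts <- vapply(group_order, function(el) sum(elements == el), 0L)
  if (sum(counts) != length(elements))
    stop("group_order does not cover all elements")
  axis <- unlist(lapply(group_order, function(el)
    sprintf("%s%d", el, seq_len(sum(elements == el)) - 1L)), use.names = FALSE)
  outer(axis, axis, function(r, c) paste0(r, "-", c, "'"))
}

#' Parse a rendered feature label
#'
#' @param label a label such as `"O2-H5'"`.
#' @return A list with `row_element`, `row_rank`, `col_element`, `col_rank`.
#' @export
parse_feature_label <- function(label) {
  m <- regmatches(label,
                  regexec("^([A-Z][a-z]?)([0-9]+)-([A-Z][a-z]?)([0-9]+)'$",
                          label))[[1L]]
  if (!length(m)) stop("unparsable feature label: ", label)
  list(row_element = m[2L], row_rank = as.integer(m[3L]),
       col_element = m[4L], col_rank = as.integer(m[5L]))
}

#' Resolve a feature label to its concrete atom pair
#'
#' Uses the invariant matrix's recorded permutations to find which two
#' physical atoms realize a labeled entry in the frame the matrix was
#' computed from.
#'
#' @param inv an `"invariant_matrix"`.
#' @param label a rendered label (e.g. `"O2-H5'"`) or a parsed label list.
#' @return Named integer vector with `row_atom`, `col_atom` (original atom
#'   indices) and `row_pos`, `col_pos` (positions in the sorted layout).
#' @export
resolve_feature_atoms <- function(inv, label) {
  lab <- if (is.character(label)) parse_feature_label(label) else label
  row_in_group <- function(order_vec, el, rank) {
    members <- which(inv$elements[order_vec] == el)
    if (rank + 1L > length(members))
      stop(sprintf("label rank %s%d' exceeds the %s count (%d)",
                   el, rank, el, length(members)))
    members[rank + 1L]
  }
  ri <- row_in_group(inv$row_order, lab$row_element, lab$row_rank)
  ci <- row_in_group(inv$col_order[[ri]], lab$col_element, lab$col_rank)
  c(row_atom = inv$row_order[ri], col_atom = inv$col_order[[ri]][ci],
    row_pos = ri, col_pos = ci)
}

#' Flatten an invariant matrix to a feature vector
#'
#' Row-major flattening; the result has length exactly M^2, with a parallel
#' vector of rendered feature labels.
#'
#' @param inv an `"invariant_matrix"`.
#' @return A list with `features` (numeric, length M^2) and `labels`
#'   (character, same length).
#' @export
flatten <- function(inv) {
  lab <- feature_labels(inv$elements, inv$element_group_order)
  list(features = as.vector(t(inv$values)), labels = as.vector(t(lab)))
}

#' Undo the invariant sorting
#'
#' Reconstructs the symmetric distance matrix from an invariant matrix using
#' its recorded permutations. The result is expressed in the sorted-row atom
#' order, i.e. it equals the original matrix up to one overall atom
#' permutation; no arithmetic is involved.
#'
#' @param inv an `"invariant_matrix"`.
#' @return A `"distance_matrix"` whose rows follow `inv$row_order`.
#' @export
unsort <- function(inv) {
  m <- nrow(inv$values)
  out <- matrix(0, m, m)
  for (i in seq_len(m)) {
    pos <- match(inv$row_order, inv$col_order[[i]])
    if (anyNA(pos)) stop("inconsistent permutations in invariant matrix")
    out[i, ] <- inv$values[i, pos]
  }
  if (max(abs(out - t(out))) > 1e-9 || any(diag(out) != 0))
    stop("inconsistent permutations: reconstruction is not symmetric")
  structure(list(values = out, elements = inv$elements[inv$row_order]),
            class = "distance_matrix")
}

#' Back-map a distance matrix to Cartesian coordinates
#'
#' Classical multidimensional scaling: the squared-distance matrix is double
#' centered to a Gram matrix, eigendecomposed, and coordinates are the
#' leading three eigenvectors scaled by the square roots of their
#' eigenvalues. For a 3D-embeddable input the pairwise distances are
#' reproduced up to numerical tolerance and the coordinates equal the
#' originals up to a rigid motion (and possible reflection). Inputs with more
#' than three significantly positive eigenvalues are not exactly embeddable
#' in 3D; a warning is emitted and the best rank-3 approximation returned.
#' Negative eigenvalues beyond tolerance are clamped to zero with a warning.
#'
#' @param dmat a `"distance_matrix"` (or bare symmetric matrix).
#' @param tol relative eigenvalue tolerance (fraction of the largest
#'   eigenvalue) for embeddability checks; default 1e-9.
#' @return An M x 3 coordinate matrix (Angstrom).
#' @export
backmap_coordinates <- function(dmat, tol = 1e-9) {
  d <- if (inherits(dmat, "distance_matrix")) dmat$values else as.matrix(dmat)
  m <- nrow(d)
  if (max(abs(d - t(d))) > 1e-8 || any(abs(diag(d)) > 1e-12))
    stop("input must be a symmetric matrix with zero diagonal")
  if (m == 1L) return(matrix(0, 1L, 3L))
  j <- diag(m) - 1 / m
  g <- -0.5 * j %*% (d^2) %*% j         # Gram matrix of centered coordinates
  g <- (g + t(g)) / 2
  e <- eigen(g, symmetric = TRUE)
  scale_ref <- max(abs(e$values))
  if (scale_ref == 0) return(matrix(0, m, 3L))  # all points coincident
  if (sum(e$values > tol * scale_ref) > 3L)
    warning("distance matrix is not 3D-embeddable; ",
            "returning the best rank-3 approximation")
  if (any(e$values < -tol * scale_ref))
    warning("negative Gram eigenvalues beyond tolerance clamped to zero")
  k <- min(3L, m)
  lam <- pmax(e$values[seq_len(k)], 0)
  xyz <- e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(lam), k)
  cbind(xyz, matrix(0, m, 3L - k))
}

#' Add dummy marker atoms for decision-split visualization
#'
#' For each feature label on a decision path, the two physical atoms that
#' realize that matrix entry in the given frame are located through the
#' invariant matrix's permutations, and a pair of marker atoms (element
#' `"X"`) is appended at their positions. Written through [write_xyz()], the
#' markers let visualization software highlight and measure the split
#' distances directly on the structure. Original atoms are unchanged.
#'
#' @param fr the [frame()] the invariant matrix was computed from.
#' @param node_features character vector of feature labels (or list of
#'   parsed labels).
#' @param inv the `"invariant_matrix"` of `fr`.
#' @return A new [frame()] with `2 * length(node_features)` marker atoms
#'   appended.
#' @export
place_dummy_atoms <- function(fr, node_features, inv) {
  if (!length(node_features)) return(fr)
  extra <- matrix(0, 0L, 3L)
  for (lab in node_features) {
    atoms <- resolve_feature_atoms(inv, lab)
    extra <- rbind(extra, fr$coords[atoms[["row_atom"]], , drop = FALSE],
                   fr$coords[atoms[["col_atom"]], , drop = FALSE])
  }
  frame(c(fr$elements, rep("X", nrow(extra))), rbind(fr$coords, extra),
        time_index = fr$time_index)
}
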