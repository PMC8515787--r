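test_that("the distance matrix matches the pairwise brute force", {
  expect_equal(distance_matrix(frame("C", matrix(0, 1, 3)))$values,
               matrix(0, 1, 1))
  fr <- frame(c("C", "O"), rbind(c(0, 0, 0), c(3, 4, 0)))
  expect_equal(distance_matrix(fr)$values[1, 2], 5)

  set.seed(3)
  fr <- rand_frame(12)
  d <- distance_matrix(fr)$values
  expect_equal(d, brute_pairwise(fr$coords))
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
})

test_that("reference-atom selection resolves element rules and indices", {
  fr <- template_cluster(4)
  expect_identical(select_reference_atom(fr, "C"), 1L)
  expect_identical(select_reference_atom(fr, 7), 7L)
  water <- frame(c("O", "H", "H"),
                 rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0)))
  expect_error(select_reference_atom(water, "C"), "explicit")
  expect_error(select_reference_atom(fr, "O"), "explicit")
})

test_that("the collinear toy system sorts to the hand-computed matrix", {
  # C at 0, O at 1, O at 2, H at 3 (on a line), fed in scrambled order
  fr <- frame(c("H", "O", "C", "O"),
              rbind(c(3, 0, 0), c(2, 0, 0), c(0, 0, 0), c(1, 0, 0)))
  inv <- index_invariant_matrix(distance_matrix(fr),
                                select_reference_atom(fr, "C"),
                                group_order = c("C", "O", "H"))
  hand <- rbind(c(0, 1, 2, 3),
                c(1, 0, 1, 2),
                c(2, 0, 1, 1),
                c(3, 1, 2, 0))
  expect_equal(inv$values, hand)
  expect_identical(inv$row_order, c(3L, 4L, 2L, 1L))
})

test_that("feature labels follow the element-grouped primed notation", {
  fa <- c("C", "O", "O", "H", "H")
  g <- feature_labels(fa, c("C", "O", "H"))
  expect_identical(g[1, ], c("C0-C0'", "C0-O0'", "C0-O1'", "C0-H0'", "C0-H1'"))
  expect_identical(g[, 1], c("C0-C0'", "O0-C0'", "O1-C0'", "H0-C0'", "H1-C0'"))
  expect_identical(feature_labels("C", "C"), matrix("C0-C0'", 1, 1))
  parsed <- parse_feature_label("O2-H5'")
  expect_identical(parsed,
                   list(row_element = "O", row_rank = 2L,
                        col_element = "H", col_rank = 5L))
})

test_that("each row's own-element rank-0 column is its zero self-distance", {
  set.seed(8)
  for (rep in 1:5) {
    fr <- rand_frame(sample(5:15, 1))
    ref <- sample(length(fr$elements), 1)
    inv <- index_invariant_matrix(distance_matrix(fr), ref)
    labs <- feature_labels(fr$elements, inv$element_group_order)
    for (i in seq_along(inv$row_order)) {
      el <- fr$elements[inv$row_order[i]]
      j <- match(sprintf("%s0'", el), sub("^.*-", "", labs[i, ]))
      expect_identical(inv$values[i, j], 0)
    }
  }
})

test_that("label semantics rank atoms by distance from reference and row atom", {
  set.seed(19)
  fr <- template_cluster(6)
  fr$coords <- fr$coords + matrix(rnorm(length(fr$coords), sd = 0.05), ncol = 3)
  inv <- featurize_frame(fr)
  d <- brute_pairwise(fr$coords)
  # O2-H5': third-closest oxygen to the reference carbon, its sixth-closest H
  os <- which(fr$elements == "O")
  row_atom <- os[order(d[1, os])][3]
  hs <- which(fr$elements == "H")
  col_atom <- hs[order(d[row_atom, hs])][6]
  fl <- flatten(inv)
  expect_equal(fl$features[match("O2-H5'", fl$labels)], d[row_atom, col_atom])
  atoms <- resolve_feature_atoms(inv, "O2-H5'")
  expect_identical(unname(atoms[c("row_atom", "col_atom")]),
                   c(row_atom, col_atom))
})

test_that("flattened feature vectors have length M^2", {
  expect_length(flatten(featurize_frame(template_cluster(6)))$features, 529L)
  expect_length(flatten(featurize_frame(template_cluster(4)))$features, 289L)
  fr1 <- frame("C", matrix(0, 1, 3))
  fl1 <- flatten(index_invariant_matrix(distance_matrix(fr1), 1L))
  expect_identical(fl1$features, 0)
  expect_identical(fl1$labels, "C0-C0'")
})

test_that("unsort undoes the invariant sorting exactly", {
  fr1 <- frame("C", matrix(0, 1, 3))
  expect_equal(unsort(index_invariant_matrix(distance_matrix(fr1), 1L))$values,
               matrix(0, 1, 1))

  set.seed(23)
  for (rep in 1:5) {
    fr <- rand_frame(sample(4:20, 1))
    dm <- distance_matrix(fr)
    inv <- index_invariant_matrix(dm, sample(length(fr$elements), 1))
    rec <- unsort(inv)
    expect_identical(rec$values,
                     dm$values[inv$row_order, inv$row_order])
    expect_identical(rec$elements, fr$elements[inv$row_order])
  }
})

test_that("back-mapping reconstructs 3D-embeddable distances", {
  # two points at distance d
  xy <- backmap_coordinates(matrix(c(0, 2.5, 2.5, 0), 2))
  expect_equal(dist(xy)[1], 2.5)

  set.seed(31)
  for (m in c(10, 25, 50)) {
    pts <- matrix(rnorm(3 * m, sd = 3), ncol = 3)
    d <- as.matrix(dist(pts))
    rec <- backmap_coordinates(d)
    expect_lt(max(abs(as.matrix(dist(rec)) - d)), 1e-8)
    expect_lt(kabsch_rmsd(pts, rec), 1e-8)
    # independent oracle: classical-scaling reference implementation
    ref <- cmdscale(d, k = 3)
    expect_lt(kabsch_rmsd(ref, rec), 1e-8)
  }
})

test_that("the Gram spectrum flags non-embeddable input", {
  set.seed(37)
  pts <- matrix(rnorm(30), ncol = 3)
  d <- as.matrix(dist(pts))
  g <- -0.5 * (diag(10) - 1 / 10) %*% d^2 %*% (diag(10) - 1 / 10)
  ev <- eigen((g + t(g)) / 2, symmetric = TRUE, only.values = TRUE)$values
  expect_lte(sum(ev > 1e-9 * max(ev)), 3L)
  # a 4D point set cannot embed in 3D
  p4 <- matrix(rnorm(40), ncol = 4)
  expect_warning(backmap_coordinates(as.matrix(dist(p4))), "not 3D-embeddable")
})

test_that("dummy atoms mark the physical atoms behind a feature label", {
  dimer <- frame(c("O", "H", "H", "O", "H", "H"),
                 rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0),
                       c(2.9, 0.1, 0), c(3.5, 0.8, 0), c(3.6, -0.5, 0)))
  inv <- featurize_frame(dimer, ref_rule = 1L)
  marked <- place_dummy_atoms(dimer, "O0-H0'", inv)
  expect_length(marked$elements, 8L)
  expect_identical(marked$elements[7:8], c("X", "X"))
  atoms <- resolve_feature_atoms(inv, "O0-H0'")
  expect_equal(marked$coords[7, ], dimer$coords[atoms[["row_atom"]], ])
  expect_equal(marked$coords[8, ], dimer$coords[atoms[["col_atom"]], ])
  # resolved pair realizes the matrix entry
  fl <- flatten(inv)
  expect_equal(sqrt(sum((marked$coords[7, ] - marked$coords[8, ])^2)),
               fl$features[match("O0-H0'", fl$labels)])

  expect_identical(place_dummy_atoms(dimer, character(0), inv), dimer)
  expect_error(place_dummy_atoms(dimer, "O5-H0'", inv), "rank")
})

test_that("feature vectors are invariant to rigid motion and atom relabeling", {
  set.seed(41)
  fr <- template_cluster(6)
  base <- flatten(featurize_frame(fr))$features
  for (rep in 1:25) {
    expect_lt(max(abs(flatten(featurize_frame(
      rigid_transform_frame(fr)))$features - base)), 1e-9)
    perm <- sample(length(fr$elements))
    expect_lt(max(abs(flatten(featurize_frame(
      permute_frame(fr, perm)))$features - base)), 1e-9)
  }
})
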