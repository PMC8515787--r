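# Geometry constants for the idealized cluster (Angstrom, degrees).
.fa_geom <- list(
  CO_double = 1.22, CO_single = 1.34, OH_acid = 0.97, CH = 1.09,
  OH_water = 0.96, HOH_half = 52.25,        # half of the 104.5 deg angle
  ring_base = 3.4, ring_step = 0.18, outer_extra = 0.6,
  OH_transfer = 0.98                        # O-H in scripted hydronium
)

.deg <- function(a) a * pi / 180

.rot2 <- function(v, a) c(cos(a) * v[1L] - sin(a) * v[2L],
                          sin(a) * v[1L] + cos(a) * v[2L], 0)

.unit <- function(v) v / sqrt(sum(v^2))

# Water radius from the carbon for water i (0-based); the outermost water is
# pushed further out so its rank among oxygens is stable under the planted
# displacement and jitter.
.water_radii <- function(n_waters) {
  g <- .fa_geom
  r <- g$ring_base + g$ring_step * (seq_len(n_waters) - 1L)
  r[n_waters] <- r[n_waters] + g$outer_extra
  r
}

.water_angles <- function(n_waters) .deg(70 + 360 / n_waters * (seq_len(n_waters) - 1L))

#' Idealized formic-acid/water cluster
#'
#' Builds a deterministic reference geometry: a planar formic acid molecule
#' (standard bond lengths: C=O 1.22, C-O 1.34, O-H 0.97, C-H 1.09 Angstrom)
#' surrounded by `n_waters` rigid waters (O-H 0.96 Angstrom, H-O-H 104.5
#' degrees) on a ring around the acid, radii staggered and orientations
#' varied so that no two interatomic distances tie exactly. All
#' intermolecular atom pairs are farther apart than 1.5 Angstrom. Atom
#' order: C, carbonyl O, hydroxyl O, acid H, formyl H, then O,H,H per water.
#'
#' @param n_waters number of water molecules (>= 1).
#' @return A [frame()] with `5 + 3 * n_waters` atoms.
#' @export
template_cluster <- function(n_waters) {
  if (n_waters < 1L) stop("n_waters must be >= 1")
  g <- .fa_geom
  C <- c(0, 0, 0)
  O_carb <- c(g$CO_double, 0, 0)
  O_hyd <- g$CO_single * c(cos(.deg(125)), sin(.deg(125)), 0)
  # acid H: off the hydroxyl oxygen, C-O-H close to 106 degrees
  h_dir <- .rot2(.unit(O_hyd - C), .deg(-74))
  H_acid <- O_hyd + g$OH_acid * h_dir
  H_form <- g$CH * c(cos(.deg(242.5)), sin(.deg(242.5)), 0)
  coords <- rbind(C, O_carb, O_hyd, H_acid, H_form)
  elements <- c("C", "O", "O", "H", "H")
  radii <- .water_radii(n_waters)
  angles <- .water_angles(n_waters)
  for (i in seq_len(n_waters)) {
    u <- c(cos(angles[i]), sin(angles[i]), 0)     # radial
    v <- c(-sin(angles[i]), cos(angles[i]), 0)    # tangential
    w <- c(0, 0, 1)
    # tilt the bisector off-radial and the H-plane out of the ring plane,
    # differently per water, to break all mirror symmetries
    delta <- .deg(8 + 6 * (i - 1L))
    phi <- .deg(20 + 40 * (i - 1L))
    b <- cos(delta) * u + sin(delta) * v
    p <- cos(phi) * (-sin(delta) * u + cos(delta) * v) + sin(phi) * w
    O_w <- radii[i] * u
    Ha <- O_w + g$OH_water * (cos(.deg(g$HOH_half)) * b +
                                sin(.deg(g$HOH_half)) * p)
    Hb <- O_w + g$OH_water * (cos(.deg(g$HOH_half)) * b -
                                sin(.deg(g$HOH_half)) * p)
    coords <- rbind(coords, O_w, Ha, Hb)
    elements <- c(elements, "O", "H", "H")
  }
  rownames(coords) <- NULL
  frame(elements, coords, time_index = 0L)
}

#' Collective-variable configuration for a generated cluster
#'
#' The acid oxygens are atoms 2 and 3, the reactive hydrogens every hydrogen
#' except the formyl (C-bound) one.
#'
#' @param n_waters number of waters in the cluster.
#' @param ... overrides passed to [colvar_config()].
#' @return A [colvar_config()].
#' @export
cluster_colvar_config <- function(n_waters, ...) {
  water_h <- 5L + as.vector(outer(c(2L, 3L), 3L * (seq_len(n_waters) - 1L), `+`))
  colvar_config(acid_oxygen_indices = c(2L, 3L),
                reactive_hydrogen_indices = c(4L, water_h), ...)
}

#' Specification of a synthetic labeled trajectory collection
#'
#' Defines the study conditions the generator emulates: cluster size, number
#' of paths, reactive fraction, the planted geometric signature and its
#' threshold, coordinate noise and the master seed. The planted signal is the
#' distance between the reference carbon and the outermost water oxygen
#' (matrix entry `C0-O<k>'`): reactive paths hold it below the threshold
#' inside the selection window, unreactive paths above it. That entry is the
#' recoverable ground truth of the fixture.
#'
#' @param n_waters waters in the cluster, default 4.
#' @param n_paths number of paths, default 200 (must be >= 2).
#' @param frac_reactive reactive fraction in `[0, 1]`, default 0.5; the
#'   reactive count is `round(frac_reactive * n_paths)`, interleaved evenly
#'   over generation order.
#' @param planted_threshold split point of the planted feature (Angstrom);
#'   default the template's carbon/outer-oxygen distance.
#' @param planted_delta class displacement of the outer water (Angstrom),
#'   default 0.25.
#' @param jitter_sigma Gaussian coordinate noise per frame (Angstrom),
#'   default 0.02.
#' @param seed integer master seed.
#' @return An object of class `"fixture_spec"` with the derived
#'   `planted_feature` label.
#' @export
fixture_spec <- function(n_waters = 4L, n_paths = 200L, frac_reactive = 0.5,
                         planted_threshold = NULL, planted_delta = 0.25,
                         jitter_sigma = 0.02, seed = 1L) {
  if (n_paths < 2L) stop("n_paths must be >= 2")
  if (frac_reactive > 0 && n_waters < 3L)
    stop("reactive paths need n_waters >= 3 (a far water to hop onto)")
  if (frac_reactive < 0 || frac_reactive > 1)
    stop("frac_reactive must be in [0, 1]")
  n_reactive <- round(frac_reactive * n_paths)
  if (frac_reactive > 0 && frac_reactive < 1 &&
      (n_reactive == 0L || n_reactive == n_paths))
    stop("both classes must be represented for 0 < frac_reactive < 1")
  radii <- .water_radii(n_waters)
  if (is.null(planted_threshold)) planted_threshold <- radii[n_waters]
  planted_feature <- sprintf("C0-O%d'", n_waters + 1L)
  if (planted_delta <= 2 * jitter_sigma)
    stop("planted_delta must exceed the jitter noise to be recoverable")
  structure(
    list(n_waters = as.integer(n_waters), n_paths = as.integer(n_paths),
         frac_reactive = frac_reactive, n_reactive = as.integer(n_reactive),
         planted_feature = planted_feature,
         planted_threshold = planted_threshold,
         planted_delta = planted_delta,
         jitter_sigma = jitter_sigma, seed = as.integer(seed)),
    class = "fixture_spec"
  )
}

# Evenly interleaved reactive labels with an exact count (Bresenham spread,
# integer arithmetic so the count is exact for any fraction).
.interleave_labels <- function(n_paths, n_reactive) {
  i <- seq_len(n_paths)
  (i * n_reactive) %/% n_paths > ((i - 1L) * n_reactive) %/% n_paths
}

# random rotation matrix (Haar-ish via QR, sign-fixed to a proper rotation)
.random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9L), 3L))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

#' Generate a synthetic labeled path collection
#'
#' Produces kinematically scripted trajectories of a formic-acid/water
#' cluster with known ground truth. Every path starts in state A (acid O-H
#' near 0.97 Angstrom) with Gaussian coordinate jitter. Unreactive paths
#' stretch the acid proton to ~1.3 Angstrom and return. Reactive paths carry
#' the proton onto the nearest water (forming a triply coordinated oxygen)
#' and then hop the hydronium identity to a water on the far side of the
#' cluster, so the order parameter jumps discontinuously above the state-B
#' bound. Independently of the proton script, the outermost water is placed
#' on a sphere around the carbon whose radius is `planted_delta` below the
#' planted threshold for reactive paths and `planted_delta` above it for
#' unreactive ones, with randomized angular position and orientation: the
#' carbon/outer-oxygen distance is thus the only cleanly class-separating
#' feature, and it survives the invariant featurization. Each path is
#' finally subjected to a random rigid rotation and translation.
#'
#' @param spec a [fixture_spec()].
#' @param dir optional directory; when given, XYZ files and a `manifest.csv`
#'   are written via [write_path_collection()].
#' @return A list of [path_record()] objects with sequential
#'   `generation_order`; if `dir` was given the manifest path is attached as
#'   attribute `"manifest"`.
#' @export
generate_paths <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  g <- .fa_geom
  tmpl <- template_cluster(spec$n_waters)
  nw <- spec$n_waters
  radii <- .water_radii(nw)
  outer_o <- 5L + 3L * (nw - 1L) + 1L          # atom index of outermost water O
  outer_atoms <- outer_o + 0:2
  hop_w <- max(1L, floor(nw / 2) + 1L)         # water on the far side
  if (hop_w == nw && nw > 1L) hop_w <- nw - 1L # never hop onto the planted water
  hop_o <- 5L + 3L * (hop_w - 1L) + 1L
  i_C <- 1L; i_Ohyd <- 3L; i_H <- 4L
  w0_o <- 6L                                   # nearest water oxygen
  h_dir_tmpl <- .unit(tmpl$coords[i_H, ] - tmpl$coords[i_Ohyd, ])
  s_window <- c(1.12, 1.18, 1.23)
  is_reactive <- .interleave_labels(spec$n_paths, spec$n_reactive)

  make_frame <- function(target, phase, r_outer) {
    co <- tmpl$coords + matrix(rnorm(3L * n_atoms(tmpl), sd = spec$jitter_sigma),
                               ncol = 3L)
    # planted signal: outer water on a sphere of exact radius r_outer about C
    dir <- .unit(.unit(tmpl$coords[outer_o, ]) + rnorm(3L, sd = 0.10))
    O_out <- co[i_C, ] + r_outer * dir
    b <- .unit(dir + rnorm(3L, sd = 0.30))
    pr <- rnorm(3L)
    p <- .unit(pr - sum(pr * b) * b)
    half <- .deg(g$HOH_half)
    co[outer_o, ] <- O_out
    co[outer_o + 1L, ] <- O_out + g$OH_water * (cos(half) * b + sin(half) * p)
    co[outer_o + 2L, ] <- O_out + g$OH_water * (cos(half) * b - sin(half) * p)
    # proton script
    if (phase == "bonded") {
      co[i_H, ] <- co[i_Ohyd, ] + target * h_dir_tmpl
    } else if (phase == "transfer") {
      co[i_H, ] <- co[w0_o, ] +
        g$OH_transfer * .unit(co[i_Ohyd, ] - co[w0_o, ])
    } else {                                   # hop
      co[i_H, ] <- co[hop_o, ] +
        g$OH_transfer * .unit(co[hop_o, ] - co[i_C, ])
    }
    co
  }

  records <- with_local_seed(spec$seed, {
    out <- vector("list", spec$n_paths)
    for (pidx in seq_len(spec$n_paths)) {
      reactive <- is_reactive[pidx]
      r_outer <- radii[nw] + if (reactive) -spec$planted_delta else spec$planted_delta
      targets <- if (reactive)
        c(0.97, s_window, 1.31)
      else
        c(0.97, s_window, 1.31, rev(s_window), 0.97)
      phases <- c(rep("bonded", length(targets)),
                  if (reactive) c("transfer", "hop"))
      targets <- c(targets, if (reactive) c(NA, NA))
      rot <- .random_rotation()
      shift <- rnorm(3L, sd = 2)
      frames <- vector("list", length(targets))
      for (k in seq_along(targets)) {
        co <- make_frame(targets[k], phases[k], r_outer)
        co <- co %*% t(rot) + matrix(shift, nrow(co), 3L, byrow = TRUE)
        frames[[k]] <- frame(tmpl$elements, co, time_index = k - 1L)
      }
      out[[pidx]] <- path_record(
        frames, if (reactive) "reactive" else "unreactive",
        sprintf("path%04d", pidx - 1L), generation_order = pidx - 1L)
    }
    out
  })
  if (!is.null(dir)) {
    manifest <- write_path_collection(records, dir)
    attr(records, "manifest") <- manifest
  }
  records
}
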