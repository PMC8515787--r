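#' Construct a trajectory frame
#'
#' A frame is one time step of a molecular trajectory: element symbols plus
#' Cartesian coordinates in Angstrom, with optional velocities. Velocities are
#' stored when present in the input but never enter the default feature set.
#'
#' @param elements character vector of chemical element symbols.
#' @param coords numeric M x 3 matrix of coordinates (Angstrom).
#' @param velocities optional numeric M x 3 matrix.
#' @param time_index integer ordinal of the frame within its trajectory.
#' @return An object of class `"frame"`.
#' @export
frame <- function(elements, coords, velocities = NULL, time_index = 0L) {
  elements <- as.character(elements)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (length(elements) < 1L)
    stop("a frame needs at least one atom")
  if (ncol(coords) != 3L || nrow(coords) != length(elements))
    stop("coords must be an M x 3 matrix with one row per element symbol")
  unknown <- setdiff(unique(elements), .known_elements)
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  if (!is.null(velocities)) {
    velocities <- as.matrix(velocities)
    storage.mode(velocities) <- "double"
    if (!identical(dim(velocities), dim(coords)))
      stop("velocities must match the dimensions of coords")
  }
  structure(
    list(elements = elements, coords = coords, velocities = velocities,
         time_index = as.integer(time_index)),
    class = "frame"
  )
}

#' @export
print.frame <- function(x, ...) {
  cat(sprintf("<frame> %d atoms (%s), time_index = %d\n",
              length(x$elements),
              paste(names(sort(table(x$elements), decreasing = TRUE)),
                    sort(table(x$elements), decreasing = TRUE),
                    sep = "", collapse = " "),
              x$time_index))
  invisible(x)
}

n_atoms <- function(fr) length(fr$elements)

#' Construct a labeled path record
#'
#' A path record is an ordered sequence of frames with a reactive/unreactive
#' label and provenance metadata. `generation_order` is the sampling-time
#' ordinal of the path, used downstream for block averaging.
#'
#' @param frames list of [frame()] objects sharing one element multiset.
#' @param label one of `"reactive"`, `"unreactive"`, `"unlabeled"`.
#' @param path_id character identifier.
#' @param generation_order integer ordinal.
#' @param weight positive statistical weight (default 1).
#' @return An object of class `"path_record"`.
#' @export
path_record <- function(frames, label, path_id,
                        generation_order = 0L, weight = 1) {
  label <- match.arg(label, c("reactive", "unreactive", "unlabeled"))
  if (!length(frames)) stop("a path record needs at least one frame")
  ms <- sort(frames[[1L]]$elements)
  for (fr in frames)
    if (!identical(sort(fr$elements), ms))
      stop("all frames in a path must share the same element multiset")
  if (weight <= 0) stop("weight must be positive")
  structure(
    list(frames = frames, label = label, path_id = as.character(path_id),
         generation_order = as.integer(generation_order),
         weight = as.numeric(weight)),
    class = "path_record"
  )
}

#' @export
print.path_record <- function(x, ...) {
  cat(sprintf("<path_record> '%s': %d frames, label = %s, generation_order = %d\n",
              x$path_id, length(x$frames), x$label, x$generation_order))
  invisible(x)
}

#' Read a multi-frame XYZ trajectory
#'
#' Parses the standard XYZ dialect: an atom-count line, a comment line, then
#' one `"El x y z"` record per atom, repeated per frame. Extra numeric columns
#' beyond the coordinates are stored as velocities.
#'
#' @param file path to an XYZ file.
#' @return A list of [frame()] objects with `time_index` 0..F-1 in file order.
#' @export
read_xyz <- function(file) {
  if (!file.exists(file)) stop("file not found: ", file)
  lines <- readLines(file, warn = FALSE)
  # drop trailing blank lines only
  while (length(lines) && !nzchar(trimws(lines[length(lines)])))
    lines <- lines[-length(lines)]
  frames <- list()
  i <- 1L
  fidx <- 0L
  while (i <= length(lines)) {
    m <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(m) || m < 1L)
      stop(sprintf("frame %d: invalid atom-count line %d ('%s')",
                   fidx, i, lines[i]))
    if (i + 1L + m > length(lines))
      stop(sprintf("frame %d: count line says %d atoms but file ends after %d atom line(s)",
                   fidx, m, length(lines) - i - 1L))
    atom_lines <- lines[(i + 2L):(i + 1L + m)]
    toks <- strsplit(trimws(atom_lines), "[[:space:]]+")
    nf <- lengths(toks)
    if (any(nf < 4L))
      stop(sprintf("frame %d: atom line with fewer than 4 fields", fidx))
    el <- vapply(toks, `[[`, "", 1L)
    unknown <- setdiff(unique(el), .known_elements)
    if (length(unknown))
      stop(sprintf("frame %d: unknown element symbol(s): %s",
                   fidx, paste(unknown, collapse = ", ")))
    num <- lapply(toks, function(t) suppressWarnings(as.numeric(t[-1L])))
    if (any(vapply(num, function(v) any(is.na(v[1:3])), TRUE)))
      stop(sprintf("frame %d: non-numeric coordinate field", fidx))
    xyz <- t(vapply(num, function(v) v[1:3], numeric(3L)))
    vel <- NULL
    if (all(nf >= 7L)) {
      vel <- t(vapply(num, function(v) v[4:6], numeric(3L)))
      if (any(is.na(vel))) vel <- NULL
    }
    frames[[fidx + 1L]] <- frame(el, xyz, velocities = vel, time_index = fidx)
    i <- i + 2L + m
    fidx <- fidx + 1L
  }
  if (!length(frames)) stop("no frames found in ", file)
  frames
}

#' Write frames to a multi-frame XYZ file
#'
#' Coordinates are written with six decimal places; the comment line carries
#' the frame's `time_index`. Dummy marker atoms (element `"X"`) are written
#' verbatim so visualization software can pick them up.
#'
#' @param frames a single [frame()] or a list of frames.
#' @param file destination path.
#' @return Invisibly, `file`.
#' @export
write_xyz <- function(frames, file) {
  if (inherits(frames, "frame")) frames <- list(frames)
  if (!length(frames)) stop("frames must be nonempty")
  out <- character(0L)
  for (fr in frames) {
    body <- sprintf("%-2s %14.6f %14.6f %14.6f", fr$elements,
                    fr$coords[, 1L], fr$coords[, 2L], fr$coords[, 3L])
    if (!is.null(fr$velocities))
      body <- paste(body, sprintf("%14.6f %14.6f %14.6f",
                                  fr$velocities[, 1L], fr$velocities[, 2L],
                                  fr$velocities[, 3L]))
    out <- c(out, as.character(n_atoms(fr)),
             sprintf("time_index=%d", fr$time_index), body)
  }
  con <- file(file, open = "wt")
  on.exit(close(con))
  writeLines(out, con)
  invisible(file)
}

#' Load a labeled path collection from a manifest
#'
#' The manifest is a header-bearing CSV with columns `path_id`, `xyz_file`,
#' `label`, `generation_order` and optionally `weight`. Relative `xyz_file`
#' paths are resolved against the manifest's directory. Row order (and
#' `generation_order`) is preserved exactly.
#'
#' @param manifest path to the manifest CSV.
#' @return A list of [path_record()] objects, one per row.
#' @export
load_path_collection <- function(manifest) {
  if (!file.exists(manifest)) stop("manifest not found: ", manifest)
  tab <- read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("path_id", "xyz_file", "label", "generation_order")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("manifest is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(tab$path_id))
    stop("duplicate path_id in manifest: ",
         paste(unique(tab$path_id[duplicated(tab$path_id)]), collapse = ", "))
  bad <- !tab$label %in% c("reactive", "unreactive", "unlabeled")
  if (any(bad))
    stop("manifest row(s) with invalid label: ",
         paste(sprintf("row %d ('%s')", which(bad), tab$label[bad]),
               collapse = ", "))
  if (!"weight" %in% names(tab)) tab$weight <- 1
  root <- dirname(normalizePath(manifest))
  records <- vector("list", nrow(tab))
  for (r in seq_len(nrow(tab))) {
    path <- tab$xyz_file[r]
    if (!file.exists(path)) path <- file.path(root, tab$xyz_file[r])
    if (!file.exists(path))
      stop(sprintf("manifest row %d ('%s'): xyz file not found: %s",
                   r, tab$path_id[r], tab$xyz_file[r]))
    records[[r]] <- path_record(read_xyz(path), tab$label[r], tab$path_id[r],
                                generation_order = tab$generation_order[r],
                                weight = tab$weight[r])
  }
  records
}

#' Write a manifest for a list of path records
#'
#' Writes one CSV row per record and each record's frames as an XYZ file
#' `<path_id>.xyz` in the same directory. Companion to
#' [load_path_collection()].
#'
#' @param records list of [path_record()] objects.
#' @param dir destination directory (created if absent).
#' @param manifest_name file name for the manifest CSV.
#' @return Invisibly, the manifest path.
#' @export
write_path_collection <- function(records, dir, manifest_name = "manifest.csv") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- data.frame(
    path_id = vapply(records, `[[`, "", "path_id"),
    xyz_file = paste0(vapply(records, `[[`, "", "path_id"), ".xyz"),
    label = vapply(records, `[[`, "", "label"),
    generation_order = vapply(records, `[[`, 0L, "generation_order"),
    weight = vapply(records, `[[`, 0, "weight")
  )
  for (i in seq_along(records))
    write_xyz(records[[i]]$frames, file.path(dir, tab$xyz_file[i]))
  manifest <- file.path(dir, manifest_name)
  write.csv(tab, manifest, row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
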