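#' Selection window near the initial state
#'
#' Training frames are drawn from a narrow order-parameter interval close to
#' the initial state, a few frames per trajectory, which limits the
#' correlation between samples while still capturing configurations that
#' precede the transition. Window location, width and the number of frames
#' per path are the three hyper-parameters of the whole approach. Defaults
#' follow the study conditions: 1.1 < s < 1.25 Angstrom, one frame per
#' trajectory. Boundaries are strict inequalities.
#'
#' @param lower lower bound of the window (Angstrom), default 1.1.
#' @param upper upper bound (Angstrom), default 1.25.
#' @param frames_per_path frames drawn per trajectory, default 1.
#' @param seed integer seed making the draw reproducible.
#' @return An object of class `"selection_window"`.
#' @export
selection_window <- function(lower = 1.1, upper = 1.25,
                             frames_per_path = 1L, seed = 1L) {
  if (!(lower < upper)) stop("need lower < upper")
  if (frames_per_path < 1L) stop("frames_per_path must be >= 1")
  structure(list(lower = lower, upper = upper,
                 frames_per_path = as.integer(frames_per_path),
                 seed = as.integer(seed)),
            class = "selection_window")
}

#' Select in-window frames from labeled paths
#'
#' For each path the frames with `lower < s < upper` are enumerated and
#' `frames_per_path` of them are drawn uniformly at random without
#' replacement (all of them if fewer are available). Paths with no in-window
#' frame contribute nothing. The draw is deterministic given the window's
#' seed and does not disturb the caller's RNG state.
#'
#' @param paths list of [path_record()] objects with labels.
#' @param cfg a [colvar_config()].
#' @param win a [selection_window()].
#' @return A data frame with columns `path_id`, `label`, `generation_order`,
#'   `frame_index` (into the path's frame list) and `s`, plus the selected
#'   frames themselves in attribute-free column `frame` (a list column).
#' @export
window_select <- function(paths, cfg, win) {
  rows <- with_local_seed(win$seed, {
    out <- list()
    for (p in paths) {
      s <- order_parameter_series(p$frames, cfg)
      cand <- which(s > win$lower & s < win$upper)
      if (!length(cand)) {
        message(sprintf("path '%s': no frame in the selection window", p$path_id))
        next
      }
      take <- if (length(cand) <= win$frames_per_path) cand
              else sort(sample(cand, win$frames_per_path))
      out[[length(out) + 1L]] <- data.frame(
        path_id = p$path_id, label = p$label,
        generation_order = p$generation_order,
        frame_index = take, s = s[take],
        stringsAsFactors = FALSE)
      out[[length(out)]]$frame <- p$frames[take]
    }
    out
  })
  if (!length(rows))
    stop("no path contributed any frame inside the selection window (",
         win$lower, ", ", win$upper, ")")
  do.call(rbind, rows)
}

#' Build the training dataset from selected frames
#'
#' Each selected frame is featurized with the index-invariant representation
#' and flattened; labels are 1 for frames from reactive paths and 0 for
#' unreactive. Rows are ordered by `generation_order` so that the
#' block-averaged error estimate downstream operates on sampling-time order.
#'
#' @param selected the data frame returned by [window_select()].
#' @param ref_rule reference-atom rule for [select_reference_atom()].
#' @param group_order optional element-group order.
#' @return An object of class `"rt_dataset"`: `features` (N x M^2 matrix),
#'   `labels` (integer 0/1), `path_ids`, `generation_orders`,
#'   `feature_labels` (length M^2), and `s` values.
#' @export
build_dataset <- function(selected, ref_rule = "C", group_order = NULL) {
  if (!nrow(selected)) stop("selection is empty")
  if (any(!selected$label %in% c("reactive", "unreactive")))
    stop("all selected paths must be labeled reactive or unreactive")
  selected <- selected[order(selected$generation_order), , drop = FALSE]
  m <- n_atoms(selected$frame[[1L]])
  feats <- matrix(NA_real_, nrow(selected), m * m)
  labs <- NULL
  for (i in seq_len(nrow(selected))) {
    fr <- selected$frame[[i]]
    if (n_atoms(fr) != m)
      stop("inconsistent atom counts across selected frames")
    fl <- flatten(featurize_frame(fr, ref_rule, group_order))
    feats[i, ] <- fl$features
    if (is.null(labs)) labs <- fl$labels
  }
  structure(
    list(features = feats,
         labels = as.integer(selected$label == "reactive"),
         path_ids = selected$path_id,
         generation_orders = selected$generation_order,
         feature_labels = labs,
         s = selected$s),
    class = "rt_dataset"
  )
}

#' @export
print.rt_dataset <- function(x, ...) {
  cat(sprintf("<rt_dataset> %d frames x %d features (%d reactive, %d unreactive)\n",
              nrow(x$features), ncol(x$features),
              sum(x$labels == 1L), sum(x$labels == 0L)))
  invisible(x)
}

#' Export a dataset as TSV
#'
#' Header row carries the rendered feature labels; a `label` column (0/1)
#' comes first, after `path_id` and `generation_order`.
#'
#' @param data an `"rt_dataset"`.
#' @param file destination path.
#' @param header_comment optional comment line written before the header.
#' @return Invisibly, `file`.
#' @export
write_dataset_tsv <- function(data, file, header_comment = NULL) {
  con <- file(file, "wt")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  writeLines(paste(c("path_id", "generation_order", "label",
                     data$feature_labels), collapse = "\t"), con)
  for (i in seq_len(nrow(data$features)))
    writeLines(paste(c(data$path_ids[i], data$generation_orders[i],
                       data$labels[i],
                       sprintf("%.9g", data$features[i, ])),
                     collapse = "\t"), con)
  invisible(file)
}
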