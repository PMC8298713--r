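#' Observation tables of tracked cells
#'
#' The universal input of the package is a table of cell detections with one
#' row per cell per frame and columns `t` (integer frame index), `x`, `y`,
#' `z` (positions in micrometres), `id` (integer cell label, consistent over
#' time) and `class` (0 = immune/searcher, 1 = target).  The frame interval
#' `frame_interval` (minutes per frame) is carried as metadata, not as a
#' column.  `observation_table()` validates a data frame and attaches the
#' class; `read_observations()` / `write_observations()` round-trip the
#' delimited-text representation.
#'
#' @param df data frame with columns `t, x, y, z, id, class`.
#' @param frame_interval time between consecutive frames (minutes); must be
#'   positive.
#' @param path file to read or write.
#' @param table an `observation_table`.
#' @param sep field separator (comma by default).
#' @return an object of class `observation_table` (a validated data frame
#'   with a `frame_interval` attribute).
#' @examples
#' df <- data.frame(t = c(0, 1, 0, 1), x = c(0, 1, 5, 5), y = 0, z = 0,
#'                  id = c(1, 1, 2, 2), class = c(0, 0, 1, 1))
#' obs <- observation_table(df, frame_interval = 1)
#' @export
observation_table <- function(df, frame_interval = 1) {
  req <- c("t", "x", "y", "z", "id", "class")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("observation table is missing column(s): ", paste(missing_cols, collapse = ", "))
  df <- as.data.frame(df)[req]
  for (cl in req) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[cl]]))))
    if (length(bad))
      stop(sprintf("non-numeric or non-finite value in column '%s' at row %d", cl, bad[1]))
    df[[cl]] <- as.numeric(df[[cl]])
  }
  if (any(df$t != round(df$t))) stop("frame index t must be integer-valued")
  if (any(df$id != round(df$id))) stop("cell id must be integer-valued")
  if (!all(df$class %in% c(0, 1)))
    stop("cell class must be 0 (immune) or 1 (target)")
  dup <- duplicated(df[c("t", "id")])
  if (any(dup)) {
    i <- which(dup)[1]
    stop(sprintf("duplicate observation of cell id %d at frame t=%d",
                 as.integer(df$id[i]), as.integer(df$t[i])))
  }
  cls_per_id <- tapply(df$class, df$id, function(v) length(unique(v)))
  if (any(cls_per_id > 1))
    stop("cell id ", names(cls_per_id)[which(cls_per_id > 1)[1]],
         " appears with more than one class label")
  if (!is.numeric(frame_interval) || length(frame_interval) != 1 || frame_interval <= 0)
    stop("frame_interval must be a single positive number")
  df <- df[order(df$id, df$t), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, frame_interval = frame_interval,
            class = c("observation_table", "data.frame"))
}

#' @rdname observation_table
#' @export
read_observations <- function(path, frame_interval = 1, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  observation_table(df, frame_interval = frame_interval)
}

#' @rdname observation_table
#' @export
write_observations <- function(table, path, sep = ",") {
  stopifnot(inherits(table, "observation_table"))
  utils::write.table(as.data.frame(table), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.observation_table <- function(x, ...) {
  if (!nrow(x)) {
    cat("<observation_table> 0 observations\n")
    return(invisible(x))
  }
  cat(sprintf("<observation_table> %d observations, %d cells (%d immune, %d target), frames %d..%d, frame interval %g\n",
              nrow(x), length(unique(x$id)),
              length(unique(x$id[x$class == 0])), length(unique(x$id[x$class == 1])),
              as.integer(min(x$t)), as.integer(max(x$t)),
              attr(x, "frame_interval")))
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("... (", nrow(x) - 6, " more rows)\n", sep = "")
  invisible(x)
}

#' Assemble per-cell trajectories
#'
#' Splits an observation table into one trajectory per cell id, sorted by
#' frame.  Tracking gaps (missing frames between the first and last
#' detection of a cell) are permitted and recorded.
#'
#' @param table an `observation_table`.
#' @return a list with one element per cell, each a list with fields
#'   `cell_id`, `cell_class`, `pos` (data frame `t, x, y, z`) and `gaps`
#'   (integer vector of missing frame indices).
#' @export
build_trajectories <- function(table) {
  stopifnot(inherits(table, "observation_table"))
  if (!nrow(table)) return(list())
  pieces <- split(as.data.frame(table), table$id)
  lapply(pieces, function(d) {
    d <- d[order(d$t), , drop = FALSE]
    full <- seq(min(d$t), max(d$t))
    list(cell_id = d$id[1], cell_class = d$class[1],
         pos = data.frame(t = d$t, x = d$x, y = d$y, z = d$z),
         gaps = setdiff(full, d$t))
  })
}

#' Extract movement triplets
#'
#' A triplet is the elementary analysis unit: three positions of one cell at
#' frames exactly `t - n`, `t`, `t + n`.  All phase offsets are used, so
#' triplets overlap; a gap-free track of `L` frames yields `max(0, L - 2n)`
#' triplets.  Frames lost to tracking gaps simply produce no triplet.
#' Triplets in which either step is shorter than `eps_step` have an undefined
#' heading and are dropped (their count is returned in the
#' `"dropped_degenerate"` attribute).
#'
#' @param x an `observation_table` (triplets for every cell of
#'   `cell_class`) or a single trajectory as returned by
#'   [build_trajectories()].
#' @param n sub-sampling factor: positive integer stride between the three
#'   frames, effectively enlarging the recording interval to `n` frames.
#' @param eps_step minimum step width in micrometres (default `1e-6`).
#' @param cell_class when `x` is a table, the class whose triplets are
#'   wanted (default 0, immune).
#' @return data frame with one row per triplet: `cell_id`, central frame
#'   `t`, stride `n`, previous/central/next in-plane positions
#'   (`px, py, cx, cy, nx, ny`) and the central 3-D z-coordinate `cz`.
#' @export
extract_triplets <- function(x, n = 1, eps_step = 1e-6, cell_class = 0) {
  stopifnot(n >= 1, n == round(n))
  if (inherits(x, "observation_table")) {
    trajs <- build_trajectories(x)
    trajs <- Filter(function(tr) tr$cell_class == cell_class, trajs)
  } else {
    trajs <- list(x)
  }
  out <- vector("list", length(trajs))
  dropped <- 0L
  for (i in seq_along(trajs)) {
    tr <- trajs[[i]]
    p <- tr$pos
    prev_idx <- match(p$t - n, p$t)
    next_idx <- match(p$t + n, p$t)
    ok <- !is.na(prev_idx) & !is.na(next_idx)
    if (!any(ok)) next
    j <- which(ok); jp <- prev_idx[j]; jn <- next_idx[j]
    d <- data.frame(cell_id = tr$cell_id, t = p$t[j], n = n,
                    px = p$x[jp], py = p$y[jp],
                    cx = p$x[j],  cy = p$y[j],
                    nx = p$x[jn], ny = p$y[jn],
                    cz = p$z[j])
    w_in <- sqrt((d$cx - d$px)^2 + (d$cy - d$py)^2)
    w_out <- sqrt((d$nx - d$cx)^2 + (d$ny - d$cy)^2)
    keep <- w_in > eps_step & w_out > eps_step
    dropped <- dropped + sum(!keep)
    out[[i]] <- d[keep, , drop = FALSE]
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(cell_id = numeric(0), t = numeric(0), n = numeric(0),
                      px = numeric(0), py = numeric(0), cx = numeric(0),
                      cy = numeric(0), nx = numeric(0), ny = numeric(0),
                      cz = numeric(0))
  rownames(res) <- NULL
  attr(res, "dropped_degenerate") <- dropped
  res
}

#' Exclude cells with too few triplets
#'
#' Cells contributing fewer than `n_tr_min` triplets are removed entirely:
#' their migration parameters cannot be estimated reliably.  Typical
#' thresholds range from 5 to 20.
#'
#' @param triplets data frame from [extract_triplets()].
#' @param n_tr_min minimum triplet count per cell (>= 1).
#' @return the filtered triplet data frame; excluded cell ids are recorded
#'   in the `"excluded_cells"` attribute.
#' @export
filter_min_triplets <- function(triplets, n_tr_min) {
  stopifnot(n_tr_min >= 1)
  if (!nrow(triplets)) {
    attr(triplets, "excluded_cells") <- numeric(0)
    return(triplets)
  }
  counts <- table(triplets$cell_id)
  bad <- as.numeric(names(counts)[counts < n_tr_min])
  out <- triplets[!(triplets$cell_id %in% bad), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped_degenerate") <- attr(triplets, "dropped_degenerate")
  attr(out, "excluded_cells") <- bad
  out
}

#' Pair triplets with nearby targets
#'
#' Joins each triplet with every cell of `target_class` observed at the
#' triplet's central frame and within a 3-D distance `r_max` of the central
#' immune position (a sphere in `"3d"` mode; in `"2d"` mode z is ignored and
#' the gate is a disk).  Pairing a class with itself is allowed (for, e.g.,
#' NK-NK analysis); a cell is never paired with its own triplet.  Targets
#' coinciding exactly with the immune position (in-plane) are dropped and
#' counted in the `"dropped_degenerate_pairs"` attribute.
#'
#' @param triplets data frame from [extract_triplets()].
#' @param table the `observation_table` providing target positions.
#' @param r_max maximum 3-D interaction distance in micrometres.
#' @param target_class class label of potential targets (default 1).
#' @param mode `"3d"` (default) or `"2d"` distance gating.
#' @param eps_step in-plane degeneracy threshold.
#' @return data frame with the triplet columns plus `target_id`, target
#'   position `tx, ty, tz` and 3-D distance `d`.
#' @export
pair_with_targets <- function(triplets, table, r_max, target_class = 1,
                              mode = c("3d", "2d"), eps_step = 1e-6) {
  mode <- match.arg(mode)
  stopifnot(r_max > 0, inherits(table, "observation_table"))
  tg <- as.data.frame(table)[table$class == target_class,
                             c("t", "x", "y", "z", "id"), drop = FALSE]
  names(tg) <- c("t", "tx", "ty", "tz", "target_id")
  empty <- cbind(triplets[0, , drop = FALSE],
                 data.frame(target_id = numeric(0), tx = numeric(0),
                            ty = numeric(0), tz = numeric(0), d = numeric(0)))
  if (!nrow(triplets) || !nrow(tg)) {
    attr(empty, "dropped_degenerate_pairs") <- 0L
    return(empty)
  }
  tg_by_t <- split(tg, tg$t)
  tr_by_t <- split(triplets, triplets$t)
  degen <- 0L
  out <- vector("list", length(tr_by_t))
  for (i in seq_along(tr_by_t)) {
    tri <- tr_by_t[[i]]
    tgt <- tg_by_t[[as.character(tri$t[1])]]
    if (is.null(tgt)) next
    comb <- merge(tri, tgt[-1], by = NULL)  # cartesian product at this frame
    comb$t <- tri$t[1]
    dz <- if (mode == "3d") comb$tz - comb$cz else 0
    comb$d <- sqrt((comb$tx - comb$cx)^2 + (comb$ty - comb$cy)^2 + dz^2)
    comb <- comb[comb$d <= r_max & comb$target_id != comb$cell_id, , drop = FALSE]
    plane <- sqrt((comb$tx - comb$cx)^2 + (comb$ty - comb$cy)^2)
    degen <- degen + sum(plane <= eps_step)
    out[[i]] <- comb[plane > eps_step, , drop = FALSE]
  }
  res <- do.call(rbind, out)
  if (is.null(res) || !nrow(res)) res <- empty
  rownames(res) <- NULL
  attr(res, "dropped_degenerate_pairs") <- degen
  attr(res, "mode") <- mode
  attr(res, "r_max") <- r_max
  res
}

# Length of the longest run of consecutive frames, per cell id.
longest_consecutive_run <- function(table) {
  pieces <- split(table$t, table$id)
  vapply(pieces, function(tt) {
    tt <- sort(tt)
    if (length(tt) == 1) return(1)
    r <- rle(diff(tt) == 1)
    m <- r$lengths[r$values]
    if (length(m)) max(m) + 1 else 1
  }, numeric(1))
}

#' Drop cells with short tracks
#'
#' Removes from the table all cells of a given class whose longest run of
#' consecutive frames is below `min_track_length` steps.  Used to mirror
#' experimental evaluations that require at least 20 consecutive entries.
#'
#' @param table an `observation_table`.
#' @param min_track_length minimum number of consecutive steps.
#' @param cell_class class to filter (default 0); other classes are kept.
#' @return the filtered `observation_table`.
#' @export
filter_min_track_length <- function(table, min_track_length, cell_class = 0) {
  if (min_track_length <= 1) return(table)
  runs <- longest_consecutive_run(table)
  bad <- as.numeric(names(runs)[runs - 1 < min_track_length])
  keep <- !(table$id %in% bad & table$class == cell_class)
  observation_table(as.data.frame(table)[keep, , drop = FALSE],
                    frame_interval = attr(table, "frame_interval"))
}
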