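#' Step widths and turning angles
#'
#' Elementary in-plane kinematics of a discrete random walk.
#' `step_width()` is the Euclidean x-y distance between consecutive
#' positions; `turning_angle()` is the signed angle (counter-clockwise
#' positive, in \eqn{(-\pi, \pi]}) between the shift vectors
#' `r_mid - r_prev` and `r_next - r_mid`, computed with the two-argument
#' arctangent of cross and dot products, which is stable for near-collinear
#' steps.  Both are vectorized over rows when given 2-column matrices.
#'
#' @param r_a,r_b,r_prev,r_mid,r_next 2-D positions: numeric vectors of
#'   length 2 or matrices with one position per row.
#' @param eps_step minimum step width; shorter shifts have an undefined
#'   heading and raise an error (they should be filtered upstream).
#' @return numeric vector of widths (micrometres) or angles (radians).
#' @examples
#' step_width(c(0, 0), c(3, 4))                      # 5
#' turning_angle(c(0, 0), c(1, 0), c(1, 1))          # +pi/2, a left turn
#' @export
step_width <- function(r_a, r_b) {
  a <- unname(rbind(r_a)); b <- unname(rbind(r_b))
  sqrt((b[, 1] - a[, 1])^2 + (b[, 2] - a[, 2])^2)
}

#' @rdname step_width
#' @export
turning_angle <- function(r_prev, r_mid, r_next, eps_step = 1e-6) {
  p <- unname(rbind(r_prev)); m <- unname(rbind(r_mid)); n <- unname(rbind(r_next))
  ux <- m[, 1] - p[, 1]; uy <- m[, 2] - p[, 2]
  vx <- n[, 1] - m[, 1]; vy <- n[, 2] - m[, 2]
  if (any(sqrt(ux^2 + uy^2) <= eps_step) || any(sqrt(vx^2 + vy^2) <= eps_step))
    stop("zero-length shift vector: turning angle undefined")
  atan2(ux * vy - uy * vx, ux * vx + uy * vy)
}

#' Fit the blind-migration null model per cell
#'
#' Estimates, for each cell of `cell_class`, the Rayleigh speed parameter
#' \eqn{\sigma_i} from its step widths and the von Mises persistence
#' parameter \eqn{\kappa_i} from its turning angles, at stride `n`.  Steps
#' are taken between frames exactly `n` apart (all phase offsets, skipping
#' tracking gaps), so that under sub-sampling the null model is re-estimated
#' at the effective recording interval and stays calibrated.
#'
#' @param table an `observation_table`.
#' @param n sub-sampling stride (frames), matching the stride used for
#'   triplet extraction.
#' @param cells optional vector of cell ids to fit (default: all of
#'   `cell_class`).
#' @param cell_class class to fit (default 0, immune).
#' @param kappa_max clamp for the persistence estimate.
#' @param eps_step degenerate-step threshold for turning angles.
#' @return data frame `cell_id, sigma, kappa, n_steps, n_angles`, one row
#'   per fitted cell; cells with no usable steps are omitted.
#' @export
fit_migration <- function(table, n = 1, cells = NULL, cell_class = 0,
                          kappa_max = 100, eps_step = 1e-6) {
  stopifnot(inherits(table, "observation_table"))
  trajs <- build_trajectories(table)
  trajs <- Filter(function(tr) tr$cell_class == cell_class, trajs)
  if (!is.null(cells)) trajs <- Filter(function(tr) tr$cell_id %in% cells, trajs)
  rows <- lapply(trajs, function(tr) {
    p <- tr$pos
    nxt <- match(p$t + n, p$t)
    ok <- !is.na(nxt)
    if (!any(ok)) return(NULL)
    j <- which(ok); jn <- nxt[j]
    w <- sqrt((p$x[jn] - p$x[j])^2 + (p$y[jn] - p$y[j])^2)
    # angles need t-n, t, t+n; reuse the step list: consecutive usable steps
    prv <- match(p$t - n, p$t)
    ja <- which(ok & !is.na(prv))
    theta <- numeric(0)
    if (length(ja)) {
      jp <- prv[ja]; jnn <- nxt[ja]
      ux <- p$x[ja] - p$x[jp]; uy <- p$y[ja] - p$y[jp]
      vx <- p$x[jnn] - p$x[ja]; vy <- p$y[jnn] - p$y[ja]
      good <- sqrt(ux^2 + uy^2) > eps_step & sqrt(vx^2 + vy^2) > eps_step
      theta <- atan2(ux[good] * vy[good] - uy[good] * vx[good],
                     ux[good] * vx[good] + uy[good] * vy[good])
    }
    w_pos <- w[w > 0]
    if (!length(w_pos)) return(NULL)
    data.frame(cell_id = tr$cell_id,
               sigma = estimate_sigma(w_pos),
               kappa = if (length(theta)) estimate_kappa(theta, kappa_max) else NA_real_,
               n_steps = length(w_pos), n_angles = length(theta))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(cell_id = numeric(0), sigma = numeric(0),
                      kappa = numeric(0), n_steps = numeric(0),
                      n_angles = numeric(0))
  rownames(out) <- NULL
  out
}

#' Write / read fitted migration parameters
#'
#' Delimited-text export of per-cell `(sigma, kappa)` fits with header
#' `id,sigma,kappa,n_steps`.
#'
#' @param params data frame from [fit_migration()].
#' @param path file path.
#' @return `write_migration_params()` returns the path invisibly.
#' @export
write_migration_params <- function(params, path) {
  out <- data.frame(id = params$cell_id, sigma = params$sigma,
                    kappa = params$kappa, n_steps = params$n_steps)
  utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Momentary persistence and speed
#'
#' Computes, for every interior point of every sufficiently long track of
#' `cell_class`, the momentary speed `v = w / dt` (step width from one frame
#' to the next divided by the frame interval, micrometres per minute) and
#' the cosine of the turning angle, a simple persistence measure in
#' \eqn{[-1, 1]}: \eqn{-1} back-and-forth wiggling, 0 non-directional,
#' \eqn{+1} straight motion.  Cells whose longest run of consecutive frames
#' is shorter than `min_track_length` steps are excluded.  The joint
#' distribution of these pairs characterizes the available movement
#' repertoire of a cell population; chemotaxis is a higher-order correlation
#' invisible in this marginal.
#'
#' @param table an `observation_table`.
#' @param min_track_length minimum consecutive track length in steps
#'   (default 20).
#' @param cell_class class to evaluate (default 0).
#' @param eps_step degenerate-step threshold.
#' @return data frame `cell_id, t, v, cos_theta` (speed uses the step
#'   leaving frame `t`; `cos_theta` the turn at frame `t`).
#' @export
momentary_steps <- function(table, min_track_length = 20, cell_class = 0,
                            eps_step = 1e-6) {
  stopifnot(inherits(table, "observation_table"))
  dt <- attr(table, "frame_interval")
  tab <- filter_min_track_length(table, min_track_length, cell_class)
  tri <- extract_triplets(tab, n = 1, eps_step = eps_step, cell_class = cell_class)
  if (!nrow(tri))
    return(data.frame(cell_id = numeric(0), t = numeric(0),
                      v = numeric(0), cos_theta = numeric(0)))
  ux <- tri$cx - tri$px; uy <- tri$cy - tri$py
  vx <- tri$nx - tri$cx; vy <- tri$ny - tri$cy
  theta <- atan2(ux * vy - uy * vx, ux * vx + uy * vy)
  data.frame(cell_id = tri$cell_id, t = tri$t,
             v = sqrt(vx^2 + vy^2) / dt, cos_theta = cos(theta))
}

#' Kernel-density plot of the momentary (persistence, speed) distribution
#'
#' Convenience ggplot of the joint density of `cos_theta` and `v` from
#' [momentary_steps()], using a Gaussian product kernel with rule-of-thumb
#' bandwidth.  Visualization only; no quantitative claims attach to it.
#'
#' @param steps data frame from [momentary_steps()].
#' @param gridsize kernel grid resolution.
#' @return a ggplot object.
#' @export
plot_momentary_density <- function(steps, gridsize = 101) {
  if (!requireNamespace("ggplot2", quietly = TRUE) ||
      !requireNamespace("MASS", quietly = TRUE))
    stop("plot_momentary_density() needs the 'ggplot2' and 'MASS' packages")
  kd <- MASS::kde2d(steps$cos_theta, steps$v, n = gridsize,
                    lims = c(-1, 1, 0, max(steps$v)))
  grid <- expand.grid(cos_theta = kd$x, v = kd$y)
  grid$density <- as.vector(kd$z)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$cos_theta, y = .data$v,
                                     fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = expression(cos(theta)), y = "speed v (µm/min)",
                  fill = "density")
}
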