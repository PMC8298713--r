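#' Configure a chemotaxis simulation scenario
#'
#' Four agent-based scenarios of immune cells hunting immobile targets on a
#' square field:
#' \describe{
#'   \item{BLS}{Blind search: a correlated random walk with per-cell,
#'     temporally constant parameters (\eqn{\sigma_i} log-uniform in
#'     `sigma_range`, \eqn{\kappa_i} uniform in `kappa_range`); no
#'     target interaction.}
#'   \item{RMS}{Random mode switching: still target-blind, but each cell
#'     occasionally (probability `p_switch` per step) toggles between a
#'     fast persistent mode (`sigma_fast`, `kappa_high`) and a slow
#'     diffusive mode (`sigma_slow`, `kappa_low`).}
#'   \item{TGS}{Temporal gradient sensing (run-and-tumble): a cell keeps the
#'     fast persistent mode while the chemoattractant concentration at its
#'     position increases over time, and tumbles (slow diffusive mode) when
#'     it decreases.}
#'   \item{SGS}{Spatial gradient sensing: per-cell parameters as in BLS, but
#'     the mean turning direction is biased towards the chemoattractant
#'     gradient: the von Mises center is the angle of
#'     \eqn{\hat u + c\,\nabla C / C} (relative, Weber-law gradient sensing,
#'     so the response coefficient is length-scale free) relative to the
#'     current heading \eqn{\hat u}.  `c_coeff = 0` reduces exactly to BLS;
#'     negative values produce repulsion.}
#' }
#' Targets emit a quasi-stationary point-source field
#' \eqn{C(r) = \sum_j 1/(d_j + r_0)}; targets within `r_kill` of an immune
#' cell are killed and disappear from that frame onward.  Boundaries
#' reflect.
#'
#' @param scenario one of `"BLS"`, `"RMS"`, `"TGS"`, `"SGS"`.
#' @param field_size side length of the square field (micrometres).
#' @param n_immune,n_targets initial cell counts.
#' @param n_steps number of time steps after the initial frame.
#' @param dt frame interval in minutes.
#' @param c_coeff chemotaxis response coefficient `c` (SGS; positive
#'   attractive, negative repulsive; default 500 for SGS, else 0).
#' @param sigma_slow,sigma_fast,kappa_low,kappa_high mode parameters
#'   (micrometres per step; dimensionless).
#' @param p_switch RMS mode-switching probability per step.
#' @param r_kill killing radius (micrometres).
#' @param r0 softening length of the concentration field (micrometres).
#' @param sigma_range,kappa_range per-cell parameter ranges for BLS/SGS.
#' @param seed optional RNG seed for a self-contained reproducible run.
#' @return a list of class `scenario_config`.
#' @export
scenario_config <- function(scenario = c("BLS", "RMS", "TGS", "SGS"),
                            field_size = 5000, n_immune = 100, n_targets = 50,
                            n_steps = 500, dt = 1, c_coeff = NULL,
                            sigma_slow = 1, sigma_fast = 5,
                            kappa_low = 0, kappa_high = 5,
                            p_switch = 0.05, r_kill = 20, r0 = 10,
                            sigma_range = c(1, 5), kappa_range = c(0, 5),
                            seed = NULL) {
  scenario <- match.arg(scenario)
  if (is.null(c_coeff)) c_coeff <- if (scenario == "SGS") 500 else 0
  stopifnot(field_size > 0, n_immune >= 1, n_targets >= 0, n_steps >= 0,
            dt > 0, r_kill >= 0, r0 > 0, p_switch >= 0, p_switch <= 1)
  structure(list(scenario = scenario, field_size = field_size,
                 n_immune = n_immune, n_targets = n_targets,
                 n_steps = n_steps, dt = dt, c = c_coeff,
                 sigma_slow = sigma_slow, sigma_fast = sigma_fast,
                 kappa_low = kappa_low, kappa_high = kappa_high,
                 p_switch = p_switch, r_kill = r_kill, r0 = r0,
                 sigma_range = sigma_range, kappa_range = kappa_range,
                 seed = seed),
            class = "scenario_config")
}

#' Chemoattractant concentration and gradient
#'
#' Each surviving target is a point source with a softened inverse-distance
#' profile: \eqn{C(\mathbf r) = \sum_j 1/(d_j + r_0)} with
#' \eqn{d_j = |\mathbf r - \mathbf r_j|}, and analytic gradient
#' \eqn{\nabla C = \sum_j -(d_j + r_0)^{-2}\, (\mathbf r - \mathbf r_j)/d_j},
#' which points towards each target.  With no targets, both are zero.
#'
#' @param targets matrix of target positions (rows `x, y`), possibly empty.
#' @param pos matrix of evaluation positions (rows `x, y`).
#' @param r0 softening length (micrometres).
#' @return list with `C` (numeric vector) and `grad` (2-column matrix).
#' @export
concentration_and_gradient <- function(targets, pos, r0 = 10) {
  pos <- rbind(pos)
  npos <- nrow(pos)
  if (is.null(targets) || !NROW(targets))
    return(list(C = numeric(npos), grad = matrix(0, npos, 2)))
  targets <- rbind(targets)
  dx <- outer(pos[, 1], targets[, 1], "-")
  dy <- outer(pos[, 2], targets[, 2], "-")
  d <- sqrt(dx^2 + dy^2)
  C <- rowSums(1 / (d + r0))
  f <- -1 / ((d + r0)^2 * pmax(d, 1e-12))   # gradient magnitude / d
  list(C = C, grad = cbind(rowSums(f * dx), rowSums(f * dy)))
}

# Advance the simulation by one step.  state: list with immune (matrix pos),
# heading, sigma, kappa (current per-cell), mode, C_prev, targets (matrix),
# alive (logical), t.
sim_step <- function(state, config) {
  ns <- state
  n <- config$n_immune
  live_targets <- ns$targets[ns$alive, , drop = FALSE]

  sigma <- ns$sigma; kappa <- ns$kappa; center <- numeric(n)
  if (config$scenario == "RMS") {
    flip <- stats::runif(n) < config$p_switch
    ns$mode[flip] <- !ns$mode[flip]
    sigma <- ifelse(ns$mode, config$sigma_fast, config$sigma_slow)
    kappa <- ifelse(ns$mode, config$kappa_high, config$kappa_low)
  } else if (config$scenario == "TGS") {
    cg <- concentration_and_gradient(live_targets, ns$immune, config$r0)
    up <- is.na(ns$C_prev) | cg$C >= ns$C_prev
    ns$C_prev <- cg$C
    ns$mode <- up
    sigma <- ifelse(up, config$sigma_fast, config$sigma_slow)
    kappa <- ifelse(up, config$kappa_high, config$kappa_low)
  } else if (config$scenario == "SGS") {
    cg <- concentration_and_gradient(live_targets, ns$immune, config$r0)
    # relative (Weber-law) gradient: cells respond to grad(log C), so the
    # response coefficient c is length-scale free
    rel <- cg$grad / pmax(cg$C, .Machine$double.xmin)
    bx <- cos(ns$heading) + config$c * rel[, 1]
    by <- sin(ns$heading) + config$c * rel[, 2]
    nonzero <- bx != 0 | by != 0
    center[nonzero] <- wrap_angle(atan2(by[nonzero], bx[nonzero]) -
                                    ns$heading[nonzero])
  }

  theta <- rvonmises(n, kappa, mu = center)
  w <- sigma * sqrt(-2 * log(stats::runif(n)))
  h <- ns$heading + theta
  px <- ns$immune[, 1] + w * cos(h)
  py <- ns$immune[, 2] + w * sin(h)

  # reflecting boundaries, heading mirrored accordingly
  L <- config$field_size
  repeat {
    out_lo <- px < 0; out_hi <- px > L
    if (!any(out_lo | out_hi)) break
    px[out_lo] <- -px[out_lo]; px[out_hi] <- 2 * L - px[out_hi]
    h[out_lo | out_hi] <- pi - h[out_lo | out_hi]
  }
  repeat {
    out_lo <- py < 0; out_hi <- py > L
    if (!any(out_lo | out_hi)) break
    py[out_lo] <- -py[out_lo]; py[out_hi] <- 2 * L - py[out_hi]
    h[out_lo | out_hi] <- -h[out_lo | out_hi]
  }
  ns$immune <- cbind(px, py)
  ns$heading <- wrap_angle(h)

  # killing: targets within r_kill of any immune cell die this frame
  if (any(ns$alive) && config$r_kill > 0) {
    alive_idx <- which(ns$alive)
    tp <- ns$targets[alive_idx, , drop = FALSE]
    dmin <- apply(sqrt(outer(tp[, 1], px, "-")^2 + outer(tp[, 2], py, "-")^2),
                  1, min)
    ns$alive[alive_idx[dmin <= config$r_kill]] <- FALSE
  }
  ns$t <- ns$t + 1L
  ns
}

#' Simulate a scenario
#'
#' Runs the configured scenario and returns an [observation_table()] with
#' class 0 for immune cells (ids `1..n_immune`) and class 1 for targets
#' (ids `n_immune + 1, ...`), targets present only while alive, z = 0
#' throughout, frames `0..n_steps`.  Deterministic given the seed.
#'
#' @param config a `scenario_config`, or a scenario name passed on to
#'   [scenario_config()] together with `...`.
#' @param ... further arguments for [scenario_config()].
#' @param seed RNG seed (overrides the one stored in `config`).
#' @return an `observation_table` with the generating `scenario_config`
#'   attached as attribute `"config"`.
#' @export
simulate_scenario <- function(config, ..., seed = NULL) {
  if (!inherits(config, "scenario_config"))
    config <- scenario_config(config, ...)
  if (!is.null(seed)) config$seed <- seed
  if (!is.null(config$seed)) set.seed(config$seed)

  n <- config$n_immune; m <- config$n_targets; L <- config$field_size
  state <- list(
    immune = cbind(stats::runif(n, 0, L), stats::runif(n, 0, L)),
    heading = stats::runif(n, -pi, pi),
    targets = cbind(stats::runif(m, 0, L), stats::runif(m, 0, L)),
    alive = rep(TRUE, m),
    mode = rep(TRUE, n),
    C_prev = rep(NA_real_, n),
    t = 0L)
  if (config$scenario %in% c("BLS", "SGS")) {
    state$sigma <- exp(stats::runif(n, log(config$sigma_range[1]),
                                    log(config$sigma_range[2])))
    state$kappa <- stats::runif(n, config$kappa_range[1], config$kappa_range[2])
  } else {
    state$mode <- if (config$scenario == "RMS")
      stats::runif(n) < 0.5 else rep(TRUE, n)
    state$sigma <- ifelse(state$mode, config$sigma_fast, config$sigma_slow)
    state$kappa <- ifelse(state$mode, config$kappa_high, config$kappa_low)
  }
  # initial kill: targets spawning on top of an immune cell
  if (m > 0 && config$r_kill > 0) {
    dmin <- apply(sqrt(outer(state$targets[, 1], state$immune[, 1], "-")^2 +
                         outer(state$targets[, 2], state$immune[, 2], "-")^2),
                  1, min)
    state$alive[dmin <= config$r_kill] <- FALSE
  }

  frames <- vector("list", config$n_steps + 1L)
  record <- function(st) {
    alive_idx <- which(st$alive)
    data.frame(
      t = st$t,
      x = c(st$immune[, 1], st$targets[alive_idx, 1]),
      y = c(st$immune[, 2], st$targets[alive_idx, 2]),
      z = 0,
      id = c(seq_len(n), n + alive_idx),
      class = c(rep(0, n), rep(1, length(alive_idx))))
  }
  frames[[1]] <- record(state)
  for (s in seq_len(config$n_steps)) {
    state <- sim_step(state, config)
    frames[[s + 1L]] <- record(state)
  }
  tab <- observation_table(do.call(rbind, frames), frame_interval = config$dt)
  attr(tab, "config") <- config
  attr(tab, "true_params") <- data.frame(cell_id = seq_len(n),
                                         sigma = state$sigma,
                                         kappa = state$kappa)
  tab
}
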