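#' Randomize target positions within the interaction radius
#'
#' Builds a reference (null) data set: the immune triplets are left
#' bit-exactly unchanged while every paired target is moved to an
#' independent uniformly random position inside the interaction range
#' around the triplet's central immune position — a ball of radius `r_max`
#' in `"3d"` mode, a disk in `"2d"` mode.  Sampling is uniform in space
#' (not in radius).  The randomization is applied independently per
#' (triplet, target) pair, so the reference p-value sample has exactly the
#' same size as the observed one.
#'
#' @param pairs data frame from [pair_with_targets()].
#' @param r_max interaction radius in micrometres.
#' @param mode `"3d"` or `"2d"`; defaults to the mode recorded on `pairs`.
#' @param eps_step in-plane degeneracy threshold; draws projecting onto the
#'   immune position are redrawn.
#' @return `pairs` with `tx, ty, tz, d` replaced by randomized values and
#'   any stale geometry columns removed.
#' @export
randomize_targets <- function(pairs, r_max = attr(pairs, "r_max"),
                              mode = attr(pairs, "mode"), eps_step = 1e-6) {
  if (is.null(mode)) mode <- "3d"
  stopifnot(r_max > 0, mode %in% c("3d", "2d"))
  m <- nrow(pairs)
  if (!m) return(pairs)
  ox <- oy <- oz <- numeric(m)
  todo <- seq_len(m)
  while (length(todo)) {
    k <- length(todo)
    if (mode == "3d") {
      g1 <- stats::rnorm(k); g2 <- stats::rnorm(k); g3 <- stats::rnorm(k)
      nrm <- sqrt(g1^2 + g2^2 + g3^2)
      r <- r_max * stats::runif(k)^(1 / 3)
      ox[todo] <- r * g1 / nrm; oy[todo] <- r * g2 / nrm; oz[todo] <- r * g3 / nrm
    } else {
      phi <- stats::runif(k, -pi, pi)
      r <- r_max * sqrt(stats::runif(k))
      ox[todo] <- r * cos(phi); oy[todo] <- r * sin(phi); oz[todo] <- 0
    }
    todo <- todo[sqrt(ox[todo]^2 + oy[todo]^2) <= eps_step]
  }
  pairs$tx <- pairs$cx + ox
  pairs$ty <- pairs$cy + oy
  pairs$tz <- pairs$cz + oz
  pairs$d <- sqrt(ox^2 + oy^2 + oz^2)
  pairs$theta_star <- pairs$delta_theta <- pairs$theta_actual <- NULL
  pairs
}

#' Histogram of pooled p-values
#'
#' Bins p-values into `K` uniform bins on `[0, 1]` and returns per-bin
#' probabilities (summing to 1).  Bins are half-open `[a, b)` except the
#' last, which is closed, so `p = 0.5` with `K = 2` falls in the upper bin.
#'
#' @param p p-values in `[0, 1]` (or a data frame with a `p` column).
#' @param K number of bins (>= 2).
#' @return numeric vector of length `K` with attributes `edges` (length
#'   `K + 1`) and `n` (sample size).
#' @export
pvalue_histogram <- function(p, K) {
  if (is.data.frame(p)) p <- p$p
  stopifnot(K >= 2, K == round(K))
  if (!length(p)) stop("cannot histogram an empty p-value set")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  edges <- seq(0, 1, length.out = K + 1)
  bin <- findInterval(p, edges, rightmost.closed = TRUE)
  q <- tabulate(bin, nbins = K) / length(p)
  structure(q, edges = edges, n = length(p))
}

#' Reference confidence band for the p-value histogram
#'
#' Generates `N_s` independent target-randomized reference data sets,
#' computes the p-value histogram of each (with the same sample size as the
#' observed set), and summarizes them by per-bin mean \eqn{\mu_k}, standard
#' deviation \eqn{\sigma_k}, and confidence limits
#' \eqn{\mu_k \mp z\,\sigma_k}.  With the default `z = 1.645` and under a
#' normal approximation, a reference bin value falls above the upper (or
#' below the lower) limit with probability 0.05; `z = 2.325` corresponds to
#' a 0.01 level (see [significance_to_z()]).
#'
#' @param pairs observed pairs from [pair_with_targets()].
#' @param params per-cell fits from [fit_migration()].
#' @param K number of histogram bins.
#' @param N_s number of reference replicates (paper-scale default 100).
#' @param z band half-width in reference standard deviations.
#' @param r_max,mode randomization range and geometry, defaulting to the
#'   values recorded on `pairs`.
#' @param q_obs optional observed per-bin probabilities to attach.
#' @return an object of class `banded_histogram`: a data frame
#'   `bin_lo, bin_hi, q_obs, mu_ref, sd_ref, lo, hi` with attributes `z`,
#'   `N_s`, `n` (sample size per replicate).
#' @export
reference_band <- function(pairs, params, K = 10, N_s = 100, z = 1.645,
                           r_max = attr(pairs, "r_max"),
                           mode = attr(pairs, "mode"), q_obs = NULL) {
  stopifnot(N_s >= 2)
  reps <- matrix(NA_real_, N_s, K)
  for (s in seq_len(N_s)) {
    ref <- randomize_targets(pairs, r_max = r_max, mode = mode)
    reps[s, ] <- pvalue_histogram(pooled_pvalues(ref, params)$p, K)
  }
  mu <- colMeans(reps)
  sd_k <- apply(reps, 2, stats::sd)
  edges <- seq(0, 1, length.out = K + 1)
  out <- data.frame(bin_lo = edges[-(K + 1)], bin_hi = edges[-1],
                    q_obs = if (is.null(q_obs)) NA_real_ else as.numeric(q_obs),
                    mu_ref = mu, sd_ref = sd_k,
                    lo = mu - z * sd_k, hi = mu + z * sd_k)
  structure(out, z = z, N_s = N_s, n = nrow(pairs),
            class = c("banded_histogram", "data.frame"))
}

#' Classify the interaction from histogram and band
#'
#' Applies the decision rule to the lowest-p bin: the interaction is
#' `"attractive"` if its observed probability exceeds the upper band limit
#' (excess of small p-values), `"repulsive"` if it falls below the lower
#' limit, and `"none"` otherwise.  All out-of-band bins are reported so
#' users can apply their own multiplicity handling; none is applied here.
#'
#' @param q_obs observed per-bin probabilities from [pvalue_histogram()],
#'   or `NULL` to use the `q_obs` column of `band`.
#' @param band a `banded_histogram` from [reference_band()].
#' @return an object of class `interaction_verdict`: a list with fields
#'   `classification` (one of `"attractive"`, `"repulsive"`, `"none"`) and
#'   `excursions` (data frame `bin, direction, q_obs, limit`).
#' @export
classify_interaction <- function(q_obs, band) {
  stopifnot(inherits(band, "banded_histogram"))
  if (is.null(q_obs)) q_obs <- band$q_obs
  if (length(q_obs) != nrow(band))
    stop("observed histogram and band have different numbers of bins")
  if (anyNA(q_obs)) stop("observed histogram contains missing values")
  above <- q_obs > band$hi
  below <- q_obs < band$lo
  exc <- rbind(
    data.frame(bin = which(above), direction = rep("above", sum(above)),
               q_obs = q_obs[above], limit = band$hi[above]),
    data.frame(bin = which(below), direction = rep("below", sum(below)),
               q_obs = q_obs[below], limit = band$lo[below]))
  exc <- exc[order(exc$bin), , drop = FALSE]
  rownames(exc) <- NULL
  classification <- if (above[1]) "attractive" else if (below[1]) "repulsive" else "none"
  structure(list(classification = classification, excursions = exc),
            class = "interaction_verdict")
}

#' @export
print.interaction_verdict <- function(x, ...) {
  cat("Interaction verdict:", x$classification, "\n")
  if (nrow(x$excursions)) {
    cat("Out-of-band bins:\n")
    print(x$excursions, row.names = FALSE)
  } else {
    cat("All bins inside the reference confidence band.\n")
  }
  invisible(x)
}

#' Export a banded histogram
#'
#' Writes the band as delimited text with header
#' `bin_lo,bin_hi,q_obs,mu_ref,sd_ref,lo,hi`, optionally with a JSON
#' verdict file alongside.
#'
#' @param band a `banded_histogram`.
#' @param path output file.
#' @param verdict optional `interaction_verdict` written as `<path>.json`.
#' @return the path, invisibly.
#' @export
write_band <- function(band, path, verdict = NULL) {
  utils::write.table(as.data.frame(band), path, sep = ",",
                     row.names = FALSE, quote = FALSE)
  if (!is.null(verdict))
    jsonlite::write_json(
      list(classification = verdict$classification,
           excursions = verdict$excursions),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
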