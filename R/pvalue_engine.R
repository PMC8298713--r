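#' Approach-cone geometry of a triplet-target pair
#'
#' For each pair, computes the geometry of Fig.-style approach cones:
#' `theta_star`, the optimal turning angle that would align the cell exactly
#' with the target (the angle of the optimal shift vector
#' `s_opt = r_target - r_center` relative to the incoming direction
#' `r_center - r_prev`, signed, in \eqn{(-\pi, \pi]}); `delta_theta`, the
#' unsigned angle in \eqn{[0, \pi]} between the realized outgoing step
#' `s1 = r_next - r_center` and `s_opt`; and `theta_actual`, the realized
#' turning angle.  The approach cone
#' \eqn{[\theta^\star - \Delta\theta,\ \theta^\star + \Delta\theta]} is the
#' set of turning angles at least as target-oriented as the observed step.
#'
#' @param pairs data frame from [pair_with_targets()] (or any frame with the
#'   triplet position columns plus `tx, ty`).
#' @return `pairs` with columns `theta_star`, `delta_theta`, `theta_actual`
#'   appended.
#' @export
approach_geometry <- function(pairs) {
  ux <- pairs$cx - pairs$px; uy <- pairs$cy - pairs$py      # incoming direction
  sx <- pairs$nx - pairs$cx; sy <- pairs$ny - pairs$cy      # realized step s1
  ox <- pairs$tx - pairs$cx; oy <- pairs$ty - pairs$cy      # optimal shift s_opt
  if (any(sqrt(ox^2 + oy^2) == 0))
    stop("target coincides with immune position: degenerate pair")
  pairs$theta_star <- atan2(ux * oy - uy * ox, ux * ox + uy * oy)
  pairs$delta_theta <- atan2(abs(sx * oy - sy * ox), sx * ox + sy * oy)
  pairs$theta_actual <- atan2(ux * sy - uy * sx, ux * sx + uy * sy)
  pairs
}

#' Blind-migration p-value of a single step
#'
#' The probability that a target-blind cell with von Mises turning-angle
#' concentration `kappa` makes a move at least as target-directed as the
#' observed one: the integral of the turning-angle density over the approach
#' cone,
#' \deqn{\hat p = \int_{\theta^\star - \Delta\theta}
#'       ^{\theta^\star + \Delta\theta} p(\theta)\, d\theta.}
#' Small \eqn{\hat p} values indicate attraction towards the target, large
#' values repulsion.  When the cone covers the full circle
#' (\eqn{\Delta\theta = \pi}) the value is exactly 1; for \eqn{\kappa = 0}
#' it reduces to \eqn{\Delta\theta / \pi}.
#'
#' @param kappa von Mises concentration (scalar, >= 0).
#' @param theta_star optimal turning angle(s), radians.
#' @param delta_theta approach-cone half-width(s), in `[0, pi]`.
#' @return p-values in `[0, 1]`, vectorized over the angles.
#' @export
pvalue_blind <- function(kappa, theta_star, delta_theta) {
  stopifnot(all(delta_theta >= 0), all(delta_theta <= pi + 1e-12))
  vonmises_arc_mass(kappa, theta_star - delta_theta, theta_star + delta_theta)
}

#' Pool p-values over all triplet-target pairs
#'
#' Computes one p-value per pair using the focal cell's own fitted
#' persistence parameter \eqn{\kappa_i}.  Pairs whose cell has no fitted
#' parameters raise an error: filtering must be consistent upstream.
#'
#' @param pairs data frame from [pair_with_targets()]; approach geometry is
#'   computed on the fly if absent.
#' @param params per-cell fits from [fit_migration()].
#' @return data frame `cell_id, target_id, t, p, kappa, distance` with one
#'   row per pair, carrying a `"provenance"` attribute describing the
#'   gating parameters.
#' @export
pooled_pvalues <- function(pairs, params) {
  if (!nrow(pairs))
    return(data.frame(cell_id = numeric(0), target_id = numeric(0),
                      t = numeric(0), p = numeric(0), kappa = numeric(0),
                      distance = numeric(0)))
  if (is.null(pairs$theta_star)) pairs <- approach_geometry(pairs)
  kmap <- params$kappa[match(pairs$cell_id, params$cell_id)]
  if (anyNA(kmap)) {
    miss <- unique(pairs$cell_id[is.na(kmap)])
    stop("no fitted migration parameters for cell id(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  p <- numeric(nrow(pairs))
  for (k in unique(kmap)) {          # one Fourier coefficient set per cell
    idx <- which(kmap == k)
    p[idx] <- pvalue_blind(k, pairs$theta_star[idx], pairs$delta_theta[idx])
  }
  out <- data.frame(cell_id = pairs$cell_id, target_id = pairs$target_id,
                    t = pairs$t, p = p, kappa = kmap, distance = pairs$d)
  attr(out, "provenance") <- list(r_max = attr(pairs, "r_max"),
                                  mode = attr(pairs, "mode"),
                                  n = if (nrow(pairs)) pairs$n[1] else NA)
  out
}

#' Export a p-value set
#'
#' Writes the pooled p-values as delimited text with header
#' `cell_id,target_id,t,p,kappa,distance`, and (optionally) a JSON
#' provenance block with all analysis parameters next to it.
#'
#' @param pvals data frame from [pooled_pvalues()].
#' @param path output file.
#' @param provenance optional list written as `<path>.json`.
#' @return the path, invisibly.
#' @export
write_pvalues <- function(pvals, path, provenance = NULL) {
  utils::write.table(pvals, path, sep = ",", row.names = FALSE, quote = FALSE)
  if (!is.null(provenance))
    jsonlite::write_json(provenance, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
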