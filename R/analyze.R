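#' End-to-end interaction detection
#'
#' Runs the full detection pipeline on an observation table:
#' \enumerate{
#'   \item optionally drop searcher cells with short tracks
#'     (`min_track_length`);
#'   \item extract overlapping triplets at stride `n` (gaps and degenerate
#'     steps excluded);
#'   \item drop cells with fewer than `n_tr_min` triplets;
#'   \item fit per-cell Rayleigh/von Mises null parameters at the same
#'     stride, so the null model matches the effective recording interval;
#'   \item pair triplets with targets within `r_max` (3-D distance);
#'   \item compute the pooled p-value histogram (`K` bins);
#'   \item build the confidence band from `N_s` target-randomized reference
#'     replicates and classify the interaction.
#' }
#' The direction of the analysis is set by `immune_class` / `target_class`;
#' both may be the same class (e.g. NK-NK).
#'
#' @param table an `observation_table`.
#' @param r_max maximum 3-D interaction distance (micrometres).
#' @param n sub-sampling stride (integer frames).
#' @param n_tr_min minimum triplets per cell.
#' @param min_track_length minimum consecutive track length in steps
#'   (0 disables the filter).
#' @param K number of histogram bins.
#' @param N_s number of reference replicates.
#' @param z band half-width in reference standard deviations.
#' @param immune_class,target_class class labels of searcher and target.
#' @param mode `"3d"` or `"2d"` distance gating.
#' @param kappa_max persistence clamp.
#' @param seed optional RNG seed for the randomization ensemble.
#' @return an object of class `pursuit_analysis`: list with `pvalues`,
#'   `q_obs`, `band` (a `banded_histogram`), `verdict`, `params` (per-cell
#'   fits), `diagnostics` (filter counts) and `config` (all arguments).
#' @examples
#' \donttest{
#' tab <- simulate_scenario("SGS", n_immune = 20, n_targets = 20,
#'                          n_steps = 100, seed = 1)
#' res <- analyze_interactions(tab, r_max = 500, N_s = 25, seed = 2)
#' print(res)
#' }
#' @export
analyze_interactions <- function(table, r_max = 500, n = 1, n_tr_min = 5,
                                 min_track_length = 0, K = 10, N_s = 100,
                                 z = 1.645, immune_class = 0, target_class = 1,
                                 mode = c("3d", "2d"), kappa_max = 100,
                                 seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(table, "observation_table"))
  if (!is.null(seed)) set.seed(seed)
  config <- list(r_max = r_max, n = n, n_tr_min = n_tr_min,
                 min_track_length = min_track_length, K = K, N_s = N_s, z = z,
                 immune_class = immune_class, target_class = target_class,
                 mode = mode, kappa_max = kappa_max, seed = seed,
                 frame_interval = attr(table, "frame_interval"))

  if (min_track_length > 0)
    table <- filter_min_track_length(table, min_track_length, immune_class)
  triplets <- extract_triplets(table, n = n, cell_class = immune_class)
  n_degenerate <- attr(triplets, "dropped_degenerate")
  triplets <- filter_min_triplets(triplets, n_tr_min)
  excluded <- attr(triplets, "excluded_cells")
  if (!nrow(triplets))
    stop_insufficient("no triplets survive the filters")

  params <- fit_migration(table, n = n, cells = unique(triplets$cell_id),
                          cell_class = immune_class, kappa_max = kappa_max)
  pairs <- pair_with_targets(triplets, table, r_max = r_max,
                             target_class = target_class, mode = mode)
  if (!nrow(pairs))
    stop_insufficient("no triplet-target pair within r_max")
  pairs <- approach_geometry(pairs)
  pvals <- pooled_pvalues(pairs, params)
  q_obs <- pvalue_histogram(pvals$p, K)
  band <- reference_band(pairs, params, K = K, N_s = N_s, z = z,
                         r_max = r_max, mode = mode, q_obs = q_obs)
  verdict <- classify_interaction(q_obs, band)

  diagnostics <- list(
    n_triplets = nrow(triplets),
    n_pairs = nrow(pairs),
    n_cells_analyzed = length(unique(triplets$cell_id)),
    n_cells_excluded_min_triplets = length(excluded),
    n_degenerate_triplets = n_degenerate,
    n_degenerate_pairs = attr(pairs, "dropped_degenerate_pairs"))

  structure(list(pvalues = pvals, q_obs = q_obs, band = band,
                 verdict = verdict, params = params,
                 diagnostics = diagnostics, config = config),
            class = "pursuit_analysis")
}

stop_insufficient <- function(msg) {
  stop(structure(class = c("cellpursuit_insufficient_data", "error", "condition"),
                 list(message = paste0("insufficient data: ", msg), call = NULL)))
}

#' @export
print.pursuit_analysis <- function(x, ...) {
  cat("Long-range interaction analysis\n")
  cat(sprintf("  %d p-values from %d cells (%d pairs within r_max = %g µm, stride n = %d)\n",
              nrow(x$pvalues), x$diagnostics$n_cells_analyzed,
              x$diagnostics$n_pairs, x$config$r_max, as.integer(x$config$n)))
  cat(sprintf("  reference band: N_s = %d replicates, K = %d bins, z = %g\n",
              attr(x$band, "N_s"), nrow(x$band), attr(x$band, "z")))
  print(x$verdict)
  invisible(x)
}

#' Analysis presets
#'
#' Parameter bundles mirroring the two published evaluation settings:
#' `preset_simulation()` for simulator-scale data (frame interval 1 min,
#' `r_max` 500 µm, `N_s` 100 replicates, `K` 10 bins) and
#' `preset_experiment()` for sparse microscopy data (`r_max` 100 µm,
#' `N_s` 300, `K` 2 bins, minimum track length 20 steps).  Use with
#' `do.call(analyze_interactions, c(list(tab), preset_simulation()))`.
#'
#' @return named list of arguments for [analyze_interactions()].
#' @export
preset_simulation <- function() {
  list(r_max = 500, n = 1, n_tr_min = 5, min_track_length = 0,
       K = 10, N_s = 100, z = 1.645)
}

#' @rdname preset_simulation
#' @export
preset_experiment <- function() {
  list(r_max = 100, n = 1, n_tr_min = 5, min_track_length = 20,
       K = 2, N_s = 300, z = 1.645)
}
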