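test_that("straight-runner fixture p-values are computable by hand", {
  tab <- make_fixture("straight-runner")
  tri <- extract_triplets(tab)
  expect_equal(nrow(tri), 9)                    # 11 frames, n = 1
  pr <- pair_with_targets(tri, tab, r_max = 1000)
  params <- fit_migration(tab)
  expect_equal(params$kappa, 100)               # straight track clamps kappa
  pv <- pooled_pvalues(approach_geometry(pr), params)
  # cell runs along +x past target at (50, 40): theta* = atan2(40, 50 - 10 t),
  # actual step is straight on, so delta_theta = |theta*|
  t_c <- pr$t
  theta_star <- atan2(40, 50 - 10 * t_c)
  by_hand <- vapply(theta_star, function(ts)
    vm_mass_quadrature(100, ts - abs(ts), ts + abs(ts)), 1)
  expect_equal(pv$p, by_hand, tolerance = 1e-8)
  # theta* grows as the runner passes the target, so p grows monotonically
  expect_true(all(diff(pv$p[order(pv$t)]) >= -1e-12))
})

test_that("gap-track and two-class fixtures exercise the filters", {
  gap <- make_fixture("gap-track")
  tri <- extract_triplets(gap)
  expect_equal(tri$t, c(1, 5))                  # gaps at t = 3 and 7 cut centers
  two <- make_fixture("two-class")
  cross <- pair_with_targets(extract_triplets(two), two, r_max = 1000,
                             target_class = 1)
  expect_setequal(unique(cross$target_id), c(3, 4))
  within <- pair_with_targets(extract_triplets(two), two, r_max = 1000,
                              target_class = 0)
  expect_setequal(unique(within$target_id), c(1, 2))
})

test_that("the pipeline reports diagnostics and refuses insufficient data", {
  set.seed(51)
  tab <- simulate_scenario("BLS", n_immune = 15, n_targets = 10, n_steps = 80,
                           seed = 51)
  res <- analyze_interactions(tab, r_max = 2000, K = 5, N_s = 20, seed = 52)
  expect_s3_class(res, "pursuit_analysis")
  expect_equal(sum(res$q_obs), 1)
  expect_equal(nrow(res$band), 5)
  expect_equal(res$diagnostics$n_pairs, nrow(res$pvalues))
  expect_true(res$verdict$classification %in% c("attractive", "repulsive", "none"))
  expect_output(print(res), "Interaction verdict")

  tiny <- observation_table(rbind(
    data.frame(t = 0:2, x = c(0, 1, 2), y = 0, z = 0, id = 1, class = 0),
    data.frame(t = 0:2, x = 10, y = 0, z = 0, id = 2, class = 1)))
  expect_error(analyze_interactions(tiny, n_tr_min = 5),
               class = "cellpursuit_insufficient_data")

  # re-running with the same seed is reproducible
  res2 <- analyze_interactions(tab, r_max = 2000, K = 5, N_s = 20, seed = 52)
  expect_equal(res$band$hi, res2$band$hi)
  expect_equal(res$pvalues$p, res2$pvalues$p)
})

test_that("the command-line front end simulates and analyzes end to end", {
  skip_if_not_installed("optparse")
  cli <- system.file("cli", "cellpursuit.R", package = "cellpursuit")
  skip_if(cli == "", "CLI script not installed")
  rscript <- file.path(R.home("bin"), "Rscript")
  # make sure the subprocess sees the library this package is installed in
  withr::local_envvar(R_LIBS = paste(.libPaths(), collapse = .Platform$path.sep))
  out <- withr::local_tempdir()

  res <- system2(rscript, c(cli, "simulate", "--scenario", "BLS",
                            "--n-immune", "8", "--n-targets", "6",
                            "--n-steps", "40", "--seed", "3", "--out", out),
                 stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(out, "observations.csv")))
  expect_true(file.exists(file.path(out, "simulate_config.json")))
  # deterministic re-run
  out2 <- withr::local_tempdir()
  system2(rscript, c(cli, "simulate", "--scenario", "BLS",
                     "--n-immune", "8", "--n-targets", "6",
                     "--n-steps", "40", "--seed", "3", "--out", out2),
          stdout = TRUE, stderr = TRUE)
  expect_equal(readLines(file.path(out, "observations.csv")),
               readLines(file.path(out2, "observations.csv")))

  verdict <- system2(rscript, c(cli, "analyze", "--input",
                                file.path(out, "observations.csv"),
                                "--r-max", "2000", "--bins", "5",
                                "--n-s", "20", "--seed", "5", "--out", out),
                     stdout = TRUE, stderr = FALSE)
  expect_true(any(grepl("attractive|repulsive|none", verdict)))
  expect_true(file.exists(file.path(out, "pvalues.csv")))
  expect_true(file.exists(file.path(out, "band.csv")))
  expect_true(file.exists(file.path(out, "band.csv.json")))
  expect_true(file.exists(file.path(out, "analyze_config.json")))

  bad <- suppressWarnings(
    system2(rscript, c(cli, "simulate", "--scenario", "XYZ"),
            stdout = TRUE, stderr = TRUE))
  expect_false(is.null(attr(bad, "status")))

  insuff <- suppressWarnings(
    system2(rscript, c(cli, "fixtures", "--name", "gap-track", "--out", out),
            stdout = TRUE, stderr = TRUE))
  gt <- file.path(out, "gap-track.csv")
  expect_true(file.exists(gt))
  short <- suppressWarnings(
    system2(rscript, c(cli, "analyze", "--input", gt, "--n-tr-min", "5",
                       "--out", out), stdout = TRUE, stderr = TRUE))
  expect_false(is.null(attr(short, "status")))
  expect_true(any(grepl("insufficient data", short)))
})
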