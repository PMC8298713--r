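test_that("concentration field has radial symmetry and an exact gradient", {
  # single target: gradient points exactly toward it
  cg <- concentration_and_gradient(c(100, 100), rbind(c(40, 20)))
  dir <- cg$grad[1, ] / sqrt(sum(cg$grad[1, ]^2))
  to_target <- c(60, 80) / 100
  expect_equal(dir, to_target, tolerance = 1e-12)
  # midpoint of two symmetric targets: zero gradient
  cg2 <- concentration_and_gradient(rbind(c(0, 0), c(10, 0)), rbind(c(5, 0)))
  expect_equal(cg2$grad[1, ], c(0, 0), tolerance = 1e-12)
  # no targets: zero field
  cg0 <- concentration_and_gradient(NULL, rbind(c(1, 2)))
  expect_equal(cg0$C, 0); expect_equal(cg0$grad[1, ], c(0, 0))

  # analytic gradient matches central differences
  set.seed(3)
  tg <- matrix(runif(20, 0, 200), ncol = 2)
  pos <- rbind(c(77, 123))
  h <- 1e-4
  gx <- (concentration_and_gradient(tg, pos + c(h, 0))$C -
           concentration_and_gradient(tg, pos - c(h, 0))$C) / (2 * h)
  gy <- (concentration_and_gradient(tg, pos + c(0, h))$C -
           concentration_and_gradient(tg, pos - c(0, h))$C) / (2 * h)
  g <- concentration_and_gradient(tg, pos)$grad[1, ]
  expect_equal(g, c(gx, gy), tolerance = 1e-6)
})

test_that("simulated tables have the configured structure and are seeded", {
  tab <- simulate_scenario("BLS", n_immune = 12, n_targets = 8, n_steps = 40,
                           seed = 4)
  expect_s3_class(tab, "observation_table")
  imm <- unique(tab$id[tab$class == 0])
  expect_length(imm, 12)
  expect_true(all(table(tab$id[tab$class == 0]) == 41))  # frames 0..40
  expect_lte(length(unique(tab$id[tab$class == 1])), 8)
  expect_true(all(tab$z == 0))
  expect_true(all(tab$x >= 0 & tab$x <= 5000 & tab$y >= 0 & tab$y <= 5000))

  tab2 <- simulate_scenario("BLS", n_immune = 12, n_targets = 8, n_steps = 40,
                            seed = 4)
  expect_identical(as.data.frame(tab), as.data.frame(tab2))

  frame0 <- simulate_scenario("BLS", n_immune = 3, n_targets = 2, n_steps = 0,
                              seed = 1)
  expect_equal(unique(frame0$t), 0)
})

test_that("full-scale defaults give 100 immune trajectories of 500 steps", {
  tab <- simulate_scenario("BLS", seed = 9)
  trs <- build_trajectories(tab)
  imm <- Filter(function(tr) tr$cell_class == 0, trs)
  expect_length(imm, 100)
  expect_true(all(vapply(imm, function(tr) nrow(tr$pos), 1) == 501))
  expect_lte(length(trs) - length(imm), 50)
  # simulator bookkeeping matches trajectory assembly: no gaps for immune
  expect_true(all(vapply(imm, function(tr) length(tr$gaps), 1) == 0))
})

test_that("targets are depleted monotonically and never reappear", {
  tab <- simulate_scenario("SGS", n_immune = 40, n_targets = 30, n_steps = 80,
                           seed = 6, r_kill = 40)
  per_frame <- tapply(tab$class, tab$t, sum)
  expect_true(all(diff(as.numeric(per_frame)) <= 0))
  expect_lt(per_frame[length(per_frame)], per_frame[1])  # some killing happened
  for (tr in build_trajectories(tab))
    if (tr$cell_class == 1) expect_length(tr$gaps, 0)    # death is final
})

test_that("spatial gradient sensing with c = 0 reduces to blind search", {
  a <- simulate_scenario("BLS", n_immune = 15, n_targets = 10, n_steps = 60,
                         seed = 12)
  b <- simulate_scenario("SGS", c_coeff = 0, n_immune = 15, n_targets = 10,
                         n_steps = 60, seed = 12)
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("turning angles of blind walkers recover the per-cell kappa", {
  tab <- simulate_scenario("BLS", n_immune = 20, n_targets = 0, n_steps = 500,
                           r_kill = 0, seed = 14)
  truth <- attr(tab, "true_params")
  fit <- fit_migration(tab)
  m <- merge(fit, truth, by = "cell_id", suffixes = c("_hat", "_true"))
  expect_equal(nrow(m), 20)
  expect_lt(median(abs(m$kappa_hat - m$kappa_true)), 0.35)
  expect_lt(median(abs(m$sigma_hat - m$sigma_true) / m$sigma_true), 0.05)
})

test_that("sub-sampling amplifies the detected chemotactic signal", {
  # larger effective recording intervals make goal-directed motion stand out
  tab <- simulate_scenario("SGS", seed = 1)
  excess <- vapply(c(1, 2, 4), function(n) {
    res <- analyze_interactions(tab, r_max = 500, n = n, N_s = 100, K = 10,
                                seed = 101)
    res$q_obs[1] - res$band$hi[1]
  }, numeric(1))
  expect_true(all(diff(excess) >= 0))
  expect_true(all(excess > 0))
})

test_that("temporal gradient sensing switches mode on the concentration history", {
  cfg <- scenario_config("TGS", n_immune = 2, n_targets = 1, n_steps = 1)
  state <- list(immune = rbind(c(100, 0), c(400, 0)), heading = c(0, 0),
                targets = rbind(c(0, 0)), alive = TRUE, mode = c(TRUE, TRUE),
                C_prev = c(NA_real_, NA_real_), t = 0L,
                sigma = c(5, 5), kappa = c(5, 5))
  set.seed(1)
  s1 <- cellpursuit:::sim_step(state, cfg)
  expect_true(all(s1$mode))              # first step: no history, stay persistent
  # second step: persistent iff the concentration did not decrease
  s2 <- cellpursuit:::sim_step(s1, cfg)
  expect_equal(unname(s2$mode), unname(s2$C_prev >= s1$C_prev))
  # a forced down-gradient history switches the cell to the diffusive mode
  s1_forced <- s1
  s1_forced$C_prev <- s1$C_prev + 1      # pretend concentration was higher
  set.seed(2)
  s2f <- cellpursuit:::sim_step(s1_forced, cfg)
  expect_false(any(s2f$mode))
})
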