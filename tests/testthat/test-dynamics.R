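test_that("squashing is odd, bounded, strictly increasing", {
  expect_equal(squash(0), 0)
  v <- seq(-3, 3, by = 0.25)
  expect_equal(squash(-v), -squash(v))
  expect_true(all(diff(squash(v)) > 0))
  expect_true(all(abs(squash(c(-15, 15))) < 1))
  expect_true(all(abs(squash(c(-100, 100))) <= 1))  # saturates numerically
  expect_gt(squash(5), 0.999)
  expect_lt(squash(5), 1)
  expect_error(squash(Inf), "non-finite")
})

test_that("zero is a fixed point of the unclamped system", {
  net <- randomNetwork(20, mean_degree = 4, seed = 1)
  x <- setNames(numeric(20), conceptIds(net))
  expect_equal(stepState(x, net), x)
  tr <- runSimulation(net, config = quiet_cfg())
  expect_true(isConverged(tr))
  expect_equal(iterationsToConvergence(tr), 5L)  # window length
  expect_true(all(terminalState(tr) == 0))
  expect_equal(attractorClass(tr), "fixed_point")
})

test_that("states stay in [-1, 1] for arbitrary networks and clamps", {
  for (s in 1:5) {
    net <- randomNetwork(30, mean_degree = 6,
                         weight_magnitude = c(0.3, 1), seed = s)
    clamps <- rbind(clampSpec("c1", "hold", -1),
                    clampSpec("c2", "hold", 0.37),
                    clampSpec("c3", "initial_only", 1))
    tr <- runSimulation(net, clamps, simConfig(noiseSigma = 0.05,
                                               seed = s,
                                               maxIterations = 60L))
    expect_true(all(abs(states(tr)) <= 1))
  }
})

test_that("hold clamps overwrite exactly from active_from onwards", {
  net <- randomNetwork(15, mean_degree = 5, seed = 2)
  clamps <- rbind(clampSpec("c4", "hold", 0.37, active_from = 3),
                  clampSpec("c5", "hold", -1))
  tr <- runSimulation(net, clamps, quiet_cfg(maxIterations = 30L))
  m <- states(tr)
  expect_true(all(m[-(1:3), "c4"] == 0.37))   # rows 4+ are iterations >= 3
  expect_true(all(m[, "c5"] == -1))           # active from iteration 0
})

test_that("initial_only clamps pulse at t = 0 and then evolve freely", {
  net <- two_node_net(1)
  tr <- runSimulation(net, clampSpec("A", "initial_only", 1), quiet_cfg())
  m <- states(tr)
  expect_equal(unname(m[1, "A"]), 1)
  expect_lt(unname(m[2, "A"]), 1)  # A has no inflow: decays via memory alone
  expect_warning(clampSpec("A", "initial_only", 1, active_from = 2),
                 "ignore")
})

test_that("trajectories are bit-identical for a fixed seed", {
  net <- randomNetwork(25, mean_degree = 5, seed = 3)
  cfg <- simConfig(noiseSigma = 0.05, seed = 99, maxIterations = 50L)
  t1 <- runSimulation(net, clampSpec("c1", "hold", 1), cfg)
  t2 <- runSimulation(net, clampSpec("c1", "hold", 1), cfg)
  expect_identical(states(t1), states(t2))
  t3 <- runSimulation(net, clampSpec("c1", "hold", 1),
                      simConfig(noiseSigma = 0.05, seed = 100,
                                maxIterations = 50L))
  expect_false(identical(states(t1), states(t3)))
})

test_that("driven-node steady states match the scalar fixed-point oracle", {
  cases <- list(list(w = 1, a = 1, mu = 0), list(w = 1, a = 1, mu = 1),
                list(w = -0.8, a = 0.5, mu = 1),
                list(w = 0.6, a = -1, mu = 0.5))
  for (cs in cases) {
    net <- two_node_net(cs$w)
    cfg <- quiet_cfg(tol = 1e-12, window = 5L, memory = cs$mu,
                     maxIterations = 5000L)
    tr <- runSimulation(net, clampSpec("A", "hold", cs$a), cfg)
    expect_true(isConverged(tr))
    expect_equal(terminalState(tr)[["B"]],
                 scalar_fixed_point(cs$w, cs$a, cs$mu), tolerance = 1e-8)
  }
})

test_that("convergence window semantics match their definitions", {
  # constant trajectory converges exactly at iteration = window
  m <- matrix(0.3, nrow = 11, ncol = 2)
  expect_equal(assessConvergence(m, tol = 1e-4, window = 5L),
               list(converged = TRUE, iteration = 5L))
  # alternating two-cycle never converges for tol < amplitude
  m2 <- matrix(rep(c(0.5, -0.5), 10), ncol = 1)
  expect_false(assessConvergence(m2, tol = 0.99, window = 3L)$converged)
  # geometric approach 1 - 0.5^t: first step difference below 1e-4 is t=14
  m3 <- matrix(1 - 0.5^(0:20), ncol = 1)
  expect_equal(assessConvergence(m3, tol = 1e-4, window = 1L)$iteration,
               14L)
})

test_that("pure negative feedback with high gain classifies as a limit cycle", {
  net <- conceptNetwork(data.frame(source = c("A", "B"),
                                   target = c("B", "A"),
                                   weight = c(1, -1)))
  cfg <- quiet_cfg(memory = 0, squashGain = 5, maxIterations = 60L)
  tr <- runSimulation(net, clampSpec("A", "initial_only", 1), cfg)
  expect_false(isConverged(tr))
  expect_equal(attractorClass(tr), "limit_cycle")
  expect_equal(cyclePeriod(tr), 4L)
})

test_that("truncated runs classify as non-convergent", {
  net <- conceptNetwork(data.frame(source = c("A", "B"),
                                   target = c("B", "A"),
                                   weight = c(1, -1)))
  cfg <- quiet_cfg(memory = 0, squashGain = 5, maxIterations = 5L,
                   window = 5L)
  tr <- runSimulation(net, clampSpec("A", "initial_only", 1), cfg)
  expect_equal(attractorClass(tr), "non_convergent")
  expect_true(is.na(cyclePeriod(tr)))
})

test_that("overtraining check keeps iterating and confirms fixed points", {
  net <- iopdNetwork()
  cl <- recipeClamps(iopdRecipes()[["aiSkMC_IOPD"]])
  tr <- runSimulation(net, cl, quiet_cfg(maxIterations = 1000L),
                      overtrain = TRUE)
  expect_true(isConverged(tr))
  expect_equal(nrow(states(tr)), 1001L)  # ran the full budget
  expect_equal(attractorClass(tr), "fixed_point")
})

test_that("replicate ensembles: zero-noise SEM and seeded reproducibility", {
  net <- iopdNetwork()
  cl <- recipeClamps(iopdRecipes()[["aiSkMC_WT"]])
  p0 <- runReplicates(net, cl, quiet_cfg(), n = 3)
  expect_true(all(profileSummary(p0)$sem == 0))
  expect_true(all(p0@convergedReplicates))

  cfg <- simConfig(seed = 5)
  p1 <- runReplicates(net, cl, cfg, n = 3)
  p2 <- runReplicates(net, cl, cfg, n = 3)
  expect_identical(terminalValues(p1), terminalValues(p2))
  expect_equal(nReplicates(p1), 3L)
})

test_that("dimension mismatches and bad configs are rejected", {
  net <- two_node_net()
  expect_error(stepState(c(0, 0, 0), net), "dimension")
  expect_error(simConfig(tol = -1), "tol")
  expect_error(simConfig(window = 0), "window")
  expect_error(simConfig(memory = 2), "memory")
})

test_that("YAML config files round through readSimConfig", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("max_iterations: 200", "tol: 1.0e-6", "noise_sigma: 0",
               "seed: 9"), f)
  cfg <- readSimConfig(f)
  expect_equal(cfg@maxIterations, 200L)
  expect_equal(cfg@tol, 1e-6)
  expect_equal(cfg@noiseSigma, 0)
  expect_equal(cfg@seed, 9L)
  writeLines("bogus_key: 1", f)
  expect_error(readSimConfig(f), "unknown config key")
})
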