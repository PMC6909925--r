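test_that("Table-1-style recipes expand to the expected clamp structure", {
  net <- iopdNetwork()
  recs <- iopdRecipes()

  f <- recs[["aiPSC_IOPD"]]@factors
  expect_equal(sum(f$mode == "initial_only"), 4L)       # OSKM pulse
  expect_equal(sum(f$mode == "hold" & f$value == 1), 2L) # Dox + MyoD1_exo
  expect_equal(recs[["aiPSC_IOPD"]]@deletions, "GAA")

  f_wt <- recs[["aiSkMC_WT"]]@factors
  expect_equal(sum(f_wt$mode == "initial_only"), 0L)     # no OSKM
  expect_equal(recs[["aiSkMC_WT"]]@deletions, character())

  cl <- recipeClamps(recs[["aiPSC_IOPD"]], net)
  expect_true("Fibroblast" %in% cl$concept[cl$mode == "hold" &
                                             cl$value == 1])
  expect_equal(cl$value[cl$concept == "GAA"], -1)

  expect_error(makeRecipe("bad", held = "NOT_A_CONCEPT", net = net),
               "unknown concept")
})

test_that("knockout is idempotent and turns WT into the disease recipe", {
  recs <- iopdRecipes()
  ko <- applyKnockout(recs[["aiSkMC_WT"]], "GAA")
  expect_equal(recipeClamps(ko), recipeClamps(recs[["aiSkMC_IOPD"]]))
  expect_equal(ko@label, "disease")
  expect_identical(recipeClamps(applyKnockout(ko, "GAA")),
                   recipeClamps(ko))
  expect_error(applyKnockout(recs[["aiSkMC_WT"]], "Doxycycline"),
               "contradictory")
})

test_that("fractional inhibition clamps at -f; f = 1 equals knockout", {
  recs <- iopdRecipes()
  r25 <- applyInhibition(recs[["aiSkMC_IOPD"]], "VDCC", 0.25)
  cl <- recipeClamps(r25)
  expect_equal(cl$value[cl$concept == "VDCC"], -0.25)
  expect_equal(cl$mode[cl$concept == "VDCC"], "hold")

  net <- iopdNetwork()
  full <- applyInhibition(recs[["aiSkMC_IOPD"]], "VDCC", 1)
  ko <- applyKnockout(recs[["aiSkMC_IOPD"]], "VDCC")
  t1 <- runSimulation(net, recipeClamps(full, net), quiet_cfg())
  t2 <- runSimulation(net, recipeClamps(ko, net), quiet_cfg())
  expect_identical(states(t1), states(t2))

  expect_error(applyInhibition(recs[["aiSkMC_IOPD"]], "VDCC", 1.2),
               "\\[0, 1\\]")
  expect_error(applyInhibition(recs[["aiSkMC_IOPD"]], "VDCC", -0.1),
               "\\[0, 1\\]")
})

test_that("recipe composition is order-independent for distinct targets", {
  recs <- iopdRecipes()
  a <- applyInhibition(applyKnockout(recs[["aiSkMC_WT"]], "GAA"),
                       "calpain", 0.25)
  b <- applyKnockout(applyInhibition(recs[["aiSkMC_WT"]], "calpain", 0.25),
                     "GAA")
  srt <- function(r) {
    cl <- recipeClamps(r)
    cl[order(cl$concept, cl$mode), ]
  }
  expect_equal(srt(a), srt(b), ignore_attr = TRUE)
})

test_that("two-phase treatment reverses disease readouts after onset", {
  net <- iopdNetwork()
  tp <- runTwoPhase(net, "aiSkMC_IOPD", "calpain", 0.25, quiet_cfg(),
                    n = 1)
  m1 <- profileMeans(tp$phase1); m2 <- profileMeans(tp$phase2)
  expect_gt(m1[["cell_death"]], 0)                 # disease established
  expect_lt(m2[["cell_death"]], m1[["cell_death"]])
  expect_lt(m2[["mitochondrial_dysfunction"]],
            m1[["mitochondrial_dysfunction"]])

  # clamping the target AT zero silences it: different from no treatment
  tp0 <- runTwoPhase(net, "aiSkMC_IOPD", "calpain", 0, quiet_cfg(), n = 1)
  expect_false(isTRUE(all.equal(profileMeans(tp0$phase2),
                                profileMeans(tp0$phase1))))
  expect_equal(profileMeans(tp0$phase2)[["calpain"]], 0)

  expect_error(runTwoPhase(net, "aiSkMC_IOPD", "calpain", 0.25,
                           schedule = "from_start"), "from_start")
})

test_that("dose-response is monotone with a no-treatment baseline at 0", {
  net <- iopdNetwork()
  cfg <- quiet_cfg(tol = 1e-9, maxIterations = 2000L)
  dr <- doseResponseSweep(net, "aiSkMC_IOPD", "VDCC",
                          grid = c(0.25, 0, 1, 0.5), n = 1, config = cfg)
  tab <- doseResponseTable(dr)
  expect_equal(unique(tab$fraction), c(0, 0.25, 0.5, 1))  # sorted
  for (ro in unique(tab$readout)) {
    v <- tab$mean[tab$readout == ro]
    expect_true(all(diff(v) <= 1e-8))
    expect_lt(v[2], v[1])   # improvement already at the lowest dose
  }
  # baseline equals the untreated disease steady state (sentinel, no clamp)
  untreated <- runRecipe(net, "aiSkMC_IOPD", cfg, n = 1)
  base <- tab[tab$fraction == 0, ]
  expect_equal(base$mean,
               unname(profileMeans(untreated)[base$readout]),
               tolerance = 1e-6)
  expect_error(doseResponseSweep(net, "aiSkMC_IOPD", "VDCC",
                                 grid = numeric()), "empty")
  expect_error(doseResponseSweep(net, "aiSkMC_IOPD", "VDCC", grid = 2),
               "\\[0, 1\\]")
})

test_that("phenotype establishment distinguishes schedules and doses", {
  net <- iopdNetwork()
  cfg <- quiet_cfg()
  # untreated disease establishes the phenotype
  dis <- runRecipe(net, "aiSkMC_IOPD", cfg, n = 1)
  expect_true(phenotypeEstablished(dis))
  wt <- runRecipe(net, "aiSkMC_WT", cfg, n = 1)
  expect_false(phenotypeEstablished(wt))
  # low-dose calpain inhibition from the start does not prevent onset;
  # full knockout from the start does
  lo <- doseResponseSweep(net, "aiSkMC_IOPD", "calpain", c(0.1, 1),
                          n = 1, config = cfg, schedule = "from_start")
  expect_true(unname(lo@established["0.1"]))
  expect_false(unname(lo@established["1"]))
})

test_that("genotype comparison calls up/down/unchanged with a dead band", {
  net <- iopdNetwork()
  wt <- runRecipe(net, "aiSkMC_WT", quiet_cfg(), n = 1)
  dis <- runRecipe(net, "aiSkMC_IOPD", quiet_cfg(), n = 1)
  cmp <- compareGenotypes(wt, dis)
  dir <- setNames(cmp$direction, cmp$concept)
  expect_equal(dir[["lysosomal_glycogen"]], "up")
  expect_equal(dir[["mTORC1_p"]], "down")
  expect_equal(dir[["lysosomal_calcium"]], "unchanged")
  expect_true(all(compareGenotypes(wt, wt)$direction == "unchanged"))

  small <- runReplicates(two_node_net(), config = quiet_cfg(), n = 1)
  expect_error(compareGenotypes(wt, small), "concept universes")
})
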