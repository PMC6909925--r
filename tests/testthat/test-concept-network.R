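test_that("single-row parse, empty files and rejected rows behave", {
  f <- tempfile(fileext = ".csv")
  writeLines("GAA,lysosomal_glycogen,-1.0", f)
  net <- readEdgeList(f)
  expect_equal(nConcepts(net), 2L)
  expect_equal(nRelations(net), 1L)
  expect_equal(relations(net)$weight, -1)

  writeLines(character(), f)
  empty <- readEdgeList(f)
  expect_equal(nConcepts(empty), 0L)
  expect_equal(nRelations(empty), 0L)

  writeLines(c("source,target,weight", "A,B,0"), f)
  expect_error(readEdgeList(f), "rejected")
  writeLines(c("A,B,1.5"), f)
  expect_error(readEdgeList(f), "rejected")
})

test_that("duplicate edges error in strict mode, last-wins otherwise", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("A,B,0.5", "A,B,-0.5", "B,A,1"), f)
  expect_error(readEdgeList(f, strict = TRUE), "A -> B")
  expect_warning(net <- readEdgeList(f), "last occurrence")
  expect_equal(nRelations(net), 2L)
  re <- relations(net)
  expect_equal(re$weight[re$source == "A" & re$target == "B"], -0.5)
})

test_that("edge-list round trip is the identity on generated networks", {
  for (s in 1:5) {
    net <- randomNetwork(20, mean_degree = 4, positive_fraction = 0.6,
                         weight_magnitude = c(0.2, 1), seed = s)
    f <- tempfile(fileext = ".csv")
    g <- tempfile(fileext = ".csv")
    writeEdgeList(net, f, concept_table = g)
    back <- readEdgeList(f, concept_table = g)
    ord <- function(x) {
      re <- relations(x)[, c("source", "target", "weight")]
      re[order(re$source, re$target), ]
    }
    expect_equal(ord(back), ord(net), ignore_attr = TRUE)
    expect_equal(concepts(back), concepts(net))
  }
})

test_that("TSV separator and headers are auto-detected", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("source\ttarget\tweight", "A\tB\t0.5"), f)
  expect_equal(nRelations(readEdgeList(f)), 1L)
})

test_that("SIF import maps activates/inhibits to signed unit weights", {
  f <- tempfile(fileext = ".sif")
  writeLines(c("GAA\tinhibits\tlysosomal_glycogen",
               "VDCC\tactivates\tintracellular_calcium"), f)
  net <- readSIF(f)
  re <- relations(net)
  expect_equal(sort(re$weight), c(-1, 1))
  writeLines("A\tbinds\tB", f)
  expect_error(readSIF(f), "binds")
})

test_that("dangling concept-table references are an error", {
  f <- tempfile(fileext = ".csv"); g <- tempfile(fileext = ".csv")
  writeLines(c("source,target,weight", "A,B,1"), f)
  writeLines(c("id,label,kind,aliases", "A,A,gene,"), g)
  expect_error(readEdgeList(f, concept_table = g), "dangling")
})

test_that("network stats: degrees, sign fraction and pretest probabilities", {
  net <- two_node_net(0.5)
  st <- networkStats(net)
  expect_equal(st$positive_fraction, 1.0)
  expect_equal(st$mean_out_degree, 0.5)

  # constructed 66 positive / 34 negative edges -> pretest 0.66 exactly
  rel <- data.frame(source = paste0("s", 1:100), target = "hub",
                    weight = c(rep(0.5, 66), rep(-0.5, 34)))
  st <- networkStats(conceptNetwork(rel))
  expect_equal(st$pretest_positive, 0.66)
  expect_equal(st$pretest_negative, 0.34)
  expect_equal(st$pretest_positive + st$pretest_negative, 1)
  expect_equal(st$n_relations, 100L)

  expect_error(networkStats(conceptNetwork()), "empty")
})

test_that("random generator is seed-reproducible with exact edge count", {
  a <- randomNetwork(100, mean_degree = 8, positive_fraction = 0.66,
                     seed = 1)
  b <- randomNetwork(100, mean_degree = 8, positive_fraction = 0.66,
                     seed = 1)
  expect_identical(relations(a), relations(b))
  expect_equal(nRelations(a), 800L)
  expect_false(identical(
    relations(randomNetwork(100, 8, seed = 2)), relations(a)))
  expect_true(all(relations(randomNetwork(50, 4, positive_fraction = 0,
                                          seed = 3))$weight < 0))
  expect_error(randomNetwork(5, mean_degree = 10), "infeasible")
  # no self loops, no duplicate ordered pairs
  re <- relations(a)
  expect_false(any(re$source == re$target))
  expect_false(anyDuplicated(paste(re$source, re$target)) > 0)
})

test_that("realized sign fraction lands in the exact binomial 99% interval", {
  net <- randomNetwork(500, mean_degree = 20, positive_fraction = 0.66,
                       seed = 4)
  m <- nRelations(net)
  expect_equal(m, 10000L)
  k <- sum(relations(net)$weight > 0)
  bounds <- qbinom(c(0.005, 0.995), m, 0.66)
  expect_gte(k, bounds[1])
  expect_lte(k, bounds[2])
})

test_that("the curated disease network satisfies its contracts", {
  net <- iopdNetwork()
  expect_true(validObject(net))
  expect_true(nConcepts(net) >= 45 && nConcepts(net) <= 60)

  panels <- c(
    "OCT4", "SOX2", "KLF4", "cMYC", "Doxycycline", "MyoD1_exo", "MyoD1",
    "Fibroblast",
    "NANOG", "GDF3", "REX1", "FGF4", "DPPA5", "DPPA2", "DPPA4", "hTERT",
    "SALL4", "ECAD", "SSEA34", "TRA_1_81", "ALP",
    "CKM", "MyHC", "Myogenin", "Pax7",
    "GAA", "lysosomal_glycogen", "LAMP2", "glucose_deprivation",
    "mTORC1_p", "p70S6K_p", "p4EBP1_p",
    "mitochondrial_dysfunction", "impaired_energy_metabolism", "ATP",
    "ADP", "ROS", "CytC", "AIF", "Caspase3", "apoptosis", "cell_death",
    "DNM1L", "MFN2",
    "LC3", "p62", "Pink2", "autophagy", "mitophagy",
    "VDCC", "intracellular_calcium", "lysosomal_calcium", "calpain")
  expect_true(all(panels %in% conceptIds(net)))

  # concepts deliberately not modelled
  absent <- c("TRA_1_60", "TRA-1-60", "Park2", "FIS1", "OPA1", "COX4l1",
              "mitochondrial_calcium")
  expect_false(any(tolower(absent) %in% tolower(conceptIds(net))))

  re <- relations(net)
  expect_lt(re$weight[re$source == "GAA" &
                        re$target == "lysosomal_glycogen"], 0)
  expect_gt(re$weight[re$source == "VDCC" &
                        re$target == "intracellular_calcium"], 0)
  # every relation carries provenance, tagged literature or curated
  expect_false(anyNA(re$provenance))
  expect_true(all(grepl("^(literature|curated)", re$provenance)))
  expect_true(any(grepl("^curated", re$provenance)))
})

test_that("alias resolution is case-insensitive and errors on unknowns", {
  net <- iopdNetwork()
  expect_equal(resolveConcepts(net, c("oct3/4", "Dox", "SSEA-3/4")),
               c("OCT4", "Doxycycline", "SSEA34"))
  expect_error(resolveConcepts(net, "NOT_A_CONCEPT"), "unknown concept")
})

test_that("the exported network files match the in-code definition", {
  edges <- system.file("extdata", "iopd_edges.csv", package = "fcmsim")
  conc <- system.file("extdata", "iopd_concepts.csv", package = "fcmsim")
  net <- readEdgeList(edges, concept_table = conc)
  ref <- iopdNetwork()
  ord <- function(x) {
    re <- relations(x)[, c("source", "target", "weight")]
    `rownames<-`(re[order(re$source, re$target), ], NULL)
  }
  expect_equal(ord(net), ord(ref))
  expect_equal(concepts(net)[order(concepts(net)$id), ],
               concepts(ref)[order(concepts(ref)$id), ],
               ignore_attr = TRUE)
})
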