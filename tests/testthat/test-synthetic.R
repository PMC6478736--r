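# Planted-structure generator and recovery scoring.

test_that("generation is byte-identical for a fixed seed", {
  a <- generateDiseasome(syntheticConfig(nGroups = 2, diseasesPerGroup = 8,
                                         seed = 4))
  b <- generateDiseasome(syntheticConfig(nGroups = 2, diseasesPerGroup = 8,
                                         seed = 4))
  expect_identical(a@genes@records, b@genes@records)
  expect_identical(a@symptoms@records, b@symptoms@records)
  expect_identical(a@comorbidity@counts, b@comorbidity@counts)
  expect_identical(a@semantic@values, b@semantic@values)
  expect_identical(a@dag@annotations, b@dag@annotations)
  c_ <- generateDiseasome(syntheticConfig(nGroups = 2, diseasesPerGroup = 8,
                                          seed = 5))
  expect_false(identical(a@genes@records, c_@genes@records))
})

test_that("noiseless two-group data decompose into label-aligned components", {
  ds <- generateDiseasome(syntheticConfig(nGroups = 2, diseasesPerGroup = 12,
                                          backgroundRate = 0,
                                          contaminationRate = 0, seed = 6))
  for (assoc in list(ds@genes, ds@symptoms)) {
    ly <- suppressMessages(projectLayer(assoc))
    g <- igraph::graph_from_data_frame(ly@edges[, 1:2], directed = FALSE,
                                       vertices = ly@nodes)
    comp <- igraph::components(g)
    expect_equal(comp$no, 2L)
    split1 <- igraph::V(g)$name[comp$membership == 1]
    expect_equal(length(unique(ds@labels[split1])), 1L)
  }
})

test_that("emitted tables satisfy the consuming modules' invariants", {
  ds <- generateDiseasome(syntheticConfig(seed = 12))
  expect_true(validObject(ds@genes))
  expect_true(validObject(ds@symptoms))
  expect_true(validObject(ds@comorbidity))
  expect_true(validObject(ds@dag))
  expect_true(validObject(ds@semantic))
  expect_setequal(names(ds@labels), unique(ds@genes@records$disease))
  # semantic matrix symmetric with unit diagonal
  expect_identical(ds@semantic@values, t(ds@semantic@values))
  expect_true(all(diag(ds@semantic@values) == 1))
})

test_that("infeasible configurations are rejected", {
  expect_error(generateDiseasome(syntheticConfig(genesPerDisease = 50,
                                                 genePoolSize = 40)),
               "pool smaller")
  expect_error(syntheticConfig(backgroundRate = 1), "rates")
})

test_that("empirical within-group relative risk tracks the configured target", {
  set.seed(0)
  withinRR <- vapply(1:20, function(s) {
    ds <- generateDiseasome(syntheticConfig(nGroups = 2, diseasesPerGroup = 8,
                                            rrWithin = 5, seed = 100 + s))
    pr <- t(combn(names(ds@labels), 2))
    same <- ds@labels[pr[, 1]] == ds@labels[pr[, 2]]
    mean(comorbidityRR(ds@comorbidity, pr[same, 1], pr[same, 2]))
  }, numeric(1))
  expect_gt(mean(withinRR), 4)
  expect_lt(mean(withinRR), 6)
})

test_that("within-group RR converges to the target as the population grows", {
  err <- vapply(c(1e3, 1e5), function(N) {
    ds <- generateDiseasome(syntheticConfig(
      nGroups = 2, diseasesPerGroup = 10, rrWithin = 5,
      population = N, prevalenceRange = c(N * 0.002, N * 0.02), seed = 3))
    pr <- t(combn(names(ds@labels), 2))
    same <- ds@labels[pr[, 1]] == ds@labels[pr[, 2]]
    abs(mean(comorbidityRR(ds@comorbidity, pr[same, 1], pr[same, 2])) - 5)
  }, numeric(1))
  expect_lte(err[2], err[1] + 1e-9)
  expect_lt(err[2], 0.2)
})

test_that("misaligned layers make symptom groups straddle planted groups", {
  ds <- generateDiseasome(syntheticConfig(nGroups = 3, diseasesPerGroup = 8,
                                          backgroundRate = 0,
                                          contaminationRate = 0,
                                          alignedLayers = FALSE, seed = 2))
  lyS <- suppressMessages(projectLayer(ds@symptoms))
  g <- igraph::graph_from_data_frame(lyS@edges[, 1:2], directed = FALSE,
                                     vertices = lyS@nodes)
  comp <- igraph::components(g)
  expect_equal(comp$no, 3L)
  # each symptom component mixes diseases from two planted gene groups
  m <- split(igraph::V(g)$name, comp$membership)
  for (grp in m) expect_equal(length(unique(ds@labels[grp])), 2L)
})

test_that("recovery score has its closed-form limits", {
  labels <- setNames(rep(1:2, each = 10), sprintf("d%02d", 1:20))
  mk <- function(assign) {
    ds <- names(labels)
    new("MultiplexPartition",
        states = data.frame(disease = ds, layer = "g",
                            stringsAsFactors = FALSE),
        assignment = as.integer(assign),
        visitRates = setNames(rep(0.05, 20), paste0(ds, "|g")),
        relaxRate = 0.45,
        codelength = new("MapEquationTerms", index = 0, module = 1,
                         total = 1),
        seed = 1L, nTrials = 1L)
  }
  expect_equal(as.numeric(recoveryScore(labels, mk(rep(1:2, each = 10)))), 1)
  # single detected cluster is degenerate -> 0 with flag
  deg <- recoveryScore(labels, mk(rep(1L, 20)))
  expect_equal(as.numeric(deg), 0)
  expect_true(attr(deg, "degenerate"))
  # one label split into two equal detected communities: contingency oracle
  split2 <- c(rep(1, 10), rep(2, 5), rep(3, 5))
  expect_equal(as.numeric(recoveryScore(labels, mk(split2))),
               oracleNMI(labels, split2), tolerance = 1e-12)
  # independent random partition on many diseases scores near 0
  set.seed(10)
  bigLabels <- setNames(rep(1:2, each = 150), sprintf("d%03d", 1:300))
  rnd <- sample(1:2, 300, replace = TRUE)
  p <- new("MultiplexPartition",
           states = data.frame(disease = names(bigLabels), layer = "g",
                               stringsAsFactors = FALSE),
           assignment = as.integer(rnd),
           visitRates = setNames(rep(1 / 300, 300),
                                 paste0(names(bigLabels), "|g")),
           relaxRate = 0.45,
           codelength = new("MapEquationTerms", index = 0, module = 1,
                            total = 1),
           seed = 1L, nTrials = 1L)
  expect_lt(as.numeric(recoveryScore(bigLabels, p)), 0.05)
})

test_that("written dataset round-trips through the package readers", {
  ds <- generateDiseasome(syntheticConfig(nGroups = 2, diseasesPerGroup = 8,
                                          seed = 15))
  dir <- withr::local_tempdir()
  writeSyntheticDataset(ds, dir)
  g2 <- suppressMessages(readBipartite(file.path(dir, "genes.tsv"), "gene"))
  expect_identical(g2@records, ds@genes@records)
  s2 <- suppressMessages(readBipartite(file.path(dir, "symptoms.tsv"),
                                       "symptom"))
  expect_identical(s2@records, ds@symptoms@records)
  ct <- readComorbidity(file.path(dir, "comorbidity_pairs.tsv"),
                        file.path(dir, "prevalence.tsv"),
                        ds@comorbidity@population)
  expect_identical(ct@counts, ds@comorbidity@counts)
  expect_identical(ct@prevalence, ds@comorbidity@prevalence)
  dag2 <- suppressMessages(readAnnotations(file.path(dir, "annotations.tsv"),
                                           file.path(dir, "term_parents.tsv")))
  a1 <- ds@dag@annotations[order(ds@dag@annotations$gene,
                                 ds@dag@annotations$term), ]
  a2 <- dag2@annotations[order(dag2@annotations$gene, dag2@annotations$term), ]
  expect_equal(a1, a2, ignore_attr = TRUE)
  sm2 <- readSemanticMatrix(file.path(dir, "semantic.tsv"))
  expect_equal(sm2@values, ds@semantic@values, tolerance = 1e-12)
})

test_that("the full synthetic pipeline recovers planted groups with bridges under misalignment", {
  # aligned strong-signal case: perfect recovery (also exercised in the
  # acceptance suite); misaligned layers produce bridge diseases
  ds <- generateDiseasome(syntheticConfig(nGroups = 2, diseasesPerGroup = 12,
                                          backgroundRate = 0,
                                          contaminationRate = 0,
                                          alignedLayers = FALSE, seed = 8))
  mx <- syntheticMultiplex(ds)
  p <- detectCommunities(mx, seed = 5, nTrials = 6)
  expect_gt(length(bridgeDiseases(p)), 0L)
})
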