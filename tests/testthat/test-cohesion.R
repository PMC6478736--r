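# Intra-community cohesion assessment.

# build a partition object directly from disease -> community labels
labelPartition <- function(labels) {
  ds <- names(labels)
  states <- data.frame(disease = ds, layer = "g", stringsAsFactors = FALSE)
  new("MultiplexPartition", states = states,
      assignment = as.integer(factor(labels)),
      visitRates = setNames(rep(1 / length(ds), length(ds)),
                            paste0(ds, "|g")),
      relaxRate = 0.45,
      codelength = new("MapEquationTerms", index = 0, module = 1, total = 1),
      seed = 1L, nTrials = 1L)
}

test_that("community pair enumeration respects the size threshold", {
  labels <- setNames(rep(1:3, c(10, 9, 12)), sprintf("d%02d", 1:31))
  prs <- communityPairs(labelPartition(labels), minSize = 10)
  expect_length(prs, 2L)                    # the 9-disease community is out
  expect_equal(nrow(prs[[1]]), choose(10, 2))
  expect_equal(nrow(prs[[2]]), choose(12, 2))
})

test_that("bridge diseases contribute pairs to both communities", {
  ds <- sprintf("d%02d", 1:21)
  states <- data.frame(disease = c(ds, "d01"), layer = c(rep("g", 21), "p"),
                       stringsAsFactors = FALSE)
  # d01's phenotype state sits in community 2
  asg <- as.integer(c(rep(1, 11), rep(2, 10), 2))
  p <- new("MultiplexPartition", states = states, assignment = asg,
           visitRates = setNames(rep(1 / 22, 22), .pk <- paste(states$disease,
             states$layer, sep = "|")),
           relaxRate = 0.45,
           codelength = new("MapEquationTerms", index = 0, module = 1,
                            total = 1),
           seed = 1L, nTrials = 1L)
  prs <- communityPairs(p, minSize = 10)
  expect_equal(nrow(prs[["1"]]), choose(11, 2))
  expect_equal(nrow(prs[["2"]]), choose(11, 2))   # d01 joins both
  expect_true("d01" %in% c(prs[["2"]]))
})

test_that("exact rank test attains the enumeration minimum when all values exceed background", {
  vals <- 100 + seq_len(6)          # 6 community values, all above
  bg <- seq_len(15)                 # 15 background values
  res <- communitySignificance(vals, bg)
  expect_equal(res$p, 1 / choose(21, 6), tolerance = 1e-12)
  # depends on ranks only: any monotone transform gives the same P
  res2 <- communitySignificance(log(vals), sqrt(bg))
  expect_equal(res2$p, res$p, tolerance = 1e-12)
  # one-sidedness: all below -> P near 1
  resLow <- communitySignificance(-vals, bg)
  expect_gt(resLow$p, 0.99)
  # large strictly-above samples: minimal attainable for the approximation
  resBig <- communitySignificance(1000 + seq_len(45), runif(1000))
  expect_lt(resBig$p, 1e-6)
})

test_that("degenerate and unscorable inputs are flagged with P = 1", {
  expect_equal(communitySignificance(numeric(), 1:10)$flag, "unscorable")
  allTied <- communitySignificance(rep(1, 5), rep(1, 50))
  expect_equal(allTied$p, 1)
  expect_equal(allTied$flag, "degenerate")
})

test_that("null calibration: P is uniform when community equals background", {
  set.seed(29)
  ps <- replicate(400, {
    pool <- rnorm(120)
    communitySignificance(pool[1:20], pool[21:120])$p
  })
  expect_gt(mean(ps), 0.42)
  expect_lt(mean(ps), 0.58)
})

# strong-signal synthetic bundle shared by the next tests
strongBundle <- function(seed = 19) {
  ds <- generateDiseasome(syntheticConfig(backgroundRate = 0,
                                          contaminationRate = 0,
                                          seed = seed))
  part <- labelPartition(ds@labels)
  list(ds = ds, part = part, gs = geneSets(ds@genes))
}

test_that("planted communities are significant on every metric at strong signal", {
  b <- strongBundle()
  rep <- assessCohesion(b$part, geneSets = b$gs,
                        comorbidity = b$ds@comorbidity, dag = b$ds@dag,
                        semantic = b$ds@semantic, minSize = 10)
  s <- cohesionSummary(rep)
  expect_equal(s$nCommunities, 4L)
  expect_equal(unname(s$perMetric), rep.int(4L, 4))
  expect_equal(s$onAllMetrics, 4L)
  expect_equal(s$onAtLeastTwo, 4L)
  tab <- cohesionTable(rep)
  expect_true(all(tab$negLogP > 2))        # -log10 P > 2 <=> P < 0.01
  expect_true(all(tab$nScorable <= tab$nPairs))
})

test_that("label shuffling collapses significance to the false-positive level", {
  b <- strongBundle()
  set.seed(77)
  shuffled <- setNames(sample(unname(b$ds@labels)), names(b$ds@labels))
  rep <- assessCohesion(labelPartition(shuffled), geneSets = b$gs,
                        comorbidity = b$ds@comorbidity, dag = b$ds@dag,
                        semantic = b$ds@semantic, minSize = 10)
  tab <- cohesionTable(rep)
  # 16 community x metric tests at alpha 0.01: expect ~0 significant
  expect_lte(sum(tab$significant), 2L)
  expect_equal(cohesionSummary(rep)$onAllMetrics, 0L)
})

test_that("report is invariant under community relabelling and metric exclusion", {
  b <- strongBundle(seed = 23)
  full <- assessCohesion(b$part, geneSets = b$gs,
                         comorbidity = b$ds@comorbidity,
                         semantic = b$ds@semantic, minSize = 10)
  # permute community ids
  perm <- setNames(sample(1:4), 1:4)
  relabelled <- labelPartition(setNames(perm[as.character(b$ds@labels)],
                                        names(b$ds@labels)))
  full2 <- assessCohesion(relabelled, geneSets = b$gs,
                          comorbidity = b$ds@comorbidity,
                          semantic = b$ds@semantic, minSize = 10)
  t1 <- cohesionTable(full); t2 <- cohesionTable(full2)
  expect_equal(sort(t1$p), sort(t2$p), tolerance = 1e-12)

  # dropping a metric leaves the others' P values untouched
  sub <- assessCohesion(b$part, geneSets = b$gs,
                        semantic = b$ds@semantic, minSize = 10)
  ts <- cohesionTable(sub)
  for (mt in unique(ts$metric))
    expect_equal(ts$p[ts$metric == mt], t1$p[t1$metric == mt],
                 tolerance = 1e-12)
  # summary count consistency
  s <- cohesionSummary(full)
  expect_lte(s$onAllMetrics, min(s$perMetric))
  expect_gte(s$onAtLeastTwo, s$onAllMetrics)
})

test_that("process similarity z-score behaves at its extremes", {
  set.seed(41)
  terms <- c("t0", paste0("t", 1:6))
  parents <- c(list(t0 = character()),
               setNames(as.list(rep("t0", 6)), paste0("t", 1:6)))
  genes <- sprintf("g%02d", 1:30)
  geneTerms <- setNames(lapply(seq_along(genes), function(i)
    paste0("t", 1 + (i - 1) %% 6)), genes)
  dag <- annotationDAG(parents,
                       data.frame(gene = rep(genes, lengths(geneTerms)),
                                  term = unlist(geneTerms),
                                  evidence = "EXP"))
  # the process's own annotated genes score above random same-size draws
  own <- genes[vapply(geneTerms, function(t) "t1" %in% t, logical(1))]
  z1 <- processSimilarityZ(own, "t1", dag, genes, nRandom = 200, seed = 2)
  expect_gt(z1$z, 2)
  expect_equal(z1$flag, "ok")
  # uniform draws from the universe are unremarkable on average
  zs <- vapply(1:15, function(i) {
    g <- sample(genes, 5)
    processSimilarityZ(g, "t1", dag, genes, nRandom = 120, seed = i)$z
  }, numeric(1))
  expect_lt(abs(mean(zs)), 0.6)
  expect_error(processSimilarityZ(genes[1:3], "nope", dag, genes), "unknown")
})
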