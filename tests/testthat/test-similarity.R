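# The four disease-pair similarity measures.

test_that("relative risk matches the closed form and its invariances", {
  expect_equal(relativeRisk(10, 100, 50, 1000), 2.0)
  # independence: C = P_A P_B / N -> RR = 1
  expect_equal(relativeRisk(100 * 50 / 1000, 100, 50, 1000), 1.0)
  expect_equal(relativeRisk(0, 100, 50, 1000), 0)
  # scaling invariance under k > 0
  set.seed(3)
  for (rep in 1:10) {
    c0 <- runif(1, 0, 50); pa <- runif(1, 50, 200); pb <- runif(1, 50, 200)
    n <- runif(1, 1e3, 1e5); k <- runif(1, 0.1, 7)
    expect_equal(relativeRisk(k * c0, k * pa, k * pb, k * n),
                 relativeRisk(c0, pa, pb, n), tolerance = 1e-12)
  }
  expect_error(relativeRisk(1, 0, 50, 1000), "prevalence")
  expect_equal(logRelativeRisk(10, 100, 50, 1000), log10(2))
})

test_that("comorbidity table lookup distinguishes missing from zero", {
  ct <- comorbidityTable(
    data.frame(a = "d1", b = "d2", count = 30),
    c(d1 = 100, d2 = 200, d3 = 50), population = 1e4)
  expect_equal(comorbidityRR(ct, "d1", "d2"),
               relativeRisk(30, 100, 200, 1e4))
  # covered pair absent from counts -> C = 0 -> RR = 0
  expect_equal(comorbidityRR(ct, "d1", "d3"), 0)
  # unknown disease -> missing, not zero
  expect_true(is.na(comorbidityRR(ct, "d1", "nope")))
  # feasibility C_AB <= min(P_A, P_B) is enforced
  expect_error(comorbidityTable(data.frame(a = "d1", b = "d2", count = 500),
                                c(d1 = 100, d2 = 200), 1e4),
               "min")
})

test_that("gene Jaccard has its closed-form values and properties", {
  expect_equal(geneJaccard(c("a","b","c"), c("b","c","d")), 0.5)
  expect_equal(geneJaccard(c("a","b"), c("b","a")), 1.0)
  expect_equal(geneJaccard(c("a"), c("b")), 0)
  expect_true(is.na(geneJaccard(character(), character())))
  set.seed(5)
  for (rep in 1:20) {
    gA <- sample(letters, sample(0:8, 1))
    gB <- sample(letters, sample(1:8, 1))
    j <- geneJaccard(gA, gB)
    expect_equal(j, geneJaccard(gB, gA))
    expect_true(j >= 0 && j <= 1)
    expect_equal(j == 1, setequal(gA, gB))
  }
})

# small diamond hierarchy: t0 root; t1, t2 children; t3 has parents t1, t2
diamondDAG <- function() {
  annotationDAG(list(t0 = character(), t1 = "t0", t2 = "t0",
                     t3 = c("t1", "t2")),
                data.frame(gene = c("g1", "g2", "g3"),
                           term = c("t1", "t2", "t3"),
                           evidence = c("EXP", "IDA", "ISS")))
}

test_that("term ancestors climb the is-a relation with set semantics", {
  dag <- diamondDAG()
  expect_equal(termAncestors(dag, "t0"), "t0")
  expect_setequal(termAncestors(dag, "t1"), c("t1", "t0"))
  # diamond: union without duplicates
  anc <- termAncestors(dag, "t3")
  expect_setequal(anc, c("t3", "t1", "t2", "t0"))
  expect_equal(anyDuplicated(anc), 0L)
  expect_error(termAncestors(dag, "nope"), "unknown term")
})

test_that("term ancestors agree with the transitive-closure oracle on random DAGs", {
  set.seed(8)
  for (rep in 1:5) {
    nT <- sample(10:30, 1)
    terms <- sprintf("t%02d", seq_len(nT))
    # random DAG: parents drawn among earlier terms only (acyclic)
    parents <- setNames(lapply(seq_len(nT), function(i) {
      if (i == 1) return(character())
      k <- sample(0:min(3, i - 1), 1)
      if (k == 0) character() else sample(terms[seq_len(i - 1)], k)
    }), terms)
    dag <- annotationDAG(parents,
                         data.frame(gene = "g", term = terms[nT],
                                    evidence = "EXP"))
    for (t in sample(terms, 5))
      expect_setequal(termAncestors(dag, t), oracleAncestors(parents, t))
  }
})

test_that("construction rejects cycles and disallowed evidence codes", {
  expect_error(annotationDAG(list(t1 = "t2", t2 = "t1"),
                             data.frame(gene = "g", term = "t1",
                                        evidence = "EXP")),
               "acyclic")
  expect_error(annotationDAG(list(t0 = character()),
                             data.frame(gene = "g", term = "t0",
                                        evidence = "IEA")),
               "evidence")
})

test_that("readAnnotations filters namespace and evidence loudly", {
  fa <- withr::local_tempfile(fileext = ".tsv")
  fp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tterm\tevidence\tnamespace",
               "g1\tt1\tEXP\tBP", "g1\tt1\tIEA\tBP", "g2\tt0\tIDA\tMF"), fa)
  writeLines(c("child\tparent", "t1\tt0"), fp)
  expect_message(dag <- readAnnotations(fa, fp), "disallowed evidence")
  expect_equal(nrow(dag@annotations), 1L)
  expect_equal(dag@annotations$gene, "g1")
})

test_that("gene-set similarity reproduces hand-computed cases", {
  # root with two children; g1 -> t1, g2 -> t2; shared root only -> 0.5
  dag <- annotationDAG(list(t0 = character(), t1 = "t0", t2 = "t0"),
                       data.frame(gene = c("g1", "g2"),
                                  term = c("t1", "t2"),
                                  evidence = c("EXP", "EXP")))
  expect_equal(genesetBPSimilarity("g1", "g2", dag), 0.5)
  # identical annotation profiles -> 1
  dag2 <- annotationDAG(list(t0 = character(), t1 = "t0"),
                        data.frame(gene = c("g1", "g2"),
                                   term = c("t1", "t1"),
                                   evidence = c("EXP", "IMP")))
  expect_equal(genesetBPSimilarity(c("g1", "g2"), c("g1", "g2"), dag2), 1.0)
  # disjoint hierarchies sharing no root -> 0
  dag3 <- annotationDAG(list(r1 = character(), r2 = character(),
                             a = "r1", b = "r2"),
                        data.frame(gene = c("g1", "g2"),
                                   term = c("a", "b"),
                                   evidence = c("EXP", "EXP")))
  expect_equal(genesetBPSimilarity("g1", "g2", dag3), 0)
  # set with no annotated gene is unscorable
  expect_true(is.na(genesetBPSimilarity("unannotated", "g1", dag)))
})

test_that("gene-set similarity is symmetric, bounded and matches the brute-force evaluator", {
  set.seed(17)
  for (rep in 1:5) {
    terms <- c("t0", "t1", "t2", "t3", "t4")
    parents <- list(t0 = character(), t1 = "t0", t2 = "t0",
                    t3 = "t1", t4 = "t1")
    genes <- sprintf("g%d", 1:6)
    geneTerms <- setNames(lapply(genes, function(g)
      sample(terms[-1], sample(1:2, 1))), genes)
    ann <- data.frame(
      gene = rep(names(geneTerms), lengths(geneTerms)),
      term = unlist(geneTerms, use.names = FALSE),
      evidence = "EXP")
    dag <- annotationDAG(parents, ann)
    A <- sample(genes, 3); B <- sample(genes, 3)
    s <- genesetBPSimilarity(A, B, dag)
    expect_equal(s, genesetBPSimilarity(B, A, dag), tolerance = 1e-12)
    expect_true(s >= 0 && s <= 1)
    expect_equal(s, oracleBPSimilarity(A, B, parents, geneTerms),
                 tolerance = 1e-12)
    # extension bound: adding a gene b of B to A cannot push the similarity
    # below min(S(A,B), S({b},B)) -- both directional means are convex
    # combinations of the originals
    extra <- setdiff(B, A)
    if (length(extra)) {
      s2 <- genesetBPSimilarity(c(A, extra[1]), B, dag)
      sb <- genesetBPSimilarity(extra[1], B, dag)
      expect_gte(s2, min(s, sb) - 1e-12)
      expect_equal(s2, oracleBPSimilarity(c(A, extra[1]), B, parents,
                                          geneTerms), tolerance = 1e-12)
    }
  }
})

test_that("semantic lookup bands scores and marks missing pairs", {
  v <- matrix(c(1, 0.65, 0.65, 1), 2, 2,
              dimnames = list(c("d1", "d2"), c("d1", "d2")))
  m <- semanticMatrix(v)
  hit <- semanticSimilarity(m, "d1", "d2")
  expect_equal(hit$value, 0.65)
  expect_equal(hit$band, "significantly functionally similar")
  expect_equal(semanticBand(0.1), "uninformative")
  expect_equal(semanticBand(c(0.3, 0.6)), c("informative", "informative"))
  miss <- semanticSimilarity(m, "d1", "d9")
  expect_true(is.na(miss$value) && is.na(miss$band))
  # asymmetric or out-of-range inputs are rejected
  bad <- v; bad[1, 2] <- 0.2
  expect_error(semanticMatrix(bad), "symmetric")
})
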