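fixtureConcepts <- function(surfaces) {
  data.frame(surface = surfaces,
             nomenclature = rep("SNOMED3_ZH", length(surfaces)),
             conceptCode = sprintf("C%03d", seq_along(surfaces)),
             stringsAsFactors = FALSE)
}

test_that("queues rank an identical concept first with a perfect score", {
  concepts <- fixtureConcepts(c("头部疼痛", "颈部麻木", "发热"))
  prof <- list("头部疼痛" = c(A10 = 5, B20 = 3))
  prof[["颈部麻木"]] <- c(C30 = 4)
  prof[["发热"]] <- c(D40 = 7)
  st <- buildCorpusStats(prof)
  q <- buildQueue("头部疼痛", concepts, prof, st)
  cd <- candidates(q)
  expect_equal(cd$surface[1], "头部疼痛")
  expect_equal(cd$hs[1], 1.0)
  expect_true(all(diff(cd$hs) <= 1e-12))
  # empty concept set gives an empty queue
  expect_equal(nrow(candidates(buildQueue("头部疼痛",
                                          fixtureConcepts(character(0))))), 0L)
})

test_that("queue ordering is a lossless permutation with lexicographic ties", {
  concepts <- fixtureConcepts(c("乙乙", "甲甲", "丙丙"))
  q <- buildQueue("丁丁", concepts)   # all ls equal by construction? not quite
  cd <- candidates(q)
  expect_setequal(cd$surface, concepts$surface)
  # rebuild hs by brute force and compare the sort
  p <- simParams()
  hs <- vapply(concepts$surface, function(s)
    hybridSimilarity(literalSimilarity("丁丁", s, p), 0, p), numeric(1))
  ord <- order(-hs, concepts$surface, method = "radix")
  expect_equal(cd$surface, concepts$surface[ord])
})

test_that("screening applies a strict threshold in descending order", {
  concepts <- fixtureConcepts(c("头部疼痛", "咳嗽"))
  q1 <- buildQueue("头部疼痛头", concepts)
  q2 <- buildQueue("完全无关无", concepts)
  out <- screenPairs(list(q1, q2), reviewThreshold = 0.3)
  expect_true(all(out$hs > 0.3))
  expect_true(all(diff(out$hs) <= 1e-12))
  # all below threshold -> empty; exactly at threshold is excluded
  expect_equal(nrow(screenPairs(list(q1), reviewThreshold = 1)), 0L)
  fake <- new("MappingQueue", termSurface = "x",
              candidates = data.frame(surface = c("a", "b"),
                                      nomenclature = "SNOMED3_ZH",
                                      conceptCode = c("1", "2"),
                                      ls = c(0.31, 0.30), ds = 0,
                                      hs = c(0.31, 0.30),
                                      stringsAsFactors = FALSE))
  picked <- screenPairs(list(fake), reviewThreshold = 0.3)
  expect_equal(picked$surface, "a")
})

test_that("rank metrics match hand enumeration on a small fixture", {
  mk <- function(term, surfaces, hs) {
    new("MappingQueue", termSurface = term,
        candidates = data.frame(surface = surfaces,
                                nomenclature = "SNOMED3_ZH",
                                conceptCode = surfaces, ls = hs, ds = 0,
                                hs = hs, stringsAsFactors = FALSE))
  }
  queues <- list(
    t1 = mk("t1", c("a", "b", "c"), c(0.9, 0.8, 0.7)),  # gold a -> rank 1
    t2 = mk("t2", c("a", "b", "c"), c(0.9, 0.8, 0.7)),  # gold c -> rank 3
    t3 = mk("t3", c("a", "b", "c"), c(0.9, 0.8, 0.7)))  # gold b -> rank 2
  gold <- c(t1 = "a", t2 = "c", t3 = "b")
  rm_ <- rankMetrics(queues, gold, ks = c(1, 2, 3))
  expect_equal(rm_$averageRank, 2)
  expect_equal(unname(rm_$topKCoverage), c(1 / 3, 2 / 3, 1))
  expect_true(all(diff(rm_$topKCoverage) >= 0))   # coverage non-decreasing
  # gold absent from a queue counts at queue length + 1
  gold2 <- c(t1 = "zzz")
  expect_message(rm2 <- rankMetrics(queues["t1"], gold2, ks = c(1, 2, 3)),
                 "absent")
  expect_equal(rm2$averageRank, 4)
  expect_equal(unname(rm2$topKCoverage["3"]), 0)
  # detection-rate bins partition all candidate pairs
  expect_equal(sum(rm_$detectionRateByBin$n), 9L)
  expect_equal(sum(rm_$detectionRateByBin$nGold), 3L)
})

test_that("beta sweep reproduces its endpoints and prefers ls when ds is noise", {
  cc <- generateCorpus(generatorConfig(seed = 13, nRecords = 40))
  terms <- cc@conceptMap$term
  gold <- setNames(cc@conceptMap$conceptSurface, terms)
  prof <- profilesFromCooccur(cc@diagCooccur)
  # scramble profile assignment: diagnosis similarity becomes pure noise
  set.seed(99)
  names(prof) <- sample(names(prof))
  st <- buildCorpusStats(prof)
  sw <- sweepBeta(terms, cc@concepts, prof, st, gold,
                  betaGrid = c(0, 0.5, 1), combiners = "AS")
  best <- attr(sw, "best")
  expect_gte(best$beta, 0.5)
  # beta = 1 equals a pure-literal ranking
  qLs <- buildQueues(terms, cc@concepts, prof, st, simParams(beta = 1))
  expect_equal(sw$averageRank[sw$beta == 1],
               rankMetrics(qLs, gold)$averageRank)
})
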