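test_that("Jaro similarity matches hand-derived and degenerate cases", {
  expect_equal(jaroSim("发热", "发热"), 1)
  expect_equal(jaroSim("abc", "xyz"), 0)
  expect_equal(jaroSim("MARTHA", "MARHTA"), (1 + 1 + 5 / 6) / 3)
  expect_equal(jaroSim("", ""), 1)
  expect_equal(jaroSim("发热", ""), 0)
})

test_that("Jaro agrees with the brute-force oracle on random pairs", {
  set.seed(17)
  for (i in 1:1000) {
    s1 <- randomCjk(0, 8)
    s2 <- if (runif(1) < 0.3) s1 else randomCjk(0, 8)
    expect_equal(jaroSim(s1, s2), jaroOracle(s1, s2), tolerance = 1e-12)
  }
})

test_that("prefix and suffix Winkler bonuses follow the published form", {
  p <- simParams()
  expect_equal(jaroWinkler("头部疼痛", "腹部疼痛", p), 5 / 6)    # no prefix
  expect_equal(adjustedJaroWinkler("头部疼痛", "腹部疼痛", p),
               5 / 6 + 3 * 0.1 * (1 - 5 / 6))                    # suffix 部疼痛
  expect_equal(literalSimilarity("头部疼痛", "腹部疼痛", p),
               adjustedJaroWinkler("头部疼痛", "腹部疼痛", p))
  expect_equal(jaroWinkler("发热", "发热", p), 1)
  expect_equal(adjustedJaroWinkler("发热", "发热", p), 1)
  # no common affix: both reduce to plain Jaro
  expect_equal(jaroWinkler("发热", "咳热嗽", p), jaroSim("发热", "咳热嗽"))
  # the prefix/suffix length entering the bonus is capped
  long1 <- "甲乙丙丁戊己庚辛"; long2 <- "甲乙丙丁戊己庚壬"
  jd <- jaroSim(long1, long2)
  expect_equal(jaroWinkler(long1, long2, p), jd + 4 * 0.1 * (1 - jd))
})

test_that("similarity metrics are symmetric, bounded and dominate Jaro", {
  set.seed(23)
  p <- simParams()
  for (i in 1:300) {
    s1 <- randomCjk(0, 8); s2 <- randomCjk(0, 8)
    jd <- jaroSim(s1, s2)
    jw <- jaroWinkler(s1, s2, p)
    aj <- adjustedJaroWinkler(s1, s2, p)
    ls <- literalSimilarity(s1, s2, p)
    for (v in c(jd, jw, aj, ls)) { expect_gte(v, 0); expect_lte(v, 1) }
    expect_gte(jw, jd - 1e-12)
    expect_gte(aj, jd - 1e-12)
    expect_equal(jaroSim(s2, s1), jd)
    expect_equal(literalSimilarity(s2, s1, p), ls)
  }
})

test_that("TF-IDF weights follow the published scheme", {
  stats <- structure(list(totalDiagnoses = 100,
                          docFreq = c(C20 = 10L, I10 = 50L),
                          catTotals = c(C20 = 10, I10 = 10)),
                     class = "CorpusDiagnosisStats")
  w <- buildWeightVector(c(C20 = 5, I10 = 5), stats)
  expect_equal(w, c(C20 = 5.0, I10 = 1.0))
  # single category with df = |D| gives weight 1 (tf = idf = 1)
  stats1 <- structure(list(totalDiagnoses = 4, docFreq = c(A10 = 4L),
                           catTotals = c(A10 = 9)),
                      class = "CorpusDiagnosisStats")
  expect_equal(buildWeightVector(c(A10 = 9), stats1), c(A10 = 1.0))
  # negated expressions are excluded from the scheme
  expect_length(buildWeightVector(c(C20 = 5), stats, surface = "无发热"), 0L)
  # unknown category is an error naming the category
  expect_error(buildWeightVector(c(Z99 = 1), stats), "Z99")
})

test_that("per-term tf sums to one and corpus stats count documents", {
  cc <- generateCorpus(generatorConfig(seed = 9, nRecords = 30))
  prof <- profilesFromCooccur(cc@diagCooccur)
  st <- buildCorpusStats(prof)
  expect_equal(st$totalDiagnoses, length(st$docFreq))
  expect_true(all(st$docFreq >= 1))
  expect_true(all(st$docFreq <= length(prof)))
  p <- simParams()
  for (tm in head(names(prof), 20)) {
    w <- buildWeightVector(prof[[tm]], st, p, surface = tm)
    tf <- prof[[tm]] / sum(prof[[tm]])
    expect_equal(sum(tf), 1)
    expect_true(all(w >= 0) && all(is.finite(w)))
  }
})

test_that("cosine diagnosis similarity handles sparsity and zero norms", {
  v <- c(A10 = 2, B20 = 3)
  expect_equal(diagnosisSimilarity(v, v), 1)
  expect_equal(diagnosisSimilarity(c(A10 = 1), c(B20 = 1)), 0)
  expect_equal(diagnosisSimilarity(c(A10 = 3, B20 = 4), c(A10 = 4, B20 = 3)),
               24 / 25)
  expect_equal(diagnosisSimilarity(setNames(numeric(0), character(0)), v), 0)
})

test_that("hybrid similarity matches both combiners and is monotone", {
  expect_equal(hybridSimilarity(0.8, 0.5, simParams(beta = 0.6)), 0.68)
  expect_equal(hybridSimilarity(0.8, 0.5, simParams(beta = 0.6,
                                                    combiner = "QS")),
               sqrt(0.484))
  # beta = 1 degenerates to pure literal similarity under both combiners
  for (cb in c("AS", "QS"))
    expect_equal(hybridSimilarity(0.37, 0.92, simParams(beta = 1,
                                                        combiner = cb)), 0.37)
  set.seed(31)
  for (i in 1:200) {
    p <- simParams(beta = runif(1), combiner = sample(c("AS", "QS"), 1))
    ls <- runif(1); ds <- runif(1)
    h <- hybridSimilarity(ls, ds, p)
    expect_gte(h, 0); expect_lte(h, 1)
    dl <- runif(1, 0, 1 - ls); dd <- runif(1, 0, 1 - ds)
    expect_gte(hybridSimilarity(ls + dl, ds, p), h - 1e-12)
    expect_gte(hybridSimilarity(ls, ds + dd, p), h - 1e-12)
  }
})
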