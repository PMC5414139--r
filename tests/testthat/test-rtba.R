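lex <- defaultKeywordLexicon()

test_that("reverse maximum matching takes the longest term from the right", {
  d <- fixtureDictionary()
  sp <- rmmMatch("患者发热咳嗽", d)
  expect_equal(sp$start, c(2L, 4L))
  expect_equal(sp$end, c(4L, 6L))
  expect_equal(sp$surface, c("发热", "咳嗽"))
  expect_equal(nrow(rmmMatch("abc", d)), 0L)
  # a substring permutation is not a dictionary surface
  expect_equal(nrow(rmmMatch("血压高", d)), 0L)
})

test_that("reverse maximum matching agrees with the enumeration oracle", {
  set.seed(29)
  pool <- CJK_POOL
  for (i in 1:1000) {
    nTerms <- sample(3:30, 1)
    surfaces <- unique(replicate(nTerms, randomCjk(1, 4, pool)))
    d <- termDictionary(data.frame(surface = surfaces, frequency = 1,
                                   source = "CCC", status = "CANDIDATE"))
    clause <- paste(sample(pool, sample(1:50, 1), replace = TRUE),
                    collapse = "")
    got <- rmmMatch(clause, d)
    want <- rmmOracle(clause, surfaces)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$surface, want$surface)
  }
})

test_that("exception contexts invalidate contained matches only", {
  d <- fixtureDictionary()
  sp <- rmmMatch("进入多尿期", d)
  expect_equal(sp$surface, "多尿")
  expect_equal(nrow(filterExceptions(sp, "进入多尿期", lex)), 0L)

  sp2 <- rmmMatch("最高血压180", d)
  expect_equal(sp2$surface, "高血压")
  expect_equal(nrow(filterExceptions(sp2, "最高血压180", lex)), 0L)

  sp3 <- rmmMatch("多尿3天", d)
  expect_equal(filterExceptions(sp3, "多尿3天", lex)$surface, "多尿")
})

test_that("aggregation index registers residuals of shared affixes", {
  d <- termDictionary(data.frame(surface = c("颈部麻木", "肩部麻木"),
                                 frequency = 1, source = "CCC",
                                 status = "VALID"))
  idx <- buildAggregationIndex(d)
  af <- idx@affixes
  pre <- af[af$side == "prefix", ]
  expect_true(any(pre$term == "肩部麻木" & pre$affix == "颈" &
                    pre$constituent == "颈部麻木"))
  expect_true(any(pre$term == "颈部麻木" & pre$affix == "肩" &
                    pre$constituent == "肩部麻木"))

  d2 <- termDictionary(data.frame(surface = c("abc", "abd"), frequency = 1,
                                  source = "CCC", status = "CANDIDATE"))
  suf <- buildAggregationIndex(d2)@affixes
  expect_setequal(suf$side, "suffix")
  expect_true(any(suf$term == "abc" & suf$affix == "d"))
  expect_true(any(suf$term == "abd" & suf$affix == "c"))

  one <- termDictionary(data.frame(surface = "abc", frequency = 1,
                                   source = "CCC", status = "CANDIDATE"))
  expect_equal(nrow(buildAggregationIndex(one)@affixes), 0L)
})

test_that("accepted affixes expand aggregated surfaces; others only tally", {
  d <- termDictionary(data.frame(surface = c("颈部麻木", "肩部麻木"),
                                 frequency = 1, source = "CCC",
                                 status = "VALID"))
  idxPending <- buildAggregationIndex(d)
  sp <- rmmMatch("颈肩部麻木", d)
  expect_equal(sp$surface, "肩部麻木")
  # unaccepted: no new span, but the observation is tallied
  ex <- expandAggregations(sp, "颈肩部麻木", idxPending)
  expect_equal(nrow(ex$spans), 1L)
  af <- ex$index@affixes
  expect_equal(af$frequency[af$term == "肩部麻木" & af$affix == "颈"], 1L)

  idxAcc <- buildAggregationIndex(d, accepted = data.frame(
    term = "肩部麻木", affix = "颈", side = "prefix"))
  ex2 <- expandAggregations(sp, "颈肩部麻木", idxAcc)
  expect_equal(nrow(ex2$spans), 2L)
  agg <- ex2$spans[ex2$spans$origin == "RTBA_AGG", ]
  expect_equal(agg$surface, "颈部麻木")
  expect_equal(c(agg$start, agg$end), c(0L, 5L))
  # no adjacent affix: nothing changes
  ex3 <- expandAggregations(rmmMatch("肩部麻木", d), "肩部麻木", idxAcc)
  expect_equal(nrow(ex3$spans), 1L)
  expect_equal(sum(ex3$index@affixes$frequency), 0L)
})

test_that("negation is cue- and clause-bounded on both sides", {
  d <- fixtureDictionary()
  r1 <- recognize("无发热", d, lex)
  expect_true(r1$spans$negated)
  r2 <- recognize("发热消失", d, lex)
  expect_true(r2$spans$negated)
  r3 <- recognize("发热3天", d, lex)
  expect_false(r3$spans$negated)
  # an intervening recognised span blocks the cue
  r4 <- recognize("无咳嗽发热", d, lex)
  expect_equal(r4$spans$surface, c("咳嗽", "发热"))
  expect_equal(r4$spans$negated, c(TRUE, FALSE))
  # negation does not cross a clause boundary
  r5 <- recognize("无咳嗽,发热", d, lex)
  expect_equal(r5$spans$negated, c(TRUE, FALSE))
})

test_that("the full pipeline composes and reports BIEO over primary spans", {
  d <- fixtureDictionary()
  r <- recognize("患者发热3天,无咳嗽", d, lex)
  expect_equal(r$spans$surface, c("发热", "咳嗽"))
  expect_equal(r$spans$negated, c(FALSE, TRUE))
  expect_equal(r$spans$start, c(2L, 8L))
  expect_equal(tagSeq(r$tagged),
               c("O", "O", "B", "E", "O", "O", "O", "O", "B", "E"))
  # no dictionary hits: all O, empty span list
  r0 <- recognize("xyz", d, lex)
  expect_equal(nrow(r0$spans), 0L)
  expect_true(all(tagSeq(r0$tagged) == "O"))
  # text equal to one long term: B I ... E across the whole text
  dLong <- fixtureDictionary("左侧腰背部放射疼痛")
  rl <- recognize("左侧腰背部放射疼痛", dLong, lex)
  tg <- tagSeq(rl$tagged)
  expect_equal(tg[1], "B")
  expect_equal(tg[length(tg)], "E")
  expect_true(all(tg[2:(length(tg) - 1)] == "I"))
})

test_that("modifiers mingled in a term are spanned by the second pass", {
  d <- fixtureDictionary()
  r <- recognize("颈部明显麻木2周", d, lex)
  expect_equal(r$spans$surface, "颈部明显麻木")
  expect_equal(c(r$spans$start, r$spans$end), c(0L, 6L))
})

test_that("BIEO grammar holds for recogniser output on random text", {
  set.seed(37)
  d <- fixtureDictionary()
  for (i in 1:100) {
    txt <- paste(sample(c(CJK_POOL, "，", "。", "无"), sample(1:40, 1),
                        replace = TRUE), collapse = "")
    tg <- tagSeq(recognize(txt, d, lex)$tagged)
    expect_true(isValidBieo(tg))
  }
  expect_false(isValidBieo(c("I", "E")))
  expect_false(isValidBieo(c("B", "I", "O")))
  expect_true(isValidBieo(c("B", "O", "B", "I", "E")))
})
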