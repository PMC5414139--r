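test_that("feature tables carry the configured columns row per code point", {
  cfg <- featureConfig(cws = 1, ngrams = c("U", "B"))
  tb <- featurize("发热", cfg)
  expect_equal(nrow(tb), 2L)
  expect_equal(names(tb), c("char", "ngramU", "ngramB"))
  expect_equal(tb$ngramU, c("发", "热"))
  expect_equal(tb$ngramB, c("_NULL_", "发热"))

  bare <- featurize("发热咳嗽", featureConfig(cws = 0, ngrams = character(0)))
  expect_equal(names(bare), "char")
  expect_equal(nrow(bare), 4L)

  scfg <- featureConfig(ngrams = "U", stopChar = TRUE)
  st <- featurize("发的热", scfg, stopChars = c("的"))
  expect_equal(st$stopFlag, c("0", "1", "0"))
})

test_that("word features project token attributes onto characters", {
  cfg <- featureConfig(ngrams = "U", currentWord = TRUE, pos = TRUE,
                       contextWord = TRUE, assocStrength = TRUE)
  adapter <- maxMatchTokenizer(c("发热", "咳嗽"))
  assoc <- buildAssocTable(list(rep(c("发热", "咳嗽"), 10)))
  tb <- featurize("发热咳嗽了", cfg, adapter, assocTable = assoc)
  expect_equal(tb$word, c("发热", "发热", "咳嗽", "咳嗽", "了"))
  expect_equal(tb$pos, c("n", "n", "n", "n", "x"))
  expect_equal(tb$prevWord, c("_NULL_", "_NULL_", "发热", "发热", "咳嗽"))
  expect_equal(tb$nextWord, c("咳嗽", "咳嗽", "了", "了", "_NULL_"))
  # association flag sits on the last character before a word boundary
  expect_equal(tb$assocFlag[1], "_NULL_")
  expect_equal(tb$assocFlag[2], "1")     # 发热 -> 咳嗽 is combined
  expect_equal(tb$assocFlag[4], "0")     # 咳嗽 -> 了 never co-occurred... unseen
  # an adapter that does not cover the text exactly is rejected
  badAdapter <- function(text) data.frame(word = "发", pos = "x")
  expect_error(featurize("发热", cfg, badAdapter), "cover")
})

test_that("chi-square adjacency gate matches the published critical value", {
  expect_equal(chiSquareAdjacent(5, 5, 5, 5)$statistic, 0)
  expect_false(chiSquareAdjacent(5, 5, 5, 5)$combined)
  x <- chiSquareAdjacent(10, 0, 0, 10)
  expect_equal(x$statistic, 20)
  expect_true(x$combined)
  expect_equal(chiSquareAdjacent(1, 1, 1, 1)$statistic, 0)
  expect_warning(z <- chiSquareAdjacent(0, 0, 3, 4), "zero marginal")
  expect_equal(z$statistic, 0)
  # invariance under simultaneous row/column swap of the 2x2 table
  set.seed(43)
  for (i in 1:50) {
    v <- sample(1:30, 4, replace = TRUE)
    expect_equal(chiSquareAdjacent(v[1], v[2], v[3], v[4])$statistic,
                 chiSquareAdjacent(v[4], v[3], v[2], v[1])$statistic)
  }
})

test_that("training files and templates follow the engine contract", {
  cfg <- featureConfig(cws = 2, ngrams = c("U", "B"))
  t1 <- featurize("发热", cfg, goldTags = c("B", "E"))
  t2 <- featurize("咳嗽", cfg, goldTags = c("B", "E"))
  path <- withr::local_tempfile(fileext = ".crf")
  emitTrainingFile(list(t1, t2), path)
  lines <- readLines(path, encoding = "UTF-8")
  expect_equal(sum(lines == ""), 1L)             # one separator line
  expect_equal(lines[1], "发\t发\t_NULL_\tB")
  expect_error(emitTrainingFile(list(t1, t1[, -2]), path), "ragged")

  tmplPath <- withr::local_tempfile(fileext = ".txt")
  emitTemplate(cfg, tmplPath)
  tmpl <- readLines(tmplPath)
  rules <- grep("^U", tmpl, value = TRUE)
  # 3 feature columns x offsets -2..2
  expect_length(rules, 15L)
  expect_true(all(grepl("^U[0-9]+:%x\\[-?[0-2],[0-2]\\]$", rules)))
  offs <- as.integer(sub("^U[0-9]+:%x\\[(-?[0-9]+),.*$", "\\1", rules))
  expect_setequal(offs, -2:2)
  expect_equal(tmpl[length(tmpl)], "B")
})

test_that("greedy forward selection follows the add-if-it-gains rule", {
  fOf <- function(cfg) {
    on <- c(cfg$stopChar, cfg$currentWord, cfg$contextWord, cfg$pos,
            cfg$assocStrength)
    key <- paste(as.integer(on), collapse = "")
    tab <- c("00000" = 0.80,
             "10000" = 0.81, "01000" = 0.83, "00100" = 0.79,
             "11000" = 0.825,               # stopChar on top of currentWord
             "01100" = 0.82)
    unname(tab[key])
  }
  sel <- greedyFeatureSelection(featureConfig(ngrams = "U"),
                                c("stopChar", "currentWord", "contextWord"),
                                fOf)
  # hand simulation: alone-gains cw +0.03 > sc +0.01 > ctx -0.01;
  # cw retained (0.83), sc then drops F (0.825), ctx drops F (0.82)
  expect_true(sel$bestConfig$currentWord)
  expect_false(sel$bestConfig$stopChar)
  expect_false(sel$bestConfig$contextWord)
  expect_equal(sel$bestF, 0.83)
  expect_equal(nrow(sel$roundLog), 7L)  # baseline + 3 singles + 3 adds

  # all candidates hurting: baseline wins
  selNeg <- greedyFeatureSelection(featureConfig(ngrams = "U"),
                                   c("stopChar", "contextWord"),
                                   function(cfg) {
                                     if (cfg$stopChar || cfg$contextWord) 0.7
                                     else 0.8
                                   })
  expect_equal(selNeg$bestF, 0.8)
  expect_false(selNeg$bestConfig$stopChar || selNeg$bestConfig$contextWord)
})

test_that("tag decoding recovers spans and repairs malformed runs", {
  ch <- strsplit("发热", "")[[1]]
  sp <- decodeTags(ch, c("B", "E"))
  expect_equal(c(sp$start, sp$end, sp$surface), c("0", "2", "发热"))
  expect_equal(nrow(decodeTags(ch, c("O", "O"))), 0L)
  expect_message(rep_ <- decodeTags(strsplit("发热了", "")[[1]],
                                    c("B", "I", "O")), "repaired")
  expect_equal(c(rep_$start, rep_$end), c(0L, 2L))
  expect_message(stray <- decodeTags(ch, c("O", "E")), "stray")
  expect_equal(nrow(stray), 0L)
  expect_error(decodeTags(ch, "B"), "equal length")
})

test_that("a memorising mock engine reproduces gold spans end to end", {
  cc <- generateCorpus(generatorConfig(seed = 21, nRecords = 30))
  cfg <- featureConfig(cws = 1, ngrams = c("U", "B"))
  texts <- head(cc@hpi, 10)
  tables <- lapply(seq_along(texts), function(r) {
    spans <- cc@goldSpans[cc@goldSpans$recordId == r, , drop = FALSE]
    spans$origin <- "GOLD"
    featurize(texts[r], cfg, goldTags = tagSeq(spansToBieo(texts[r], spans)))
  })
  # mock linear-chain engine: memorises the training rows verbatim
  mockPredict <- function(table, record) tables[[record]]$tag
  for (r in seq_along(texts)) {
    feats <- featurize(texts[r], cfg)
    pred <- mockPredict(feats, r)
    expect_equal(nrow(feats), length(strsplit(texts[r], "")[[1]]))
    spans <- decodeTags(strsplit(texts[r], "")[[1]], pred)
    gold <- cc@goldSpans[cc@goldSpans$recordId == r, c("start", "end"),
                        drop = FALSE]
    expect_equal(spans[, c("start", "end")], gold, ignore_attr = TRUE)
  }
})
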