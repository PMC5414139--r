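# Independent brute-force oracles used by the property suites. These
# deliberately restate the definitions (flag arrays, full occurrence
# enumeration, explicit contingency tables) rather than reusing package code.

# Jaro similarity via explicit match-flag arrays and matched-subsequence
# comparison.
jaroOracle <- function(s1, s2) {
  a <- strsplit(enc2utf8(s1), "")[[1]]
  b <- strsplit(enc2utf8(s2), "")[[1]]
  la <- length(a); lb <- length(b)
  if (la == 0L && lb == 0L) return(1)
  if (la == 0L || lb == 0L) return(0)
  w <- max(floor(max(la, lb) / 2) - 1, 0)
  fa <- logical(la); fb <- logical(lb)
  for (i in seq_len(la)) {
    lo <- max(1L, i - w); hi <- min(lb, i + w)
    if (lo > hi) next
    for (j in lo:hi) {
      if (!fb[j] && a[i] == b[j]) { fa[i] <- TRUE; fb[j] <- TRUE; break }
    }
  }
  m <- sum(fa)
  if (m == 0L) return(0)
  t <- sum(a[fa] != b[fb]) / 2
  (m / la + m / lb + (m - t) / m) / 3
}

# Reverse maximum matching restated as: enumerate every occurrence of every
# dictionary surface, then from the right repeatedly take the longest
# occurrence ending at the current scan position.
rmmOracle <- function(clause, surfaces, maxLen = 16L) {
  ch <- strsplit(enc2utf8(clause), "")[[1]]
  n <- length(ch)
  occ <- list()
  for (s in surfaces) {
    sc <- strsplit(enc2utf8(s), "")[[1]]
    L <- length(sc)
    if (L == 0L || L > n || L > maxLen) next
    for (st in seq_len(n - L + 1L)) {
      if (all(ch[st:(st + L - 1L)] == sc))
        occ[[length(occ) + 1L]] <- c(start = st - 1L, end = st - 1L + L)
    }
  }
  occ <- if (length(occ)) do.call(rbind, occ) else
    matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end")))
  picked <- list()
  e <- n
  while (e >= 1L) {
    here <- occ[occ[, "end"] == e, , drop = FALSE]
    if (nrow(here) == 0L) { e <- e - 1L; next }
    best <- here[which.max(here[, "end"] - here[, "start"]), ]
    picked[[length(picked) + 1L]] <- best
    e <- best[["start"]]
  }
  if (length(picked) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      surface = character(0)))
  m <- do.call(rbind, rev(picked))
  data.frame(start = as.integer(m[, "start"]), end = as.integer(m[, "end"]),
             surface = vapply(seq_len(nrow(m)), function(i)
               paste(ch[(m[i, "start"] + 1L):m[i, "end"]], collapse = ""),
               ""))
}

# Cohen's kappa from the full contingency table, spelled out.
kappaOracle <- function(l1, l2) {
  cats <- union(unique(l1), unique(l2))
  tab <- matrix(0, length(cats), length(cats), dimnames = list(cats, cats))
  for (i in seq_along(l1)) tab[l1[i], l2[i]] <- tab[l1[i], l2[i]] + 1
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - pe) < 1e-12) return(if (abs(1 - po) < 1e-12) 1 else 0)
  (po - pe) / (1 - pe)
}

# Pool of real CJK code points for random-string generation, so Unicode
# paths are exercised.
CJK_POOL <- strsplit("头颈肩腰背胸腹膝肘腕踝痛麻木肿胀热晕咳嗽", "")[[1]]

randomCjk <- function(minLen = 1L, maxLen = 6L, pool = CJK_POOL) {
  paste(sample(pool, sample(minLen:maxLen, 1L), replace = TRUE),
        collapse = "")
}

# A tiny fixed dictionary + lexicon shared across recogniser tests.
fixtureDictionary <- function(extra = character(0)) {
  termDictionary(data.frame(
    surface = c("发热", "咳嗽", "头部疼痛", "颈部麻木", "肩部麻木",
                "高血压", "多尿", "腹部肿胀", extra),
    frequency = 1L, source = "CCC", status = "VALID",
    stringsAsFactors = FALSE))
}
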