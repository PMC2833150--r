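iidBg <- function(p = 0.5) {
  backgroundModel(c("X", "Y"), matrix(c(p, 1 - p, p, 1 - p), 2, 2,
                                      byrow = TRUE),
                  initial = c(p, 1 - p))
}

test_that("background fitting recovers forced digram counts", {
  bg <- fitBackground(c("ABAB", "ABAB"))
  tr <- transitionMatrix(bg)
  expect_equal(unname(tr["A", "B"]), 1)
  expect_equal(unname(tr["B", "A"]), 1)
  expect_equal(unname(initialProbs(bg)), c(1, 0))
  expect_equal(bg@totalLetters, 8L)
})

test_that("fitted transitions equal digram-count oracle ratios", {
  set.seed(19)
  alph <- c("B", "G", "F", "K")
  seqs <- vapply(1:30, function(i)
    paste(sample(alph, sample(5:15, 1), replace = TRUE), collapse = ""), "")
  bg <- fitBackground(seqs)
  ## oracle: raw digram counts
  dig <- matrix(0, 4, 4, dimnames = list(alph, alph))
  for (s in seqs) {
    ch <- strsplit(s, "")[[1]]
    for (t in seq_len(length(ch) - 1))
      dig[ch[t], ch[t + 1]] <- dig[ch[t], ch[t + 1]] + 1
  }
  expect_equal(unname(transitionMatrix(bg)[alph, alph]),
               unname(dig / rowSums(dig)))
})

test_that("letters never seen as source get a uniform row with a warning", {
  expect_warning(bg <- fitBackground(c("AB", "AB"), alphabet = c("A", "B", "C")),
                 "uniform")
  expect_equal(unname(transitionMatrix(bg)["B", ]), rep(1 / 3, 3))
  expect_error(fitBackground(c("ABZ"), alphabet = c("A", "B")), "absent")
  expect_error(fitBackground(character()), "empty")
  expect_error(fitBackground("AB", order = 2), "first-order")
})

test_that("exact DP reproduces the enumerated two-letter worked case", {
  bg <- iidBg(0.5)
  r1 <- wordPvalue("XY", bg, lengths = 4, observed = 1)
  expect_equal(r1$p_over, 11 / 16, tolerance = 1e-12)
  r2 <- wordPvalue("XY", bg, lengths = 4, observed = 2)
  expect_equal(r2$p_over, 1 / 16, tolerance = 1e-12)
})

test_that("overlapping occurrences are counted with automaton semantics", {
  expect_equal(naiveWordCount("XX", "XXXX"), 3)
  bg <- iidBg(0.5)
  r <- wordPvalue("XX", bg, lengths = 4, observed = 3, cmax = 5)
  ## P(X = 3 overlapping XX in XXXX) = P(XXXX) = 1/16
  expect_equal(r$p_over, 1 / 16, tolerance = 1e-12)
})

test_that("zero observations and zero-probability words behave at the edges", {
  bg <- iidBg(0.5)
  r <- wordPvalue("XY", bg, lengths = 4, observed = 0)
  expect_equal(r$p_over, 1)
  expect_equal(r$p_under, 1 - 11 / 16, tolerance = 1e-12)
  ## word with an impossible transition
  tr <- matrix(c(1, 0, 0.5, 0.5), 2, 2, byrow = TRUE)
  bg0 <- backgroundModel(c("X", "Y"), tr, initial = c(1, 0))
  r0 <- wordPvalue("XY", bg0, lengths = 6, observed = 2)
  expect_equal(r0$expected, 0)
  expect_equal(r0$p_over, 0)
  expect_error(wordPvalue("XZ", bg, lengths = 4, observed = 1), "alphabet")
})

test_that("DP expectation matches the analytic Markov expectation", {
  set.seed(23)
  alph <- c("B", "G", "F")
  tr <- matrix(runif(9) + 0.1, 3, 3); tr <- tr / rowSums(tr)
  bg <- backgroundModel(alph, tr, initial = c(0.2, 0.5, 0.3))
  lens <- c(5, 7, 7, 9)
  for (w in c("BG", "GFB", "FF")) {
    r <- wordPvalue(w, bg, lengths = lens, observed = 1, cmax = 30)
    pmf <- r$distribution[seq_len(31)]
    expect_lt(r$distribution[32], 1e-12)   # nothing in overflow
    expect_equal(sum(pmf), 1, tolerance = 1e-9)
    expect_equal(sum(pmf * 0:30), r$expected, tolerance = 1e-9)
  }
})

test_that("p_over and p_under always share the point mass at the observation", {
  set.seed(29)
  bg <- iidBg(0.3)
  for (obs in 0:4) {
    r <- wordPvalue("XYX", bg, lengths = c(6, 8), observed = obs)
    expect_gte(r$p_over + r$p_under, 1 - 1e-12)
    expect_true(r$p_over >= 0 && r$p_over <= 1)
    expect_true(r$p_under >= 0 && r$p_under <= 1)
  }
})

test_that("exact DP equals full enumeration on mixed-length Markov corpora", {
  alph <- c("X", "Y")
  tr <- matrix(c(0.7, 0.3, 0.4, 0.6), 2, 2, byrow = TRUE)
  init <- c(0.55, 0.45)
  bg <- backgroundModel(alph, tr, initial = init)
  cases <- list(list(w = "XY", lens = c(3, 5)),
                list(w = "XX", lens = c(4, 4)),
                list(w = "YXY", lens = 6),
                list(w = "XXY", lens = c(2, 4, 5)))
  for (cs in cases) {
    ref <- enumCountDist(cs$w, alph, tr, init, cs$lens)
    maxc <- length(ref) - 1
    for (obs in 0:maxc) {
      r <- wordPvalue(cs$w, bg, lengths = cs$lens, observed = obs,
                      cmax = maxc + 1)
      expect_equal(r$p_over, sum(ref[(obs + 1):(maxc + 1)]),
                   tolerance = 1e-9)
      expect_equal(r$p_under, sum(ref[1:(obs + 1)]), tolerance = 1e-9)
    }
  }
})

test_that("Monte-Carlo oracle is deterministic and agrees with enumeration", {
  bg <- iidBg(0.5)
  mc1 <- mcPvalueOracle("XY", bg, lengths = 4, observed = 1, nSim = 10000,
                        seed = 11)
  mc2 <- mcPvalueOracle("XY", bg, lengths = 4, observed = 1, nSim = 10000,
                        seed = 11)
  expect_identical(mc1, mc2)
  expect_lt(abs(mc1$p_over - 11 / 16), 3 * mc1$se_over + 1e-9)
  expect_true(mc1$p_over >= 0 && mc1$p_over <= 1)
  expect_error(mcPvalueOracle("XY", bg, lengths = 4, observed = 1,
                              nSim = 10), "1000")
})

test_that("L_p scores are signed log10 tails", {
  expect_equal(lpScore(10^-21.3, 1, observed = 64, expected = 10), 21.3)
  expect_equal(lpScore(1, 10^-17.7, observed = 5, expected = 50), -17.7)
  expect_equal(lpScore(1, 1, observed = 3, expected = 3), 0)
  expect_error(lpScore(NA, NA, 1, 1), "missing")
})

test_that("classification thresholds are strict and boundary-safe", {
  expect_equal(classifyWord(102.2), "OR")
  expect_equal(classifyWord(-2.8), "NS")
  expect_equal(classifyWord(-5.94), "NS")
  expect_equal(classifyWord(5.94), "NS")
  expect_equal(classifyWord(-5.95), "UR")
  expect_equal(classifyWord(c(7, 0, -8)), c("OR", "NS", "UR"))
})

test_that("score rescaling is a size-ratio multiplication with an inverse", {
  expect_equal(rescaleScores(10, 100, 200), 5)
  expect_equal(rescaleScores(10, 7, 7), 10)
  expect_equal(rescaleScores(rescaleScores(3.2, 50, 80), 80, 50), 3.2)
  expect_error(rescaleScores(1, 0, 10), "positive")
})

test_that("compound-Poisson approximation tracks the exact DP", {
  ## moderately long iid corpus where clumping matters for XX
  bg <- iidBg(0.5)
  lens <- rep(40, 25)
  for (w in c("XYX", "XX")) {
    exp0 <- wordPvalue(w, bg, lengths = lens, observed = 1)$expected
    obs <- ceiling(exp0 + 2 * sqrt(exp0))
    ex <- wordPvalue(w, bg, lengths = lens, observed = obs)
    ap <- wordPvalue(w, bg, lengths = lens, observed = obs,
                     method = "compound-poisson")
    expect_equal(ap$method, "compound-poisson")
    expect_equal(ex$method, "exact-dp")
    expect_equal(ap$p_over, ex$p_over, tolerance = 0.25)
    expect_equal(ap$expected, ex$expected, tolerance = 1e-9)
  }
})

test_that("planted motifs are called OR and suppressed motifs UR", {
  alph <- c("B", "G", "F", "K")
  tr <- matrix(1 / 4, 4, 4)
  bg <- backgroundModel(alph, tr, initial = rep(1 / 4, 4))
  gen <- genLetterSequences(500, lengths = 20, background = bg,
                            planted = data.frame(word = "BGFK", factor = 5),
                            seed = 99)
  fit <- fitBackground(gen$sequences, alphabet = alph)
  obs <- naiveWordCount("BGFK", gen$sequences)
  r <- wordPvalue("BGFK", fit, observed = obs)
  lp <- lpScore(r$p_over, r$p_under, obs, r$expected)
  expect_equal(classifyWord(lp), "OR")
  ## suppress a word: remove every sequence containing it
  keep <- !grepl("GFKB", gen$sequences)
  seqs2 <- gen$sequences[keep]
  fit2 <- fitBackground(seqs2, alphabet = alph)
  ## high-expectation word under the fitted background, never observed
  r2 <- wordPvalue("GFKB", fit2, lengths = fit2@lengths, observed = 0)
  lp2 <- lpScore(r2$p_over, r2$p_under, 0, r2$expected)
  expect_equal(classifyWord(lp2), "UR")
})

test_that("batch exceptionality table is consistent with its parts", {
  bg <- iidBg(0.5)
  tab <- wordExceptionality(list(XY = 3L, XX = 0L), bg, lengths = c(4, 4, 4))
  expect_equal(names(tab), c("word", "N_w", "expected", "p_over", "p_under",
                             "lp", "class", "method"))
  expect_equal(tab$class,
               classifyWord(tab$lp))
  r <- wordPvalue("XY", bg, lengths = c(4, 4, 4), observed = 3L)
  expect_equal(tab$p_over[tab$word == "XY"], r$p_over)
})
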