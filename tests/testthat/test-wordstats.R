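frag7 <- function(seed = 1, n = 7) {
  set.seed(seed)
  matrix(cumsum(rnorm(3 * n, sd = 2)), n, 3)
}

test_that("superposed RMSD: zero cases, symmetry, rigid-motion invariance", {
  A <- frag7(1)
  expect_equal(superposeRMSD(A, A), 0)
  B <- rigidMotion(A, seed = 2)
  expect_lt(superposeRMSD(A, B), 1e-6)
  C <- frag7(3)
  expect_equal(superposeRMSD(A, C), superposeRMSD(C, A), tolerance = 1e-10)
  expect_error(superposeRMSD(A, C[1:5, ]), "equal size")
})

test_that("superposed RMSD equals the quaternion oracle and bio3d", {
  for (seed in 1:6) {
    A <- frag7(seed * 11)
    B <- frag7(seed * 11 + 5)
    ours <- superposeRMSD(A, B)
    expect_equal(ours, quaternionRMSD(A, B), tolerance = 1e-8)
    bio <- bio3d::rmsd(as.vector(t(A)), as.vector(t(B)), fit = TRUE)
    expect_lt(abs(ours - bio), 6e-4)   # bio3d reports 3 decimals
  }
})

test_that("reflections are disallowed: mirrored fragments keep nonzero RMSD", {
  A <- frag7(9)
  M <- A %*% diag(c(1, 1, -1))       # improper transform
  expect_gt(superposeRMSD(A, M), 0.1)
})

mkCluster <- function(word, coordsList, seqs = character(),
                      b = numeric()) {
  n <- max(length(coordsList), length(seqs), length(b))
  new("WordCluster", word = word,
      fragments = data.frame(loop_id = if (n) paste0("l", seq_len(n))
                             else character(),
                             position = if (n) 1L else integer()),
      coords = coordsList, sequences = seqs, bfactors = b)
}

test_that("intra-word RMSD: identical members, determinism, exhaustive mean", {
  same <- mkCluster("BGFK", replicate(4, frag7(2), simplify = FALSE))
  expect_equal(intraWordRMSD(same, seed = 1), 0)

  cl <- mkCluster("BGFK", lapply(1:5, function(i) frag7(40 + i)))
  expect_identical(intraWordRMSD(cl, seed = 7), intraWordRMSD(cl, seed = 7))
  ## sample >= population: equals full pairwise mean from the oracle
  pairs <- combn(5, 2)
  oracle <- mean(apply(pairs, 2, function(p)
    quaternionRMSD(cl@coords[[p[1]]], cl@coords[[p[2]]])))
  expect_equal(intraWordRMSD(cl, nSample = 30, seed = 1), oracle,
               tolerance = 1e-8)
  ## undefined for singletons
  expect_true(is.na(intraWordRMSD(mkCluster("BGFK", list(frag7(1))))))
})

test_that("inter-word RMSD: degenerate and exhaustive cases", {
  a <- mkCluster("BGFK", list(frag7(1)))
  expect_equal(interWordRMSD(a, mkCluster("GZID", list(rigidMotion(frag7(1))))),
               0, tolerance = 1e-6)
  b <- mkCluster("GZID", list(frag7(5)))
  expect_equal(interWordRMSD(a, b), superposeRMSD(a@coords[[1]], b@coords[[1]]))
  A3 <- mkCluster("BGFK", lapply(1:3, function(i) frag7(60 + i)))
  B3 <- mkCluster("GZID", lapply(1:3, function(i) frag7(70 + i)))
  oracle <- mean(outer(1:3, 1:3, Vectorize(function(i, j)
    quaternionRMSD(A3@coords[[i]], B3@coords[[j]]))))
  expect_equal(interWordRMSD(A3, B3, nPairs = 30, seed = 1), oracle,
               tolerance = 1e-8)
  expect_error(interWordRMSD(a, mkCluster("X", list())), "non-empty")
})

test_that("Z-score arithmetic follows the Poisson standardization", {
  ## observed = expected gives Z = 0; mu at the validity boundary is masked
  bg <- matrix(200, 7, 20, dimnames = list(NULL, strsplit(
    "ACDEFGHIKLMNPQRSTVWY", "")[[1]]))
  obs <- matrix(10, 7, 20)
  p <- zscoreProfile(obs, bg, N = 1000, Nw = 50, word = "BGFK")
  expect_equal(unname(zMatrix(p)[1, 1]), 0)
  expect_true(all(validMask(p)))    # mu = 10 > 5

  bg5 <- matrix(100, 7, 20, dimnames = dimnames(bg))
  p5 <- zscoreProfile(obs, bg5, N = 1000, Nw = 50)
  expect_false(any(validMask(p5)))  # mu = 5 is not > 5
  expect_true(is.na(p5@zMax))
  expect_equal(p5@nbPosSig, 0L)

  obs2 <- matrix(10, 7, 20); obs2[3, 2] <- 20
  p2 <- zscoreProfile(obs2, bg, N = 1000, Nw = 50)
  expect_equal(unname(zMatrix(p2)[3, 2]), 10 / sqrt(10), tolerance = 1e-12)
  expect_equal(p2@zMax, 10 / sqrt(10), tolerance = 1e-12)
})

test_that("Poisson Z agrees in direction and scale with the binomial tail", {
  ## z-equivalent of the exact binomial tail for a moderately enriched cell
  N <- 10000; Nw <- 500; Nal <- 2000; obs <- 130
  mu <- Nal * Nw / N
  z <- (obs - mu) / sqrt(mu)
  pbin <- pbinom(obs - 1, Nw, Nal / N, lower.tail = FALSE)
  zbin <- qnorm(pbin, lower.tail = FALSE)
  expect_equal(z, zbin, tolerance = 0.15)
})

test_that("per-position observed counts always sum to the cluster size", {
  gen <- genFragmentSequences(40, seed = 5)
  cl <- mkCluster("BGFK", list(), seqs = gen$sequences)
  bg <- aaCounts(gen$sequences)
  p <- zscoreProfile(cl, bg, N = 40)
  expect_equal(unname(rowSums(p@observed)), rep(40, 7))
})

test_that("Z-profile input errors", {
  bg <- matrix(200, 7, 20)
  expect_error(zscoreProfile(matrix(1, 7, 20), bg, N = 0), "positive")
  expect_error(zscoreProfile(matrix(1, 7, 20), bg, N = 10, Nw = 20),
               "exceeds")
  expect_error(zscoreProfile(matrix(1, 6, 20), bg, N = 100, Nw = 10),
               "shape")
})

test_that("Z-score distances are Euclidean with masked cells zeroed", {
  bg <- matrix(200, 7, 20, dimnames = list(NULL, strsplit(
    "ACDEFGHIKLMNPQRSTVWY", "")[[1]]))
  mk <- function(obs) zscoreProfile(obs, bg, N = 1000, Nw = 50)
  o1 <- matrix(10, 7, 20)
  p1 <- mk(o1)
  expect_equal(zscoreDistance(p1, p1), 0)
  o2 <- o1; o2[1, 1] <- 10 + 3 * sqrt(10); o2[1, 2] <- 10 + 4 * sqrt(10)
  p2 <- mk(o2)
  expect_equal(zscoreDistance(p1, p2), 5, tolerance = 1e-10)
  ## direct recomputation on random profiles
  set.seed(77)
  oa <- matrix(rpois(140, 10), 7, 20); ob <- matrix(rpois(140, 10), 7, 20)
  pa <- mk(oa); pb <- mk(ob)
  za <- zMatrix(pa); za[!validMask(pa)] <- 0
  zb <- zMatrix(pb); zb[!validMask(pb)] <- 0
  expect_equal(zscoreDistance(pa, pb), sqrt(sum((za - zb)^2)))
})

test_that("KLD is zero iff the word matches the background distribution", {
  p0 <- c(short = 0.25, long = 0.75)
  r <- kldPreference(c(short = 25, long = 75), p0)
  expect_equal(r$kld, 0)
  expect_equal(r$p, 1)
  r2 <- kldPreference(c(short = 50, long = 50), p0)
  expect_equal(r2$kld, 0.5 * log(2) + 0.5 * log(2 / 3), tolerance = 1e-12)
  expect_equal(r2$stat, 2 * 100 * r2$kld)
  expect_equal(r2$df, 1)
  expect_equal(r2$preferred, "short")
})

test_that("KLD is invariant to type relabeling and handles empty types", {
  p0 <- c(aa = 0.2, ab = 0.3, ba = 0.1, bb = 0.4)
  cnt <- c(aa = 10, ab = 0, ba = 5, bb = 35)
  r <- kldPreference(cnt, p0)
  perm <- c("bb", "aa", "ba", "ab")
  r2 <- kldPreference(cnt[perm], p0[perm])
  expect_equal(r$kld, r2$kld)
  expect_equal(r$p, r2$p)
  expect_gte(r$kld, 0)
  expect_error(kldPreference(c(aa = 0, ab = 0), p0[1:2] * 0 + c(1, 0)),
               "no fragments|zero")
})

test_that("paper-style degrees of freedom are available as a switch", {
  p0 <- c(short = 0.5, long = 0.5)
  r <- kldPreference(c(short = 30, long = 70), p0, dfAsPaper = TRUE)
  expect_equal(r$df, 99)
})

test_that("loop-type preference table joins, adjusts and flags", {
  loops <- data.frame(
    loop_id = paste0("l", 1:8),
    letters = strrep("B", 6),
    length_class = rep(c("short", "long"), 4),
    flank_class = rep(c("aa", "bb"), each = 4),
    stringsAsFactors = FALSE)
  frag <- data.frame(
    loop_id = rep(loops$loop_id, each = 3),
    word = rep(c("BGFK", "GZID"), 12),
    stringsAsFactors = FALSE)
  tab <- loopTypePreference(frag, loops, "length")
  expect_setequal(tab$word, c("BGFK", "GZID"))
  expect_true(all(tab$p_adj >= tab$p - 1e-15))
  expect_true(all(tab$df == 1))
  tab8 <- loopTypePreference(frag, loops, "both")
  expect_true(all(tab8$df == 3))   # 4 occupied combinations in this bank
})
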