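## Independent oracles and small fixture builders used across the suite.
## Oracles deliberately use naive algorithms (enumeration, direct scans,
## quaternion superposition) that share no code with the implementation.

## ---- toy alphabet models --------------------------------------------

toyModel <- function(K = 3, d = 4, seed = 1, sep = 5) {
  set.seed(seed)
  letters <- c(LETTERS, "a")[seq_len(K)]
  tr <- matrix(runif(K * K) + 0.2, K, K)
  tr <- tr / rowSums(tr)
  mu <- matrix(rnorm(K * d, sd = 1), K, d) + sep * seq_len(K)
  new("AlphabetModel", letters = letters,
      initial = rep(1 / K, K), transitions = tr,
      emissionMean = mu, emissionCov = array(diag(d), c(d, d, K)))
}

fixtureModelPath <- function() {
  system.file("extdata", "fixture_alphabet.json", package = "loopwords")
}

## ---- Viterbi brute force --------------------------------------------

logdmvnormOracle <- function(x, mean, sigma) {
  d <- length(mean)
  as.numeric(-0.5 * t(x - mean) %*% solve(sigma) %*% (x - mean) -
             0.5 * log(det(sigma)) - 0.5 * d * log(2 * pi))
}

viterbiBruteForce <- function(descr, model) {
  K <- nStates(model)
  Tn <- nrow(descr)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), Tn)))
  ## expand.grid varies the first column fastest; order rows so that
  ## lexicographic (alphabet-order) paths come first for tie-breaking
  paths <- paths[do.call(order, as.data.frame(paths)), , drop = FALSE]
  lp <- apply(paths, 1, function(p) {
    v <- log(model@initial[p[1]]) +
      logdmvnormOracle(descr[1, ], model@emissionMean[p[1], ],
                       model@emissionCov[, , p[1]])
    if (Tn > 1) for (t in 2:Tn) {
      v <- v + log(model@transitions[p[t - 1], p[t]]) +
        logdmvnormOracle(descr[t, ], model@emissionMean[p[t], ],
                         model@emissionCov[, , p[t]])
    }
    v
  })
  best <- which.max(lp)   # first max = lexicographically smallest path
  list(letters = paste(model@letters[paths[best, ]], collapse = ""),
       logProb = lp[best])
}

## ---- naive word scanning --------------------------------------------

naiveWordPositions <- function(word, s) {
  m <- nchar(word); n <- nchar(s)
  if (n < m) return(integer())
  which(vapply(seq_len(n - m + 1), function(i)
    substr(s, i, i + m - 1) == word, TRUE))
}

naiveWordCount <- function(word, sequences) {
  sum(vapply(sequences, function(s) length(naiveWordPositions(word, s)), 0))
}

## ---- exhaustive occurrence-count distribution -----------------------

## exact distribution of the total count of `word` in a corpus whose
## sequence lengths are `lens`, under a first-order Markov background,
## by full enumeration of every possible corpus
enumCountDist <- function(word, alphabet, trans, init, lens) {
  dimnames(trans) <- list(alphabet, alphabet)
  names(init) <- alphabet
  seqProbs <- function(len) {
    combos <- expand.grid(rep(list(alphabet), len), stringsAsFactors = FALSE)
    s <- apply(combos, 1, paste, collapse = "")
    p <- apply(combos, 1, function(x) {
      pr <- init[x[1]]
      if (len > 1) for (t in 2:len) pr <- pr * trans[x[t - 1], x[t]]
      pr
    })
    cnt <- vapply(s, function(si) length(naiveWordPositions(word, si)), 0)
    tapply(p, cnt, sum)
  }
  dist <- c(`0` = 1)
  for (len in lens) {
    d1 <- seqProbs(len)
    new <- numeric(0)
    for (i in names(dist)) for (j in names(d1)) {
      k <- as.character(as.integer(i) + as.integer(j))
      new[k] <- (if (k %in% names(new)) new[k] else 0) + dist[[i]] * d1[[j]]
    }
    dist <- new
  }
  counts <- as.integer(names(dist))
  out <- numeric(max(counts) + 1)
  out[counts + 1] <- as.numeric(dist)
  out  # index c+1 = P(X = c)
}

## ---- quaternion superposition oracle --------------------------------

## optimal rotation via the Horn quaternion method (largest eigenvalue of
## the 4x4 key matrix); proper rotations only
quaternionRMSD <- function(A, B) {
  A <- sweep(A, 2, colMeans(A)); B <- sweep(B, 2, colMeans(B))
  M <- crossprod(A, B)
  Sxx <- M[1,1]; Sxy <- M[1,2]; Sxz <- M[1,3]
  Syx <- M[2,1]; Syy <- M[2,2]; Syz <- M[2,3]
  Szx <- M[3,1]; Szy <- M[3,2]; Szz <- M[3,3]
  Kmat <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,      -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,      -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lam <- max(eigen(Kmat, symmetric = TRUE, only.values = TRUE)$values)
  ssd <- sum(A^2) + sum(B^2) - 2 * lam
  sqrt(max(0, ssd) / nrow(A))
}

## random rigid motion applied to a point set
rigidMotion <- function(X, seed = 1) {
  set.seed(seed)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, 0, 2 * pi)
  Kx <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
  R <- diag(3) + sin(th) * Kx + (1 - cos(th)) * Kx %*% Kx
  sweep(X %*% t(R), 2, rnorm(3, sd = 5), `+`)
}

## ---- naive secondary-structure scanner ------------------------------

naiveSegmentLabels <- function(s, helixSet = c("A","a","V","W"), minH = 4,
                               strandSet = c("L","M","N","T","X"), minS = 3) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  lab <- rep("coil", n)
  runs <- function(set, minLen) {
    inSet <- ch %in% set
    r <- rle(inSet)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- which(r$values & r$lengths >= minLen)
    lapply(keep, function(i) starts[i]:ends[i])
  }
  for (span in runs(helixSet, minH)) lab[span] <- "helix"
  for (span in runs(strandSet, minS))
    if (all(lab[span] == "coil")) lab[span] <- "strand"
  lab
}

## random coil-ish letter string avoiding SS letters
randomCoilString <- function(n, seed = 1) {
  set.seed(seed)
  paste(sample(c("B","C","D","E","F","G","H","I","J","K"), n,
               replace = TRUE), collapse = "")
}

## write a tiny hand-rolled PDB file for filter tests
writeTestPDB <- function(path, n = 35, resolution = 1.8, gapAt = NULL,
                         altlocAt = NULL, bfactor = 20) {
  resno <- seq_len(n)
  if (!is.null(gapAt)) resno[resno >= gapAt] <- resno[resno >= gapAt] + 1L
  lines <- c(
    "HEADER    TEST STRUCTURE",
    if (is.na(resolution))
      "REMARK   2 RESOLUTION. NOT APPLICABLE."
    else sprintf("REMARK   2 RESOLUTION.    %4.2f ANGSTROMS.", resolution))
  for (i in seq_len(n)) {
    alt <- if (!is.null(altlocAt) && i == altlocAt) "A" else " "
    lines <- c(lines, sprintf(
      "ATOM  %5d  CA %sALA A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
      i, alt, resno[i], 3.8 * i, 0, 0, 1.0, bfactor))
  }
  writeLines(c(lines, "TER", "END"), path)
  path
}
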