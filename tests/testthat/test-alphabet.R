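test_that("descriptors of a collinear trace are forced by geometry", {
  ca <- cbind(3.8 * (0:3), 0, 0)
  d <- computeDescriptors(ca)
  expect_equal(nrow(d), 1L)
  expect_equal(unname(d[1, ]), c(7.6, 11.4, 7.6, 0.0))
})

test_that("descriptor errors: too short and non-finite input", {
  expect_error(computeDescriptors(cbind(1:3, 0, 0)), "at least 4")
  bad <- cbind(c(0, 1, 2, NA), 0, 0)
  expect_error(computeDescriptors(bad), "non-finite")
})

test_that("first helix fragment matches independent coordinate geometry", {
  r <- 2.3; rise <- 1.5; turn <- 100 * pi / 180
  th <- (0:3) * turn
  pts <- cbind(r * cos(th), r * sin(th), (0:3) * rise)
  D <- as.matrix(dist(pts))          # independent pairwise geometry
  n0 <- function(u, v)
    c(u[2]*v[3]-u[3]*v[2], u[3]*v[1]-u[1]*v[3], u[1]*v[2]-u[2]*v[1])
  nrm <- n0(pts[2, ] - pts[1, ], pts[3, ] - pts[1, ])
  hp <- sum(nrm / sqrt(sum(nrm^2)) * (pts[4, ] - pts[1, ]))
  d <- computeDescriptors(pts)
  expect_equal(unname(d[1, ]), c(D[1, 3], D[1, 4], D[2, 4], hp),
               tolerance = 1e-12)
  expect_gt(abs(hp), 0)              # helix chirality is carried
})

test_that("shared descriptor between consecutive fragments is exact", {
  set.seed(11)
  for (rep in 1:5) {
    ca <- matrix(rnorm(3 * 20, sd = 5), 20, 3)
    d <- computeDescriptors(ca)
    expect_identical(d[-nrow(d), "d24"], d[-1, "d13"])
  }
})

test_that("model file round-trips and validation errors name the state", {
  m <- toyModel(3, seed = 5)
  path <- tempfile(fileext = ".json")
  writeAlphabetModel(m, path)
  m2 <- readAlphabetModel(path)
  expect_equal(modelLetters(m2), modelLetters(m))
  expect_equal(unname(transitionMatrix(m2)), unname(transitionMatrix(m)),
               tolerance = 1e-12)
  expect_equal(unname(emissionMeans(m2)), unname(emissionMeans(m)),
               tolerance = 1e-12)
  expect_equal(emissionCovs(m2), emissionCovs(m), tolerance = 1e-12)
  expect_equal(initialProbs(m2), initialProbs(m), tolerance = 1e-12)

  ## corrupt a transition row
  obj <- jsonlite::fromJSON(path)
  obj$transitions[2, 1] <- obj$transitions[2, 1] - 0.1
  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(obj, bad, auto_unbox = TRUE, digits = NA)
  expect_error(readAlphabetModel(bad), "state 'B'.*sums to")

  ## non-positive-definite covariance
  obj2 <- jsonlite::fromJSON(path)
  obj2$emissions$cov[3, , ] <- 0
  bad2 <- tempfile(fileext = ".json")
  jsonlite::write_json(obj2, bad2, auto_unbox = TRUE, digits = NA)
  expect_error(readAlphabetModel(bad2), "state 'C'.*positive definite")

  expect_error(readAlphabetModel(tempfile()), "not found")
})

test_that("shipped fixture model loads, validates, and encodes an ideal helix
          as a constant letter run", {
  m <- readAlphabetModel(fixtureModelPath())
  expect_true(validObject(m))
  expect_true(all(c("A", "L") %in% modelLetters(m)))
  r <- 2.3; rise <- 1.5; turn <- 100 * pi / 180
  th <- (0:19) * turn
  helix <- cbind(r * cos(th), r * sin(th), (0:19) * rise)
  enc <- as.character(encodeStructure(helix, m))
  expect_equal(enc, strrep("A", 17))
})

test_that("single-fragment Viterbi is the emission-times-initial argmax", {
  m <- toyModel(3, seed = 2)
  x <- matrix(m@emissionMean[2, ] + 0.1, 1)
  dens <- vapply(1:3, function(k)
    log(m@initial[k]) + logdmvnormOracle(x[1, ], m@emissionMean[k, ],
                                         m@emissionCov[, , k]), 0)
  expect_equal(as.character(viterbiEncode(x, m)),
               modelLetters(m)[which.max(dens)])
})

test_that("Viterbi equals exhaustive path enumeration on toy models", {
  set.seed(7)
  for (K in 2:4) for (Tn in c(2, 4, 5)) {
    m <- toyModel(K, seed = K * 10 + Tn, sep = 2)
    x <- matrix(rnorm(Tn * 4, sd = 4), Tn, 4) + 2 * seq_len(Tn)
    got <- viterbiEncode(x, m)
    want <- viterbiBruteForce(x, m)
    expect_equal(as.character(got), want$letters)
    expect_equal(attr(got, "logProb"), want$logProb, tolerance = 1e-8)
  }
})

test_that("Viterbi ties break toward the first letter in alphabet order", {
  mu <- rbind(c(0, 0, 0, 0), c(0, 0, 0, 0))
  m <- new("AlphabetModel", letters = c("A", "B"), initial = c(0.5, 0.5),
           transitions = matrix(0.5, 2, 2), emissionMean = mu,
           emissionCov = array(diag(4), c(4, 4, 2)))
  x <- matrix(rnorm(4 * 6), 6, 4)
  expect_equal(as.character(viterbiEncode(x, m)), strrep("A", 6))
})

test_that("Viterbi path beats randomly sampled paths", {
  set.seed(3)
  m <- toyModel(3, seed = 9, sep = 1.5)
  x <- matrix(rnorm(6 * 4, sd = 3), 6, 4)
  best <- attr(viterbiEncode(x, m), "logProb")
  pathLP <- function(p) {
    v <- log(m@initial[p[1]]) +
      logdmvnormOracle(x[1, ], m@emissionMean[p[1], ], m@emissionCov[, , p[1]])
    for (t in 2:6) v <- v + log(m@transitions[p[t - 1], p[t]]) +
      logdmvnormOracle(x[t, ], m@emissionMean[p[t], ], m@emissionCov[, , p[t]])
    v
  }
  samples <- replicate(1000, pathLP(sample.int(3, 6, replace = TRUE)))
  expect_true(all(best >= samples - 1e-10))
})

test_that("encoding length is residues minus three, with boundary errors", {
  m <- readAlphabetModel(fixtureModelPath())
  set.seed(21)
  ca30 <- matrix(cumsum(rnorm(90, sd = 2)), 30, 3)
  expect_equal(nchar(encodeStructure(ca30, m)), 27L)
  ca4 <- matrix(rnorm(12, sd = 3), 4, 3)
  expect_equal(nchar(encodeStructure(ca4, m)), 1L)
  expect_error(encodeStructure(matrix(rnorm(9), 3, 3), m), "at least 4")
  expect_error(viterbiEncode(matrix(0, 2, 3), m), "dimensionality")
})

test_that("training contracts: one state, iteration cap, monotone loglik", {
  set.seed(4)
  series <- replicate(10, matrix(rnorm(40), 10, 4), simplify = FALSE)
  m1 <- trainAlphabetModel(series, nStates = 1, seed = 1)
  expect_equal(unname(transitionMatrix(m1)), matrix(1, 1, 1))

  mCap <- trainAlphabetModel(series, nStates = 2, seed = 1, maxIter = 1)
  expect_false(attr(mCap, "converged"))

  m2 <- trainAlphabetModel(series, nStates = 2, seed = 1, maxIter = 25)
  ll <- attr(m2, "loglik")
  expect_true(all(diff(ll) > -1e-6 * abs(ll[-length(ll)])))
})

test_that("training refuses too few fragments", {
  expect_error(trainAlphabetModel(matrix(rnorm(36), 9, 4), nStates = 1),
               "at least 10")
})
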