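## Structural-alphabet encoding: backbone descriptors, model file I/O,
## Viterbi decoding and Baum-Welch training.

#' Run code with a temporary RNG seed
#'
#' Evaluates `expr` after seeding R's RNG with `seed`, then restores the
#' caller's RNG state, so stochastic operations are reproducible without
#' touching global state.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Compute the four backbone descriptors of every four-residue fragment
#'
#' Each overlapping four-residue fragment `(r1, r2, r3, r4)` of a C-alpha
#' trace is described by three non-adjacent inter-C-alpha distances
#' `d(r1,r3)`, `d(r1,r4)`, `d(r2,r4)` and the signed distance of `r4` to
#' the plane through `(r1, r2, r3)` (positive on the side of the plane
#' normal `cross(r2-r1, r3-r1)`), which carries the fragment handedness.
#' Consecutive fragments overlap on three residues, so descriptor
#' `d(r2,r4)` of fragment `i` is exactly descriptor `d(r1,r3)` of
#' fragment `i+1` (both are computed once from the same pair).
#'
#' @param ca n x 3 numeric matrix of C-alpha coordinates, one row per
#'   residue, in chain order (angstroms).
#' @param chainId optional chain identifier stored as an attribute.
#' @return numeric matrix with `n - 3` rows and columns
#'   `d13`, `d14`, `d24`, `hp`, with attributes `chainId` and
#'   `residueIndex` (index of the fragment's first residue).
#' @examples
#' ca <- cbind(3.8 * (0:4), 0, 0)
#' computeDescriptors(ca)
#' @export
computeDescriptors <- function(ca, chainId = NA_character_) {
  ca <- as.matrix(ca)
  if (!is.numeric(ca) || ncol(ca) != 3)
    stop("`ca` must be an n x 3 numeric coordinate matrix")
  n <- nrow(ca)
  if (n < 4) stop("at least 4 residues are required to form a fragment")
  if (!all(is.finite(ca))) stop("non-finite coordinates in C-alpha trace")
  d2 <- sqrt(rowSums((ca[-(1:2), , drop = FALSE] -
                      ca[seq_len(n - 2), , drop = FALSE])^2))  # |r_{i+2}-r_i|
  d3 <- sqrt(rowSums((ca[-(1:3), , drop = FALSE] -
                      ca[seq_len(n - 3), , drop = FALSE])^2))  # |r_{i+3}-r_i|
  m <- n - 3
  i <- seq_len(m)
  u <- ca[i + 1, , drop = FALSE] - ca[i, , drop = FALSE]
  v <- ca[i + 2, , drop = FALSE] - ca[i, , drop = FALSE]
  nrm <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
               u[, 3] * v[, 1] - u[, 1] * v[, 3],
               u[, 1] * v[, 2] - u[, 2] * v[, 1])
  nn <- sqrt(rowSums(nrm^2))
  w <- ca[i + 3, , drop = FALSE] - ca[i, , drop = FALSE]
  hp <- ifelse(nn > 0, rowSums(nrm * w) / nn, 0)
  out <- cbind(d13 = d2[i], d14 = d3[i], d24 = d2[i + 1], hp = hp)
  attr(out, "chainId") <- chainId
  attr(out, "residueIndex") <- i
  out
}

## log multivariate normal density, vectorized over rows of x
.logdmvnorm <- function(x, mean, sigma) {
  R <- chol(sigma)
  d <- length(mean)
  xc <- sweep(x, 2, mean)
  z <- backsolve(R, t(xc), transpose = TRUE)
  -0.5 * colSums(z^2) - sum(log(diag(R))) - 0.5 * d * log(2 * pi)
}

## K x T matrix of per-state log emission densities
.logEmissions <- function(model, descr) {
  K <- nStates(model)
  out <- matrix(0, K, nrow(descr))
  for (k in seq_len(K))
    out[k, ] <- .logdmvnorm(descr, model@emissionMean[k, ],
                            model@emissionCov[, , k])
  out
}

#' Viterbi decoding of a descriptor series into structural letters
#'
#' Finds the single most probable state path under the model's Gaussian
#' emissions, initial distribution and transition matrix. All arithmetic
#' is in log space; exact ties are broken toward the letter that comes
#' first in the model's alphabet order, so decoding is deterministic.
#'
#' @param descr descriptor matrix from [computeDescriptors()] (one row per
#'   fragment; columns must match the model's emission dimensionality).
#' @param model an [AlphabetModel].
#' @return single character string of structural letters, one per
#'   fragment, with attribute `logProb` (log joint probability of the
#'   returned path).
#' @export
viterbiEncode <- function(descr, model) {
  stopifnot(is(model, "AlphabetModel"))
  validObject(model)
  descr <- as.matrix(descr)
  if (nrow(descr) == 0) stop("empty descriptor series")
  if (ncol(descr) != ncol(model@emissionMean))
    stop("descriptor dimensionality (", ncol(descr),
         ") does not match model emissions (", ncol(model@emissionMean), ")")
  K <- nStates(model)
  Tn <- nrow(descr)
  logB <- .logEmissions(model, descr)
  logA <- log(model@transitions)
  delta <- log(model@initial) + logB[, 1]
  psi <- matrix(NA_integer_, K, Tn)
  if (Tn > 1) {
    for (t in 2:Tn) {
      cand <- delta + logA               # K x K: cand[i, j] = from i to j
      best <- apply(cand, 2, which.max)  # first max = alphabet-order tie-break
      psi[, t] <- best
      delta <- cand[cbind(best, seq_len(K))] + logB[, t]
    }
  }
  path <- integer(Tn)
  path[Tn] <- which.max(delta)
  if (Tn > 1) for (t in Tn:2) path[t - 1] <- psi[path[t], t]
  out <- paste(model@letters[path], collapse = "")
  attr(out, "logProb") <- max(delta)
  out
}

#' Encode a C-alpha trace as a string of structural letters
#'
#' Composition of [computeDescriptors()] and [viterbiEncode()]: a chain of
#' `n` residues becomes a string of `n - 3` structural letters.
#'
#' @param chain either an n x 3 C-alpha coordinate matrix or a chain
#'   record from [readStructure()] (a list with element `ca`).
#' @param model an [AlphabetModel].
#' @inherit viterbiEncode return
#' @export
encodeStructure <- function(chain, model) {
  ca <- if (is.list(chain) && !is.null(chain$ca)) chain$ca else chain
  id <- if (is.list(chain) && !is.null(chain$id)) chain$id else NA_character_
  viterbiEncode(computeDescriptors(ca, chainId = id), model)
}

## ---- model file I/O --------------------------------------------------

.modelFormatVersion <- 1L

#' Read / write a structural-alphabet model file
#'
#' Model files are JSON with keys `format_version`, `letters`, `initial`,
#' `transitions`, and `emissions` (`mean`: list of per-state descriptor
#' mean vectors in angstroms; `cov`: list of per-state covariance matrices
#' in square angstroms). The letter order in the file fixes the canonical
#' state order. `writeAlphabetModel()` followed by `readAlphabetModel()`
#' is the identity on the model's fields.
#'
#' @param path path to the JSON model file.
#' @return `readAlphabetModel()` returns a validated [AlphabetModel];
#'   `writeAlphabetModel()` returns `path` invisibly.
#' @export
readAlphabetModel <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyMatrix = TRUE),
                  error = function(e) stop("malformed model file: ",
                                           conditionMessage(e)))
  need <- c("format_version", "letters", "initial", "transitions", "emissions")
  miss <- setdiff(need, names(obj))
  if (length(miss))
    stop("malformed model file: missing keys ", paste(miss, collapse = ", "))
  if (obj$format_version > .modelFormatVersion)
    stop("unsupported model format version ", obj$format_version)
  letters <- as.character(obj$letters)
  K <- length(letters)
  tr <- obj$transitions
  if (!is.matrix(tr))
    tr <- do.call(rbind, lapply(tr, as.numeric))
  if (!is.numeric(tr) || !all(dim(tr) == c(K, K)))
    stop("malformed model file: transitions must be a ", K, " x ", K,
         " matrix")
  rs <- rowSums(tr)
  bad <- which(abs(rs - 1) > .prob_tol)
  if (length(bad))
    stop("transition row for state '", letters[bad[1]],
         "' sums to ", format(rs[bad[1]]), ", not 1")
  mu <- obj$emissions$mean
  if (!is.matrix(mu)) mu <- do.call(rbind, lapply(mu, as.numeric))
  d <- ncol(mu)
  covs <- array(NA_real_, c(d, d, K))
  cv <- obj$emissions$cov
  for (k in seq_len(K)) {
    S <- if (is.list(cv)) as.matrix(cv[[k]]) else matrix(cv[k, , ], d, d)
    if (inherits(try(chol(S), silent = TRUE), "try-error"))
      stop("emission covariance for state '", letters[k],
           "' is not positive definite")
    covs[, , k] <- S
  }
  model <- new("AlphabetModel", letters = letters,
               initial = as.numeric(obj$initial), transitions = tr,
               emissionMean = mu, emissionCov = covs)
  validObject(model)
  dimnames(model@transitions) <- list(letters, letters)
  rownames(model@emissionMean) <- letters
  model
}

#' @rdname readAlphabetModel
#' @param model an [AlphabetModel] to serialize.
#' @export
writeAlphabetModel <- function(model, path) {
  stopifnot(is(model, "AlphabetModel"))
  validObject(model)
  K <- nStates(model)
  obj <- list(
    format_version = .modelFormatVersion,
    letters = model@letters,
    initial = model@initial,
    transitions = model@transitions,
    emissions = list(
      mean = lapply(seq_len(K), function(k) unname(model@emissionMean[k, ])),
      cov = lapply(seq_len(K), function(k) unname(model@emissionCov[, , k]))
    )
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' Untrained alphabet template
#'
#' Returns an [AlphabetModel] skeleton with the requested state names
#' (default the 27 letters `A`-`Z`, `a` of the full structural alphabet),
#' uniform transitions and initial distribution, zero descriptor means and
#' identity covariances. Intended as a starting point for
#' [trainAlphabetModel()] or for writing a model file template.
#'
#' @param letters state names; default the 27-letter alphabet.
#' @param nDescriptors number of emission descriptors (default 4).
#' @export
alphabetTemplate <- function(letters = c(LETTERS, "a"), nDescriptors = 4) {
  K <- length(letters)
  new("AlphabetModel",
      letters = letters,
      initial = rep(1 / K, K),
      transitions = matrix(1 / K, K, K, dimnames = list(letters, letters)),
      emissionMean = matrix(0, K, nDescriptors,
                            dimnames = list(letters, NULL)),
      emissionCov = array(diag(nDescriptors), c(nDescriptors, nDescriptors, K)))
}

## ---- Baum-Welch training --------------------------------------------

## scaled forward-backward for one sequence; B is K x T emission densities
## (probability scale, rescaled per column upstream to avoid underflow)
.forwardBackward <- function(init, A, logB) {
  K <- nrow(logB); Tn <- ncol(logB)
  bmax <- apply(logB, 2, max)
  B <- exp(sweep(logB, 2, bmax))
  alpha <- matrix(0, K, Tn); beta <- matrix(0, K, Tn)
  cvec <- numeric(Tn)
  a <- init * B[, 1]
  cvec[1] <- sum(a); alpha[, 1] <- a / cvec[1]
  if (Tn > 1) for (t in 2:Tn) {
    a <- (crossprod(A, alpha[, t - 1])) * B[, t]
    cvec[t] <- sum(a)
    alpha[, t] <- a / cvec[t]
  }
  beta[, Tn] <- 1
  if (Tn > 1) for (t in (Tn - 1):1) {
    b <- A %*% (B[, t + 1] * beta[, t + 1])
    beta[, t] <- b / cvec[t + 1]
  }
  gamma <- alpha * beta
  gamma <- sweep(gamma, 2, colSums(gamma), "/")
  ## expected transition counts
  xi <- matrix(0, K, K)
  if (Tn > 1) for (t in 1:(Tn - 1)) {
    m <- (alpha[, t] %o% (B[, t + 1] * beta[, t + 1])) * A / cvec[t + 1]
    xi <- xi + m
  }
  list(gamma = gamma, xi = xi, loglik = sum(log(cvec)) + sum(bmax))
}

#' Train a structural-alphabet HMM by Baum-Welch EM
#'
#' Fits a Gaussian-emission hidden Markov model to a collection of
#' descriptor series. States are initialized by k-means on the pooled
#' fragments (seeded), after which expectation-maximization runs until the
#' log-likelihood improves by less than `tol` or `maxIter` is reached. The
#' log-likelihood is checked to be non-decreasing at every iteration. A
#' state whose expected occupancy collapses is re-seeded from a randomly
#' chosen fragment, with a warning.
#'
#' @param series list of descriptor matrices (one per chain), as returned
#'   by [computeDescriptors()].
#' @param nStates number of structural letters to fit.
#' @param letters state names (default `A`, `B`, ... truncated/extended to
#'   `nStates` from the 27-letter alphabet).
#' @param seed RNG seed for k-means initialization and re-seeding.
#' @param maxIter,tol EM stopping rule (default 100 iterations, 1e-6
#'   relative log-likelihood change).
#' @param covType `"full"` (default) or `"diagonal"` emission covariances.
#' @return an [AlphabetModel] with attributes `loglik` (per-iteration
#'   log-likelihood trace) and `converged`.
#' @export
trainAlphabetModel <- function(series, nStates, letters = NULL, seed = 1,
                               maxIter = 100, tol = 1e-6,
                               covType = c("full", "diagonal")) {
  covType <- match.arg(covType)
  if (is.matrix(series)) series <- list(series)
  series <- lapply(series, as.matrix)
  pool <- do.call(rbind, series)
  d <- ncol(pool)
  if (nrow(pool) < 10 * nStates)
    stop("need at least 10 fragments per state to train (",
         nrow(pool), " < ", 10 * nStates, ")")
  if (is.null(letters)) letters <- c(LETTERS, "a")[seq_len(nStates)]
  K <- nStates
  ridge <- diag(1e-6, d)

  mstepCov <- function(S) {
    if (covType == "diagonal") S <- diag(diag(S), d)
    S + ridge
  }

  init <- withSeed(seed, {
    if (K == 1) list(cluster = rep(1L, nrow(pool)),
                     centers = matrix(colMeans(pool), 1))
    else kmeans(pool, centers = K, nstart = 5, iter.max = 50)
  })
  mu <- matrix(init$centers, K, d)
  covs <- array(0, c(d, d, K))
  for (k in seq_len(K)) {
    xk <- pool[init$cluster == k, , drop = FALSE]
    covs[, , k] <- mstepCov(if (nrow(xk) > d) cov(xk) else diag(1, d))
  }
  ## transition / initial counts from the k-means labelling
  lens <- vapply(series, nrow, 1L)
  labs <- split(init$cluster, rep(seq_along(series), lens))
  trc <- matrix(1e-3, K, K); inic <- rep(1e-3, K)
  for (lb in labs) {
    inic[lb[1]] <- inic[lb[1]] + 1
    if (length(lb) > 1)
      for (t in seq_len(length(lb) - 1))
        trc[lb[t], lb[t + 1]] <- trc[lb[t], lb[t + 1]] + 1
  }
  A <- trc / rowSums(trc)
  piv <- inic / sum(inic)

  llTrace <- numeric(0)
  converged <- FALSE
  prevLL <- -Inf
  reseed <- seed + 1L
  for (iter in seq_len(maxIter)) {
    gsum <- matrix(0, K, 1 + d)        # occupancy and weighted sums
    ssum <- array(0, c(d, d, K))
    xiSum <- matrix(0, K, K)
    g1Sum <- rep(0, K)
    ll <- 0
    for (s in seq_along(series)) {
      x <- series[[s]]
      logB <- t(vapply(seq_len(K), function(k)
        .logdmvnorm(x, mu[k, ], covs[, , k]), numeric(nrow(x))))
      if (nrow(x) == 1) dim(logB) <- c(K, 1)
      fb <- .forwardBackward(piv, A, logB)
      ll <- ll + fb$loglik
      g1Sum <- g1Sum + fb$gamma[, 1]
      xiSum <- xiSum + fb$xi
      gsum[, 1] <- gsum[, 1] + rowSums(fb$gamma)
      gsum[, -1] <- gsum[, -1] + fb$gamma %*% x
      for (k in seq_len(K))
        ssum[, , k] <- ssum[, , k] + crossprod(x * fb$gamma[k, ], x)
    }
    llTrace <- c(llTrace, ll)
    if (ll < prevLL - 1e-6 * abs(prevLL))
      warning("log-likelihood decreased at iteration ", iter)
    if (is.finite(prevLL) &&
        abs(ll - prevLL) < tol * (abs(prevLL) + 1e-12)) {
      converged <- TRUE
      break
    }
    prevLL <- ll
    ## M-step
    for (k in seq_len(K)) {
      nk <- gsum[k, 1]
      if (nk < 1e-8) {
        warning("state '", letters[k],
                "' collapsed; re-seeding from a random fragment")
        idx <- withSeed(reseed, sample.int(nrow(pool), 1))
        reseed <- reseed + 1L
        mu[k, ] <- pool[idx, ]
        covs[, , k] <- mstepCov(diag(1, d))
        next
      }
      mu[k, ] <- gsum[k, -1] / nk
      S <- ssum[, , k] / nk - tcrossprod(mu[k, ])
      covs[, , k] <- mstepCov((S + t(S)) / 2)
    }
    A <- xiSum + 1e-10
    A <- A / rowSums(A)
    piv <- (g1Sum + 1e-10) / sum(g1Sum + 1e-10)
  }
  if (K == 1) { A <- matrix(1, 1, 1); piv <- 1 }
  dimnames(A) <- list(letters, letters)
  rownames(mu) <- letters
  model <- new("AlphabetModel", letters = letters, initial = piv,
               transitions = A, emissionMean = mu, emissionCov = covs)
  validObject(model)
  attr(model, "loglik") <- llTrace
  attr(model, "converged") <- converged
  model
}
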