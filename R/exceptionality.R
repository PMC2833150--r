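## Statistical exceptionality of structural words against a first-order
## Markov background: exact occurrence-count distributions via a pattern
## automaton embedded in the letter Markov chain, a compound-Poisson
## approximation for large corpora, Monte-Carlo validation, L_p scores
## and OR/NS/UR classification.

#' Fit a first-order Markov background on a letter corpus
#'
#' Maximum-likelihood transition probabilities from the observed digram
#' counts of the corpus (optionally with a pseudocount), and an initial
#' distribution from the sequence-start letters. A letter never observed
#' as a transition source gets a uniform row, with a warning.
#'
#' @param sequences character vector of letter strings (the loop corpus).
#' @param order Markov order; only 1 is supported.
#' @param pseudocount added to every digram and start count (default 0).
#' @param alphabet letters of the model; default the letters observed in
#'   the corpus, sorted. Letters of the corpus absent from a supplied
#'   alphabet raise an error.
#' @return a [BackgroundModel].
#' @export
fitBackground <- function(sequences, order = 1, pseudocount = 0,
                          alphabet = NULL) {
  if (order != 1) stop("only first-order backgrounds are supported")
  if (!length(sequences)) stop("empty corpus")
  chars <- strsplit(sequences, "")
  seen <- sort(unique(unlist(chars)))
  if (is.null(alphabet)) alphabet <- seen
  extra <- setdiff(seen, alphabet)
  if (length(extra))
    stop("corpus contains letters absent from the alphabet: ",
         paste(extra, collapse = ", "))
  K <- length(alphabet)
  trc <- matrix(pseudocount, K, K, dimnames = list(alphabet, alphabet))
  ini <- rep(pseudocount, K); names(ini) <- alphabet
  for (s in chars) {
    ini[s[1]] <- ini[s[1]] + 1
    if (length(s) > 1) {
      from <- match(s[-length(s)], alphabet)
      to <- match(s[-1], alphabet)
      for (j in seq_along(from)) trc[from[j], to[j]] <- trc[from[j], to[j]] + 1
    }
  }
  rs <- rowSums(trc)
  zero <- rs == 0
  if (any(zero)) {
    warning("letter(s) ", paste(alphabet[zero], collapse = ", "),
            " never observed as transition source; using uniform rows")
    trc[zero, ] <- 1
    rs <- rowSums(trc)
  }
  new("BackgroundModel", alphabet = alphabet, order = 1L,
      transitions = trc / rs, initial = ini / sum(ini),
      nSeq = length(sequences),
      totalLetters = sum(lengths(chars)),
      lengths = lengths(chars))
}

#' Construct a background model directly from parameters
#'
#' @param alphabet letters.
#' @param transitions row-stochastic matrix.
#' @param initial initial distribution (default the uniform distribution).
#' @param lengths corpus sequence lengths carried for bookkeeping.
#' @return a [BackgroundModel].
#' @export
backgroundModel <- function(alphabet, transitions,
                            initial = rep(1 / length(alphabet),
                                          length(alphabet)),
                            lengths = integer()) {
  dimnames(transitions) <- list(alphabet, alphabet)
  new("BackgroundModel", alphabet = alphabet, order = 1L,
      transitions = transitions, initial = initial,
      nSeq = length(lengths), totalLetters = as.integer(sum(lengths)),
      lengths = as.integer(lengths))
}

## KMP border (failure) function of an integer-coded word
.kmpBorder <- function(w) {
  m <- length(w)
  b <- integer(m)
  k <- 0L
  for (i in seq_len(m)[-1]) {
    while (k > 0L && w[k + 1L] != w[i]) k <- b[k]
    if (w[k + 1L] == w[i]) k <- k + 1L
    b[i] <- k
  }
  b
}

## automaton transition table: delta[s + 1, c] = next prefix state after
## reading letter c in prefix state s (0..m); state m re-enters via its
## border, so overlapping occurrences are counted.
.wordAutomaton <- function(w, K) {
  m <- length(w)
  b <- .kmpBorder(w)
  delta <- matrix(0L, m + 1L, K)
  for (s in 0:m) for (c in seq_len(K)) {
    k <- if (s == m) b[m] else s
    while (k > 0L && w[k + 1L] != c) k <- b[k]
    if (w[k + 1L] == c) k <- k + 1L
    delta[s + 1L, c] <- k
  }
  delta
}

## Exact occurrence-count distribution of `wInt` in one sequence of length
## `len` under the background: DP over (pattern-automaton state crossed
## with last letter, truncated count). Rows of the state space: for
## automaton state 0 the last letter must be tracked (K rows), for state
## s >= 1 the last letter is word[s] (m rows). Returns a vector of
## probabilities for counts 0..cmax plus an overflow bucket `> cmax`.
.seqCountDist <- function(wInt, len, trans, init, cmax) {
  m <- length(wInt)
  K <- ncol(trans)
  if (len < m) return(c(1, rep(0, cmax + 1L)))
  delta <- .wordAutomaton(wInt, K)
  nS <- K + m                       # rows 1..K: (state0, letter c); K+s: state s
  lastLetter <- c(seq_len(K), wInt) # last letter per DP row
  rowOf <- function(s, c) if (s == 0L) c else K + s
  ## transition structure: for each DP row u and next letter c, target row
  toRow <- matrix(0L, nS, K)
  emits <- matrix(FALSE, nS, K)
  stateOf <- c(rep(0L, K), seq_len(m))
  for (u in seq_len(nS)) for (c in seq_len(K)) {
    s2 <- delta[stateOf[u] + 1L, c]
    toRow[u, c] <- rowOf(s2, c)
    emits[u, c] <- s2 == m
  }
  f <- matrix(0, nS, cmax + 2L)     # columns: count 0..cmax, overflow
  ## first letter
  for (c in seq_len(K)) {
    s2 <- if (m == 1L && wInt[1L] == c) 1L else (if (wInt[1L] == c) 1L else 0L)
    occ <- m == 1L && s2 == m
    f[rowOf(s2, c), 1L + occ] <- f[rowOf(s2, c), 1L + occ] + init[c]
  }
  if (len > 1) for (t in 2:len) {
    g <- matrix(0, nS, cmax + 2L)
    for (c in seq_len(K)) {
      p <- trans[lastLetter, c] # prob per source row
      mass <- f * p
      tr <- toRow[, c]
      em <- emits[, c]
      if (any(!em)) {
        src <- which(!em)
        for (u in src) g[tr[u], ] <- g[tr[u], ] + mass[u, ]
      }
      if (any(em)) {
        src <- which(em)
        for (u in src) {
          g[tr[u], 2:(cmax + 1L)] <- g[tr[u], 2:(cmax + 1L)] +
            mass[u, 1:cmax]
          g[tr[u], cmax + 2L] <- g[tr[u], cmax + 2L] +
            mass[u, cmax + 1L] + mass[u, cmax + 2L]
        }
      }
    }
    f <- g
  }
  colSums(f)
}

## convolve two truncated count distributions (last element = overflow).
## Direct convolution (no FFT) so that very small tail probabilities are
## not swamped by transform round-off.
.convTrunc <- function(a, b) {
  cmax <- length(a) - 2L
  aa <- a[1:(cmax + 1L)]; bb <- b[1:(cmax + 1L)]
  head <- vapply(0:cmax, function(k)
    sum(aa[1:(k + 1L)] * bb[(k + 1L):1]), 0)
  ov <- a[cmax + 2L] * sum(b) + b[cmax + 2L] * sum(aa) +
    (sum(aa) * sum(bb) - sum(head))
  c(head, max(0, ov))
}

.convPower <- function(dist, n) {
  cmax <- length(dist) - 2L
  acc <- c(1, rep(0, cmax + 1L))
  base <- dist
  while (n > 0) {
    if (n %% 2 == 1) acc <- .convTrunc(acc, base)
    n <- n %/% 2
    if (n > 0) base <- .convTrunc(base, base)
  }
  acc
}

## analytic expected total count of the word across the corpus
.expectedCount <- function(wInt, lengths, trans, init) {
  m <- length(wInt)
  wTransProb <- if (m > 1)
    prod(trans[cbind(wInt[-m], wInt[-1])]) else 1
  tab <- table(lengths)
  total <- 0
  for (li in seq_along(tab)) {
    len <- as.integer(names(tab)[li])
    if (len < m) next
    nPos <- len - m + 1L
    ## marginal probability of the word's first letter at each start
    marg <- init
    pstart <- numeric(nPos)
    for (p in seq_len(nPos)) {
      pstart[p] <- marg[wInt[1L]]
      marg <- as.numeric(marg %*% trans)
    }
    total <- total + as.numeric(tab[li]) * sum(pstart) * wTransProb
  }
  total
}

## Polya-Aeppli (geometric compound Poisson) tail approximation
.polyaAeppliDist <- function(lambda, a, upto) {
  ## severity: clump size ~ Geometric on {1, 2, ...} with P(size=k) =
  ## (1-a) a^(k-1); Panjer recursion for the compound Poisson
  g <- numeric(upto + 1L)
  g[1] <- exp(-lambda)
  if (upto >= 1) {
    fk <- (1 - a) * a^(0:(upto - 1))   # f_1..f_upto
    for (n in seq_len(upto)) {
      k <- seq_len(n)
      g[n + 1L] <- (lambda / n) * sum(k * fk[k] * g[n - k + 1L])
    }
  }
  g
}

#' Occurrence-count p-values of a word under the Markov background
#'
#' Builds the word's pattern automaton (overlapping occurrences counted),
#' embeds it in the background Markov chain, and runs a dynamic program
#' over (automaton state, truncated count) per distinct sequence length
#' to obtain each sequence's exact occurrence-count distribution. The
#' per-length distributions are convolved across the corpus (sequences
#' independent), giving the exact distribution of the total count, from
#' which `p_over = P(X >= N_w)` and `p_under = P(X <= N_w)` are read off.
#' Counts are truncated at `cmax` with an overflow bucket, which leaves
#' both tails exact as long as `cmax >= observed` (the default is
#' `observed + 1`). For corpora beyond `maxExactSeq` sequences or with
#' expected count beyond `maxExactExpected`, a Polya-Aeppli
#' (geometric compound Poisson) approximation is used instead, with the
#' clump-extension probability summed over the word's periods; the
#' `method` field records which path ran.
#'
#' @param word structural word (string over the background alphabet).
#' @param background a [BackgroundModel].
#' @param lengths integer vector (or multiset) of sequence lengths;
#'   default the background's source corpus lengths.
#' @param observed observed total count `N_w`.
#' @param cmax truncation bound for the exact DP (default
#'   `observed + 1`; larger values give more of the distribution).
#' @param maxExactSeq,maxExactExpected switch-over thresholds to the
#'   compound-Poisson approximation (defaults 1e5 sequences / 1e4
#'   expected occurrences).
#' @param method force `"exact-dp"` or `"compound-poisson"`.
#' @return list `word`, `observed`, `expected`, `p_over`, `p_under`,
#'   `method`, and `distribution` (counts 0..cmax plus overflow; exact
#'   path only).
#' @examples
#' bg <- backgroundModel(c("X", "Y"), matrix(0.5, 2, 2))
#' wordPvalue("XY", bg, lengths = 4, observed = 1)$p_over  # 11/16
#' @export
wordPvalue <- function(word, background, lengths = background@lengths,
                       observed, cmax = observed + 1L,
                       maxExactSeq = 1e5, maxExactExpected = 1e4,
                       method = NULL) {
  stopifnot(is(background, "BackgroundModel"))
  wInt <- match(strsplit(word, "")[[1]], background@alphabet)
  if (anyNA(wInt))
    stop("word '", word, "' contains letters outside the model alphabet")
  trans <- background@transitions
  init <- background@initial
  expected <- .expectedCount(wInt, lengths, trans, init)
  if (expected == 0) {
    return(list(word = word, observed = observed, expected = 0,
                p_over = if (observed > 0) 0 else 1, p_under = 1,
                method = "exact-dp", distribution = NULL))
  }
  if (is.null(method))
    method <- if (length(lengths) <= maxExactSeq &&
                  expected <= maxExactExpected) "exact-dp"
              else "compound-poisson"
  cmax <- max(cmax, observed, 1L)
  if (method == "exact-dp") {
    tab <- table(lengths)
    total <- c(1, rep(0, cmax + 1L))
    for (li in seq_along(tab)) {
      len <- as.integer(names(tab)[li])
      d1 <- .seqCountDist(wInt, len, trans, init, cmax)
      total <- .convTrunc(total, .convPower(d1, as.integer(tab[li])))
    }
    pmf <- total[1:(cmax + 1L)]
    over <- total[cmax + 2L]
    p_over <- if (observed == 0) 1 else
      sum(pmf[(observed + 1L):(cmax + 1L)]) + over
    p_under <- sum(pmf[1:(observed + 1L)])
    dist <- total
  } else {
    ## clump-extension probability over the word's periods
    m <- length(wInt)
    aExt <- 0
    if (m > 1) for (p in seq_len(m - 1)) {
      if (all(wInt[seq_len(m - p)] == wInt[seq_len(m - p) + p])) {
        ext <- c(wInt[m], wInt[(m - p + 1):m])
        aExt <- aExt + prod(trans[cbind(ext[-length(ext)], ext[-1])])
      }
    }
    lambda <- (1 - aExt) * expected
    upto <- max(observed, ceiling(expected + 10 * sqrt(expected)))
    g <- .polyaAeppliDist(lambda, aExt, upto)
    p_over <- if (observed == 0) 1 else
      max(0, 1 - sum(g[seq_len(observed)]))
    p_under <- min(1, sum(g[seq_len(observed + 1L)]))
    dist <- NULL
  }
  list(word = word, observed = observed, expected = expected,
       p_over = min(1, p_over), p_under = min(1, p_under),
       method = method, distribution = dist)
}

#' Monte-Carlo oracle for word-count p-values
#'
#' Simulates corpora from the background, counts occurrences with a
#' naive scanner, and returns the empirical tail probabilities with
#' binomial standard errors. Intended as an independent check of
#' [wordPvalue()].
#'
#' @inheritParams wordPvalue
#' @param nSim number of simulated corpora (at least 1000).
#' @param seed RNG seed; the same seed gives identical estimates.
#' @return list `p_over`, `p_under`, `se_over`, `se_under`, `mean_count`.
#' @export
mcPvalueOracle <- function(word, background, lengths = background@lengths,
                           observed, nSim = 10000, seed = 1) {
  if (nSim < 1000) stop("nSim must be at least 1000")
  wInt <- match(strsplit(word, "")[[1]], background@alphabet)
  if (anyNA(wInt)) stop("word outside the model alphabet")
  K <- length(background@alphabet)
  trans <- background@transitions
  init <- background@initial
  m <- length(wInt)
  counts <- withSeed(seed, {
    total <- numeric(nSim)
    for (len in sort(unique(lengths))) {
      nrep <- sum(lengths == len) * nSim
      X <- matrix(0L, nrep, len)
      X[, 1] <- sample.int(K, nrep, replace = TRUE, prob = init)
      cum <- t(apply(trans, 1, cumsum))
      if (len > 1) for (t in 2:len) {
        u <- runif(nrep)
        X[, t] <- max.col(u < cum[X[, t - 1], , drop = FALSE],
                          ties.method = "first")
      }
      if (len >= m) {
        hit <- matrix(TRUE, nrep, len - m + 1L)
        for (j in seq_len(m))
          hit <- hit & (X[, j:(len - m + j), drop = FALSE] == wInt[j])
        cnt <- rowSums(hit)
        total <- total + rowsum(cnt, rep(seq_len(nSim),
                                         times = sum(lengths == len)))[, 1]
      }
    }
    total
  })
  pOver <- mean(counts >= observed)
  pUnder <- mean(counts <= observed)
  list(p_over = pOver, p_under = pUnder,
       se_over = sqrt(pOver * (1 - pOver) / nSim),
       se_under = sqrt(pUnder * (1 - pUnder) / nSim),
       mean_count = mean(counts))
}

#' Signed log10 exceptionality score
#'
#' `L_p = -log10(p_over)` (positive) when the word is seen at least as
#' often as expected, `log10(p_under)` (negative) otherwise: an `L_p` of
#' 21.3 means over-represented with p-value `10^-21.3`; -17.7 means
#' under-represented with p-value `10^-17.7`. A p-value of 1 maps to 0.
#'
#' @param p_over,p_under tail probabilities from [wordPvalue()].
#' @param observed,expected counts deciding the direction.
#' @return the signed score (may be `Inf` when the tail is exactly 0).
#' @export
lpScore <- function(p_over, p_under, observed, expected) {
  if (is.na(p_over) && is.na(p_under)) stop("both p-values missing")
  if (observed >= expected) -log10(p_over) else log10(p_under)
}

#' Classify a word by its exceptionality score
#'
#' Over-represented (`"OR"`) when `L_p > threshold`, under-represented
#' (`"UR"`) when `L_p < -threshold`, not significant (`"NS"`) otherwise;
#' the boundary values are not significant. The default threshold 5.94
#' is the Bonferroni-adjusted significance level of the original survey,
#' kept as a configurable constant.
#'
#' @param lp score from [lpScore()] (vectorized).
#' @param threshold significance threshold (default 5.94).
#' @return character vector in `{"OR", "NS", "UR"}`.
#' @export
classifyWord <- function(lp, threshold = 5.94) {
  ifelse(lp > threshold, "OR", ifelse(lp < -threshold, "UR", "NS"))
}

#' Rescale exceptionality scores between databases of different size
#'
#' Extreme pattern scores grow linearly with database size (large
#' deviations), so scores from a second database are made comparable to a
#' reference by multiplying with the ratio of total letter counts.
#'
#' @param scores numeric scores from the second database.
#' @param sizeRef,sizeOther total letter counts of the reference and the
#'   second database (both positive).
#' @return rescaled scores.
#' @export
rescaleScores <- function(scores, sizeRef, sizeOther) {
  if (sizeRef <= 0 || sizeOther <= 0) stop("database sizes must be positive")
  scores * (sizeRef / sizeOther)
}

#' Exceptionality table for a set of words
#'
#' Runs [wordPvalue()], [lpScore()] and [classifyWord()] for each word.
#'
#' @param counts named integer vector of observed counts (names = words),
#'   e.g. from `clusterWords()$summary`.
#' @param background a [BackgroundModel].
#' @param lengths corpus length multiset (default from the background).
#' @param threshold classification threshold on `|L_p|`.
#' @param ... passed to [wordPvalue()].
#' @return data.frame `word`, `N_w`, `expected`, `p_over`, `p_under`,
#'   `lp`, `class`, `method`.
#' @export
wordExceptionality <- function(counts, background,
                               lengths = background@lengths,
                               threshold = 5.94, ...) {
  rows <- lapply(names(counts), function(w) {
    r <- wordPvalue(w, background, lengths = lengths,
                    observed = as.integer(counts[[w]]), ...)
    lp <- lpScore(r$p_over, r$p_under, r$observed, r$expected)
    data.frame(word = w, N_w = r$observed, expected = r$expected,
               p_over = r$p_over, p_under = r$p_under, lp = lp,
               class = classifyWord(lp, threshold), method = r$method,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
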