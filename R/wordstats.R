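## Per-word statistics: structural variability (superposed C-alpha RMSD),
## positional amino-acid Z-score profiles, and loop-type preference
## (Kullback-Leibler divergence with a chi-square / G-test).

#' Optimal-superposition C-alpha RMSD between two fragments
#'
#' Least-squares rigid-body superposition (rotation + translation,
#' reflections disallowed) of two equal-length point sets, followed by the
#' root-mean-square deviation. The rotation is the Kabsch solution: SVD of
#' the cross-covariance with the smallest singular direction flipped when
#' the determinant would be negative.
#'
#' @param fragA,fragB m x 3 coordinate matrices (angstroms).
#' @return RMSD in angstroms; symmetric in its arguments.
#' @export
superposeRMSD <- function(fragA, fragB) {
  A <- as.matrix(fragA); B <- as.matrix(fragB)
  if (!all(dim(A) == dim(B)) || ncol(A) != 3)
    stop("fragments must be m x 3 matrices of equal size")
  A <- sweep(A, 2, colMeans(A))
  B <- sweep(B, 2, colMeans(B))
  s <- svd(crossprod(B, A))          # maps A onto B
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sqrt(mean(rowSums((A %*% t(R) - B)^2)))
}

#' Intra-word structural variability (RMSd_w)
#'
#' Average superposed RMSD over all pairs among `min(nSample, N_w)`
#' cluster members sampled without replacement (seeded). Clusters of
#' fewer than two members have undefined variability (`NA`).
#'
#' @param cluster a [WordCluster] with coordinates.
#' @param nSample number of fragments to sample (default 30).
#' @param seed RNG seed; the same seed always selects the same members.
#' @return mean pairwise RMSD in angstroms, or `NA` if `N_w < 2`.
#' @export
intraWordRMSD <- function(cluster, nSample = 30, seed = 1) {
  n <- clusterSize(cluster)
  if (n < 2 || !length(cluster@coords)) return(NA_real_)
  take <- min(nSample, n)
  idx <- if (take == n) seq_len(n) else withSeed(seed, sample.int(n, take))
  xs <- cluster@coords[idx]
  pr <- utils::combn(take, 2)
  mean(vapply(seq_len(ncol(pr)), function(j)
    superposeRMSD(xs[[pr[1, j]]], xs[[pr[2, j]]]), 0))
}

#' Inter-word structural dissimilarity (RMSd_dev)
#'
#' Average superposed RMSD over `nPairs` random cross-pairs, one fragment
#' drawn from each cluster per pair (seeded; pairs are drawn with
#' replacement, so the value depends on the seed and on the argument
#' order of the sampling, though it is symmetric in expectation). When
#' both clusters are singletons the single cross-pair is used.
#'
#' @param clusterA,clusterB [WordCluster] objects with coordinates.
#' @param nPairs number of random pairs (default 30).
#' @param seed RNG seed.
#' @return mean RMSD in angstroms.
#' @export
interWordRMSD <- function(clusterA, clusterB, nPairs = 30, seed = 1) {
  nA <- length(clusterA@coords); nB <- length(clusterB@coords)
  if (nA < 1 || nB < 1)
    stop("both clusters must be non-empty and carry coordinates")
  if (nA * nB <= nPairs) {
    pr <- expand.grid(i = seq_len(nA), j = seq_len(nB))
  } else {
    pr <- withSeed(seed, data.frame(i = sample.int(nA, nPairs, replace = TRUE),
                                    j = sample.int(nB, nPairs, replace = TRUE)))
  }
  mean(vapply(seq_len(nrow(pr)), function(r)
    superposeRMSD(clusterA@coords[[pr$i[r]]], clusterB@coords[[pr$j[r]]]), 0))
}

## ---- amino-acid Z-score profiles ------------------------------------

.aa_order <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Positional amino-acid counts of a set of fragment sequences
#'
#' Counts each amino acid at each of the fragment positions, the building
#' block for both a cluster's observed counts and the whole-bank
#' background counts `N_{a,l}`.
#'
#' @param sequences character vector of equal-length one-letter-code
#'   sequences.
#' @param nPos number of positions (default from the first sequence).
#' @return integer matrix `nPos x 20` (columns in the order
#'   `ACDEFGHIKLMNPQRSTVWY`).
#' @export
aaCounts <- function(sequences, nPos = nchar(sequences[1])) {
  out <- matrix(0L, nPos, length(.aa_order),
                dimnames = list(NULL, .aa_order))
  if (!length(sequences)) return(out)
  m <- do.call(rbind, strsplit(sequences, ""))
  for (p in seq_len(nPos)) {
    tb <- table(factor(m[, p], levels = .aa_order))
    out[p, ] <- as.integer(tb)
  }
  out
}

#' Positional amino-acid Z-score profile of a word cluster
#'
#' For amino acid `a` at fragment position `l`, the observed count in the
#' cluster is compared with the count expected if the cluster drew its
#' sequences at random from the whole fragment bank:
#' `mu = N_{a,l} * N_w / N`, where `N_{a,l}` is the bank-wide count of
#' `a` at position `l`, `N_w` the cluster size and `N` the bank size. The
#' count is approximated as Poisson, giving `Z = (obs - mu) / sqrt(mu)`.
#' Cells with `mu <= 5` are masked invalid and excluded from `Z_max` and
#' from the count of significant positions (positions with at least one
#' valid `Z >= cutoff`; positive Z means over-representation).
#'
#' @param cluster a [WordCluster] with sequences, or a precomputed
#'   observed-count matrix (`positions x 20`, columns ordered
#'   `ACDEFGHIKLMNPQRSTVWY`) — the count interface lets profiles be
#'   computed without materializing sequences.
#' @param backgroundCounts bank-wide positional count matrix `N_{a,l}`
#'   (same shape), e.g. from [aaCounts()] over all fragments.
#' @param N total number of fragments in the bank.
#' @param Nw cluster size; taken from `cluster` when it is a
#'   [WordCluster].
#' @param cutoff significance cutoff on Z (default 4, Bonferroni-style).
#' @param minExpected validity threshold on the expected count (cells
#'   with `mu <= minExpected` are masked; default 5).
#' @param word word label for the profile.
#' @return a [ZProfile].
#' @export
zscoreProfile <- function(cluster, backgroundCounts, N, Nw = NULL,
                          cutoff = 4, minExpected = 5, word = NULL) {
  if (is(cluster, "WordCluster")) {
    if (is.null(word)) word <- cluster@word
    if (is.null(Nw)) Nw <- clusterSize(cluster)
    obs <- aaCounts(cluster@sequences, nPos = nrow(backgroundCounts))
  } else {
    obs <- as.matrix(cluster)
    if (is.null(Nw)) Nw <- as.integer(round(sum(obs[1, ])))
    if (is.null(word)) word <- "word"
  }
  if (N <= 0) stop("total fragment count N must be positive")
  if (Nw > N) stop("cluster size exceeds the total fragment count")
  if (!all(dim(obs) == dim(backgroundCounts)))
    stop("observed and background count matrices differ in shape")
  mu <- backgroundCounts * Nw / N
  valid <- mu > minExpected
  z <- matrix(NA_real_, nrow(obs), ncol(obs), dimnames = dimnames(obs))
  z[mu > 0] <- (obs[mu > 0] - mu[mu > 0]) / sqrt(mu[mu > 0])
  zMax <- if (any(valid)) max(z[valid]) else NA_real_
  sig <- valid & !is.na(z) & z >= cutoff
  new("ZProfile", word = word, z = z, valid = valid,
      expected = mu, observed = obs + 0,
      zMax = zMax, nbPosSig = as.integer(sum(rowSums(sig) > 0)),
      cutoff = cutoff)
}

#' Euclidean distance between two Z-score profiles
#'
#' Masked (invalid) cells are treated as 0 in both vectors, keeping
#' distances comparable across words with different validity masks.
#'
#' @param profileA,profileB [ZProfile] objects of the same shape.
#' @return non-negative Euclidean distance over the flattened profiles.
#' @export
zscoreDistance <- function(profileA, profileB) {
  za <- zMatrix(profileA); zb <- zMatrix(profileB)
  if (!all(dim(za) == dim(zb)))
    stop("profiles have different shapes")
  za[!validMask(profileA) | is.na(za)] <- 0
  zb[!validMask(profileB) | is.na(zb)] <- 0
  sqrt(sum((za - zb)^2))
}

## ---- loop-type preference (KLD) -------------------------------------

#' Kullback-Leibler loop-type preference of one word
#'
#' Compares the distribution of a word's fragments over loop types with
#' the global loop-type distribution using the asymmetric divergence
#' `KLD(w) = sum_l p_{w,l} ln(p_{w,l} / p_l)` (natural log; terms with
#' `p_{w,l} = 0` contribute 0). `2 * N_w * KLD(w)` is the G statistic and
#' is referred to a chi-square distribution, by default with
#' `length(globalProbs) - 1` degrees of freedom (`dfAsPaper = TRUE`
#' switches to `N_w - 1`).
#'
#' @param typeCounts named integer vector of the word's fragment counts
#'   per loop type (zeros allowed).
#' @param globalProbs named probability vector of loop-type frequencies,
#'   strictly positive for every type occupied by the word.
#' @param dfAsPaper use `N_w - 1` degrees of freedom instead of the
#'   number of types minus one.
#' @return list `kld` (nats), `stat`, `df`, `p`, `preferred` (type with
#'   the largest `p_{w,l}/p_l` ratio).
#' @export
kldPreference <- function(typeCounts, globalProbs, dfAsPaper = FALSE) {
  typeCounts <- typeCounts[names(globalProbs)]
  typeCounts[is.na(typeCounts)] <- 0
  names(typeCounts) <- names(globalProbs)
  Nw <- sum(typeCounts)
  if (Nw == 0) stop("word has no fragments in any loop type")
  if (any(globalProbs[typeCounts > 0] <= 0))
    stop("global probability is zero for an occupied loop type")
  pw <- typeCounts / Nw
  pos <- pw > 0
  kld <- sum(pw[pos] * log(pw[pos] / globalProbs[pos]))
  df <- if (dfAsPaper) Nw - 1 else length(globalProbs) - 1
  stat <- 2 * Nw * kld
  ratio <- ifelse(globalProbs > 0, pw / globalProbs, 0)
  list(kld = kld, stat = stat, df = df,
       p = pchisq(stat, df = df, lower.tail = FALSE),
       preferred = names(globalProbs)[which.max(ratio)])
}

#' Loop-type preference for every retained word, with FDR correction
#'
#' Joins the fragment table to the loop table to label each fragment with
#' its loop type under one of three partitions — length (`short`/`long`),
#' flank class (`aa`, `ab`, `ba`, `bb`), or their 8-type product — then
#' tests every word with [kldPreference()] and adjusts the p-values by
#' Benjamini-Hochberg across words. The global type frequencies are taken
#' from the loop bank.
#'
#' @param fragments fragment table (`loop_id`, `word`).
#' @param loops loop table with `length_class` and `flank_class`.
#' @param partition `"length"`, `"flank"` or `"both"`.
#' @param alpha FDR level for the significance flag (default 0.05).
#' @param words words to test (default all words in `fragments`).
#' @param dfAsPaper see [kldPreference()].
#' @return data.frame `word`, `N_w`, `kld`, `stat`, `df`, `p`, `p_adj`,
#'   `significant`, `preferred` (`NA` when not significant).
#' @export
loopTypePreference <- function(fragments, loops,
                               partition = c("length", "flank", "both"),
                               alpha = 0.05, words = NULL,
                               dfAsPaper = FALSE) {
  partition <- match.arg(partition)
  idx <- match(fragments$loop_id, loops$loop_id)
  lab <- switch(partition,
    length = loops$length_class[idx],
    flank = loops$flank_class[idx],
    both = paste(loops$flank_class[idx], loops$length_class[idx], sep = "_"))
  loopLab <- switch(partition,
    length = loops$length_class,
    flank = loops$flank_class,
    both = paste(loops$flank_class, loops$length_class, sep = "_"))
  types <- sort(unique(loopLab))
  p0 <- as.numeric(table(factor(loopLab, levels = types))) / length(loopLab)
  names(p0) <- types
  if (is.null(words)) words <- sort(unique(fragments$word))
  rows <- lapply(words, function(w) {
    cnt <- table(factor(lab[fragments$word == w], levels = types))
    res <- kldPreference(as.integer(cnt) |> setNames(types), p0,
                         dfAsPaper = dfAsPaper)
    data.frame(word = w, N_w = sum(cnt), kld = res$kld, stat = res$stat,
               df = res$df, p = res$p, preferred = res$preferred,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out$significant <- out$p_adj < alpha
  out$preferred[!out$significant] <- NA_character_
  rownames(out) <- NULL
  out[, c("word", "N_w", "kld", "stat", "df", "p", "p_adj",
          "significant", "preferred")]
}
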