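## Structural words: overlapping k-letter substrings of loops, fragment
## clusters, coverage rates, B-factor flags and the word-length survey.

.default_ss_letters <- c("A", "a", "V", "W", "L", "M", "N", "T", "X")

#' Split a loop into overlapping structural words
#'
#' A loop of `l` structural letters yields the `l - k + 1` overlapping
#' words of `k` letters (for the default `k = 4`: `l - 3` words, each a
#' seven-residue fragment). Words that begin or end with a letter specific
#' to regular secondary structures (default `A a V W L M N T X`) are then
#' excluded, because such fragments protrude into the flanking helix or
#' strand.
#'
#' @param letters loop letter string (or a one-row loop record from
#'   [extractLoops()]).
#' @param k word length in letters (default 4).
#' @param ssLetters letters excluded at word boundaries; set to
#'   `character()` to keep everything.
#' @param loopId loop identifier recorded in the output.
#' @return data.frame with columns `loop_id`, `position` (1-based within
#'   the loop letters), `word`; attribute `nBeforeExclusion` records the
#'   pre-exclusion word count.
#' @examples
#' extractWords("BGFKD")
#' @export
extractWords <- function(letters, k = 4, ssLetters = .default_ss_letters,
                         loopId = "loop") {
  if (is.data.frame(letters)) {
    loopId <- letters$loop_id[1]
    letters <- letters$letters[1]
  }
  l <- nchar(letters)
  out <- data.frame(loop_id = character(), position = integer(),
                    word = character(), stringsAsFactors = FALSE)
  if (l < k) { attr(out, "nBeforeExclusion") <- 0L; return(out) }
  p <- seq_len(l - k + 1L)
  w <- substring(letters, p, p + k - 1L)
  out <- data.frame(loop_id = loopId, position = p, word = w,
                    stringsAsFactors = FALSE)
  nb <- nrow(out)
  if (length(ssLetters)) {
    keep <- !(substr(w, 1, 1) %in% ssLetters |
              substr(w, k, k) %in% ssLetters)
    out <- out[keep, , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "nBeforeExclusion") <- nb
  out
}

#' Build the fragment table of a loop bank
#'
#' Applies [extractWords()] to every loop and, when per-chain C-alpha
#' data are supplied, attaches each fragment's coordinates, amino-acid
#' sequence and mean C-alpha B-factor. A word at loop position `p` covers
#' residues `res_start + p - 1` to `res_start + p + k + 1` of the chain
#' (`k + 3` residues).
#'
#' @param loops loop table from [extractLoops()].
#' @param chains optional named list of chain records (elements `ca`
#'   n x 3 matrix, `bfactor`, `sequence` a one-letter-code string), e.g.
#'   from [readStructure()].
#' @inheritParams extractWords
#' @return data.frame `loop_id`, `position`, `word` plus, with chain
#'   data, `aa`, `mean_bfactor` and a list column `ca` of coordinate
#'   matrices; attribute `nBeforeExclusion`.
#' @export
buildFragments <- function(loops, chains = NULL, k = 4,
                           ssLetters = .default_ss_letters) {
  tabs <- lapply(seq_len(nrow(loops)), function(i)
    extractWords(loops$letters[i], k = k, ssLetters = ssLetters,
                 loopId = loops$loop_id[i]))
  nb <- sum(vapply(tabs, function(t) attr(t, "nBeforeExclusion"), 0L))
  frag <- do.call(rbind, tabs)
  rownames(frag) <- NULL
  if (!is.null(chains) && nrow(frag)) {
    idx <- match(frag$loop_id, loops$loop_id)
    first <- loops$res_start[idx] + frag$position - 1L
    chainId <- loops$chain[idx]
    res <- lapply(seq_len(nrow(frag)), function(i) {
      ch <- chains[[chainId[i]]]
      span <- first[i]:(first[i] + k + 2L)
      list(ca = ch$ca[span, , drop = FALSE],
           aa = substr(ch$sequence, span[1], span[length(span)]),
           b = mean(ch$bfactor[span]))
    })
    frag$aa <- vapply(res, `[[`, "", "aa")
    frag$mean_bfactor <- vapply(res, `[[`, 0, "b")
    frag$ca <- I(lapply(res, `[[`, "ca"))
  }
  attr(frag, "nBeforeExclusion") <- nb
  frag
}

#' Group fragments into word clusters
#'
#' Fragments are grouped by exact word identity; every fragment belongs to
#' exactly one cluster. The retained subset keeps clusters with at least
#' `minCount` members (default 30, the recurrent-word threshold).
#'
#' @param fragments fragment table from [buildFragments()] or
#'   [extractWords()].
#' @param minCount minimum cluster size for the retained subset.
#' @return list with elements `clusters` (named list of [WordCluster]),
#'   `summary` (data.frame `word`, `N_w`, `retained`), `retained`
#'   (character vector of retained words) and `nSingletons`.
#' @export
clusterWords <- function(fragments, minCount = 30) {
  if (!nrow(fragments))
    return(list(clusters = list(),
                summary = data.frame(word = character(), N_w = integer(),
                                     retained = logical()),
                retained = character(), nSingletons = 0L))
  idx <- split(seq_len(nrow(fragments)), fragments$word)
  clusters <- lapply(idx, function(i) {
    new("WordCluster",
        word = fragments$word[i[1]],
        fragments = fragments[i, c("loop_id", "position"), drop = FALSE],
        coords = if (!is.null(fragments$ca))
                   unname(as.list(unclass(fragments$ca))[i]) else list(),
        sequences = if (!is.null(fragments$aa)) fragments$aa[i]
                    else character(),
        bfactors = if (!is.null(fragments$mean_bfactor))
                     fragments$mean_bfactor[i] else numeric())
  })
  nw <- vapply(clusters, clusterSize, 0L)
  summary <- data.frame(word = names(clusters), N_w = as.integer(nw),
                        retained = nw >= minCount, stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  list(clusters = clusters, summary = summary,
       retained = summary$word[summary$retained],
       nSingletons = sum(nw == 1L))
}

## all overlapping match start positions of `word` in `s`
.wordMatches <- function(word, s) {
  m <- Biostrings::matchPattern(word, Biostrings::BString(s))
  BiocGenerics::start(m)
}

#' Per-letter loop coverage by a word set
#'
#' For each loop, every occurrence of every word of `wordSet` in the
#' loop's letter string is located; the covered letters are the union of
#' the spanned positions (overlapping matches counted once). The global
#' rate is total covered letters over total loop letters.
#'
#' @param loops loop table from [extractLoops()] (columns `loop_id`,
#'   `letters`, `n_letters`).
#' @param wordSet character vector of structural words.
#' @return list with `rate` (fraction in `[0, 1]`) and `detail`
#'   (data.frame `loop_id`, `n_letters`, `covered`).
#' @export
coverageRate <- function(loops, wordSet) {
  wordSet <- unique(wordSet)
  covered <- vapply(seq_len(nrow(loops)), function(i) {
    s <- loops$letters[i]
    pos <- logical(nchar(s))
    for (w in wordSet) {
      if (nchar(w) > nchar(s)) next
      for (st in .wordMatches(w, s)) pos[st:(st + nchar(w) - 1L)] <- TRUE
    }
    sum(pos)
  }, 0)
  detail <- data.frame(loop_id = loops$loop_id,
                       n_letters = loops$n_letters,
                       covered = as.integer(covered),
                       stringsAsFactors = FALSE)
  tot <- sum(loops$n_letters)
  list(rate = if (tot > 0) sum(covered) / tot else 0, detail = detail)
}

#' Flag clusters of fragments with high positional uncertainty
#'
#' Computes the mean over cluster members of the per-fragment mean
#' C-alpha B-factor and flags the cluster when it strictly exceeds the
#' cutoff (default 40, the usual rule of thumb for mobile regions).
#'
#' @param cluster a [WordCluster].
#' @param cutoff B-factor cutoff in square angstroms.
#' @return list `mean` (numeric) and `flag` (`TRUE`/`FALSE`, or
#'   `"unknown"` when B-factors are absent).
#' @export
flagHighBfactor <- function(cluster, cutoff = 40) {
  b <- cluster@bfactors
  if (!length(b) || anyNA(b)) {
    message("cluster '", cluster@word, "': B-factors missing, flag unknown")
    return(list(mean = NA_real_, flag = "unknown"))
  }
  m <- mean(b)
  list(mean = m, flag = m > cutoff)
}

#' Survey word frequencies across candidate word lengths
#'
#' For each word length `k`, counts the distinct words and total fragments
#' in the loop bank and reports the occurrence count below which 80% of
#' words fall — the data-sparsity diagnostic used to choose the working
#' word length.
#'
#' @param loops loop table from [extractLoops()].
#' @param kRange integer vector of word lengths (default 2:7, i.e. five to
#'   ten residues).
#' @param ssLetters boundary-exclusion letters applied when
#'   `applyExclusion = TRUE`; the survey counts all words by default.
#' @param applyExclusion apply the secondary-structure end-letter
#'   exclusion before counting?
#' @return data.frame `k`, `n_residues`, `n_distinct`, `n_fragments`,
#'   `q80_occurrences`.
#' @export
wordLengthSurvey <- function(loops, kRange = 2:7,
                             ssLetters = .default_ss_letters,
                             applyExclusion = FALSE) {
  rows <- lapply(kRange, function(k) {
    frag <- do.call(rbind, lapply(seq_len(nrow(loops)), function(i)
      extractWords(loops$letters[i], k = k,
                   ssLetters = if (applyExclusion) ssLetters else character(),
                   loopId = loops$loop_id[i])))
    counts <- if (!is.null(frag) && nrow(frag)) table(frag$word) else integer()
    data.frame(k = k, n_residues = k + 3L,
               n_distinct = length(counts),
               n_fragments = sum(counts),
               q80_occurrences = if (length(counts))
                 as.numeric(quantile(as.numeric(counts), 0.8, type = 1))
                 else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
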