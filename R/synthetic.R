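## Synthetic fixtures: Markov letter corpora with planted words,
## synthetic PDB structures (ideal helices/strands joined by perturbed
## connectors), and fragment amino-acid sequences with planted positional
## preferences. Every generator is a pure function of its arguments
## (seed included) and returns its ground truth alongside the data.

#' Generate a Markov letter corpus with planted words
#'
#' Samples sequences from a first-order letter Markov chain, then plants
#' extra copies of designated words by overwriting random positions:
#' for a word with enrichment factor `f` and analytic background
#' expectation `E0`, `round((f - 1) * E0)` extra copies are inserted
#' (factor 1 or 0 extra inserts nothing — the word still occurs at its
#' background rate).
#'
#' @param nSeq number of sequences.
#' @param lengths sequence length, recycled or sampled: either a single
#'   value, a vector of length `nSeq`, or a vector sampled with
#'   replacement.
#' @param background a [BackgroundModel] to sample from.
#' @param planted optional data.frame with columns `word` and `factor`.
#' @param seed RNG seed.
#' @return list `sequences` (character vector), `truth` (data.frame
#'   `word`, `factor`, `expected_background`, `n_inserted`).
#' @export
genLetterSequences <- function(nSeq, lengths, background, planted = NULL,
                               seed = 1) {
  K <- length(background@alphabet)
  trans <- background@transitions
  init <- background@initial
  withSeed(seed, {
    lens <- if (length(lengths) == nSeq) as.integer(lengths)
            else if (length(lengths) == 1) rep(as.integer(lengths), nSeq)
            else sample(as.integer(lengths), nSeq, replace = TRUE)
    cum <- t(apply(trans, 1, cumsum))
    seqs <- vapply(lens, function(len) {
      x <- integer(len)
      x[1] <- sample.int(K, 1, prob = init)
      if (len > 1) for (t in 2:len)
        x[t] <- max.col(matrix(runif(1) < cum[x[t - 1], ], 1),
                        ties.method = "first")
      paste(background@alphabet[x], collapse = "")
    }, "")
    truth <- NULL
    if (!is.null(planted) && nrow(planted)) {
      truth <- do.call(rbind, lapply(seq_len(nrow(planted)), function(i) {
        w <- planted$word[i]
        wInt <- match(strsplit(w, "")[[1]], background@alphabet)
        if (anyNA(wInt)) stop("planted word '", w, "' not over the alphabet")
        e0 <- .expectedCount(wInt, lens, trans, init)
        nIns <- max(0L, as.integer(round((planted$factor[i] - 1) * e0)))
        if (nIns > 0) {
          m <- nchar(w)
          ok <- which(lens >= m)
          for (j in seq_len(nIns)) {
            s <- sample(ok, 1)
            pos <- sample.int(lens[s] - m + 1L, 1)
            substr(seqs[s], pos, pos + m - 1L) <<- w
          }
        }
        data.frame(word = w, factor = planted$factor[i],
                   expected_background = e0, n_inserted = nIns,
                   stringsAsFactors = FALSE)
      }))
    }
    list(sequences = seqs, truth = truth)
  })
}

## ideal alpha-helix C-alpha trace: radius 2.3 A, rise 1.5 A/residue,
## 100 degree turn/residue
.helixTemplate <- function(n, radius = 2.3, rise = 1.5, turn = 100) {
  th <- (seq_len(n) - 1) * turn * pi / 180
  cbind(x = radius * cos(th), y = radius * sin(th),
        z = (seq_len(n) - 1) * rise)
}

## extended beta-strand C-alpha trace: ~3.8 A between consecutive C-alpha,
## zigzag in y
.strandTemplate <- function(n, rise = 3.36, offset = 0.9) {
  cbind(x = rep(0, n), y = offset * (-1)^(seq_len(n) - 1),
        z = (seq_len(n) - 1) * rise)
}

## rigid placement: translate `pts` so its first point continues from
## `from` along +z with spacing ~3.8
.place <- function(pts, from) {
  sweep(pts, 2, pts[1, ]) + matrix(from + c(0, 0, 3.8),
                                   nrow(pts), 3, byrow = TRUE)
}

#' Generate synthetic PDB structures with known secondary structure
#'
#' Builds chains as alternating ideal helix / strand segments joined by
#' perturbed connector ("loop") segments: connector C-alphas are linearly
#' interpolated between the flanking endpoints and jittered by Gaussian
#' noise of standard deviation `loopSigma`. Each chain is written to a
#' parseable PDB file with a `REMARK 2` resolution header, CA `ATOM`
#' records, per-atom B-factors and a random amino-acid sequence, so the
#' structure filters are exercisable. The per-residue ground-truth
#' secondary-structure labels are returned.
#'
#' @param nChains number of chains (one file per chain).
#' @param dir output directory (created if needed).
#' @param architecture character vector cycled along the chain,
#'   e.g. `c("helix", "loop", "strand", "loop", "helix")`.
#' @param helixLen,strandLen,loopLen length ranges (in residues) from
#'   which each segment's length is drawn uniformly.
#' @param loopSigma connector jitter standard deviation (angstroms).
#' @param resolution value written to the resolution header.
#' @param bfactor mean B-factor; per-atom values are jittered around it.
#' @param seed RNG seed; the same seed gives byte-identical files.
#' @return list `files` (paths), `truth` (data.frame `chain`, `residue`,
#'   `ss` in helix/strand/loop).
#' @export
genStructures <- function(nChains = 5, dir = tempfile("synthpdb"),
                          architecture = c("helix", "loop", "strand",
                                           "loop", "helix"),
                          helixLen = c(8, 12), strandLen = c(6, 9),
                          loopLen = c(4, 10), loopSigma = 0.4,
                          resolution = 1.8, bfactor = 20, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
           "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
           "TYR", "VAL")
  withSeed(seed, {
    files <- character(nChains)
    truth <- list()
    for (ci in seq_len(nChains)) {
      coords <- NULL
      labels <- character()
      last <- c(0, 0, 0)
      for (seg in architecture) {
        n <- switch(seg,
          helix = sample(helixLen[1]:helixLen[2], 1),
          strand = sample(strandLen[1]:strandLen[2], 1),
          loop = sample(loopLen[1]:loopLen[2], 1))
        if (seg == "loop") {
          ## straight interpolation toward a forward target + jitter
          ## (already in absolute coordinates)
          target <- last + c(0, 0, 3.5 * (n + 1))
          tfrac <- seq_len(n) / (n + 1)
          pts <- matrix(last, n, 3, byrow = TRUE) +
            outer(tfrac, target - last) +
            matrix(rnorm(3 * n, sd = loopSigma), n, 3)
        } else {
          pts <- if (seg == "helix") .helixTemplate(n) else .strandTemplate(n)
          if (!is.null(coords)) pts <- .place(pts, last)
        }
        coords <- rbind(coords, pts)
        last <- coords[nrow(coords), ]
        labels <- c(labels, rep(seg, n))
      }
      n <- nrow(coords)
      aaSeq <- sample(aa3, n, replace = TRUE)
      bf <- round(bfactor + rnorm(n, sd = 2), 2)
      id <- sprintf("SYN%02d", ci)
      path <- file.path(dir, paste0(tolower(id), ".pdb"))
      lines <- c(
        sprintf("HEADER    SYNTHETIC STRUCTURE                     01-JAN-26   %s", id),
        sprintf("REMARK   2 RESOLUTION.    %4.2f ANGSTROMS.", resolution),
        sprintf(paste0("ATOM  %5d  CA  %3s A%4d    ",
                       "%8.3f%8.3f%8.3f%6.2f%6.2f           C"),
                seq_len(n), aaSeq, seq_len(n),
                coords[, 1], coords[, 2], coords[, 3], 1.0, bf),
        "TER", "END")
      writeLines(lines, path)
      files[ci] <- path
      truth[[ci]] <- data.frame(chain = id, residue = seq_len(n),
                                ss = labels, stringsAsFactors = FALSE)
    }
    list(files = files, truth = do.call(rbind, truth))
  })
}

#' Generate fragment amino-acid sequences with planted preferences
#'
#' Draws fixed-length amino-acid sequences from background frequencies;
#' for designated (position, residue) cells the residue's probability is
#' multiplied by the fold enrichment (then renormalized), emulating a
#' positional sequence preference of a structural word.
#'
#' @param n number of sequences (the cluster size `N_w`).
#' @param len sequence length (default 7, a four-letter word).
#' @param bgFreqs background frequencies over the 20 amino acids
#'   (default uniform; order `ACDEFGHIKLMNPQRSTVWY`).
#' @param planted optional data.frame with columns `position`, `aa`,
#'   `fold`.
#' @param seed RNG seed.
#' @return list `sequences` (character vector), `truth` (the planted
#'   table with the realized per-position probability).
#' @export
genFragmentSequences <- function(n, len = 7,
                                 bgFreqs = rep(1 / 20, 20),
                                 planted = NULL, seed = 1) {
  aa <- .aa_order
  stopifnot(length(bgFreqs) == 20)
  probs <- matrix(bgFreqs, len, 20, byrow = TRUE,
                  dimnames = list(NULL, aa))
  truth <- NULL
  if (!is.null(planted) && nrow(planted)) {
    for (i in seq_len(nrow(planted))) {
      p <- planted$position[i]
      probs[p, planted$aa[i]] <- probs[p, planted$aa[i]] * planted$fold[i]
      probs[p, ] <- probs[p, ] / sum(probs[p, ])
    }
    truth <- planted
    truth$prob <- probs[cbind(planted$position, match(planted$aa, aa))]
  }
  seqs <- withSeed(seed, {
    draws <- vapply(seq_len(len), function(p)
      sample(aa, n, replace = TRUE, prob = probs[p, ]), character(n))
    if (n == 1) draws <- matrix(draws, 1)
    apply(draws, 1, paste, collapse = "")
  })
  list(sequences = seqs, truth = truth)
}
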