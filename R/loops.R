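## Segmentation of structural-letter strings into regular secondary
## structures and loops.

.default_helix_pattern <- "[AaVW]{4,}"
.default_strand_pattern <- "[LMNTX]{3,}"

.matchesEmpty <- function(pattern) {
  m <- regexpr(pattern, "", perl = TRUE)
  m[1] != -1
}

#' Segment a letter string into helix, strand and coil runs
#'
#' Helix and strand segments are maximal matches of the configured
#' regular expressions over the structural letters (defaults: runs of at
#' least four helix letters `[AaVW]`, runs of at least three strand
#' letters `[LMNTX]`). Helix matches are assigned first; strand matches
#' are then searched in the remaining positions. Everything else is coil.
#' The returned segments tile the string with no gaps or overlaps.
#'
#' @param letters a single structural-letter string.
#' @param helixPattern,strandPattern regular expressions describing
#'   simplified helices and strands; neither may match the empty string.
#' @return data.frame with columns `start`, `end` (1-based inclusive
#'   letter indices) and `type` (`"helix"`, `"strand"` or `"coil"`).
#' @examples
#' segmentSecondaryStructure("AAAAABGFKLLLL")
#' @export
segmentSecondaryStructure <- function(letters,
                                      helixPattern = .default_helix_pattern,
                                      strandPattern = .default_strand_pattern) {
  stopifnot(is.character(letters), length(letters) == 1)
  if (.matchesEmpty(helixPattern) || .matchesEmpty(strandPattern))
    stop("secondary-structure patterns must not match the empty string")
  n <- nchar(letters)
  if (n == 0)
    return(data.frame(start = integer(), end = integer(),
                      type = character()))
  lab <- rep("coil", n)
  mark <- function(s, pattern, avoid) {
    m <- gregexpr(pattern, s, perl = TRUE)[[1]]
    if (m[1] != -1)
      for (j in seq_along(m)) {
        span <- m[j]:(m[j] + attr(m, "match.length")[j] - 1)
        lab[span] <<- avoid
      }
  }
  mark(letters, helixPattern, "helix")
  ## mask helix positions so strand runs cannot straddle them
  masked <- strsplit(letters, "")[[1]]
  masked[lab == "helix"] <- "-"
  mark(paste(masked, collapse = ""), strandPattern, "strand")
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  data.frame(start = ends - r$lengths + 1L, end = ends, type = r$values,
             stringsAsFactors = FALSE)
}

#' Extract loop records from a segmentation
#'
#' Every coil segment of at least `minLetters` structural letters that
#' lies between two regular secondary structures becomes a loop record. A
#' loop of `l` letters spans `l + 3` residues. Flanks are the types of the
#' neighbouring segments; the flank class is one of `"aa"`, `"ab"`,
#' `"ba"`, `"bb"` (`a` = helix, `b` = strand) or `"terminal"`. Terminal
#' coils (touching a chain end) are excluded unless `keepTerminal = TRUE`.
#' Loops longer than 12 residues (10 or more letters) are classed long.
#'
#' @param segments segmentation from [segmentSecondaryStructure()].
#' @param letters the segmented letter string.
#' @param chain chain identifier recorded in the output.
#' @param minLetters minimum loop length in letters (default 4, the word
#'   length).
#' @param keepTerminal keep coils flanked by a chain terminus?
#' @return data.frame with one row per loop: `loop_id`, `chain`,
#'   `start_letter`, `end_letter`, `n_letters`, `n_residues`, `letters`,
#'   `res_start`, `res_end`, `left_flank`, `right_flank`, `flank_class`,
#'   `length_class`.
#' @export
extractLoops <- function(segments, letters, chain = "chain",
                         minLetters = 4, keepTerminal = FALSE) {
  stopifnot(is.data.frame(segments))
  empty <- data.frame(loop_id = character(), chain = character(),
                      start_letter = integer(), end_letter = integer(),
                      n_letters = integer(), n_residues = integer(),
                      letters = character(), res_start = integer(),
                      res_end = integer(), left_flank = character(),
                      right_flank = character(), flank_class = character(),
                      length_class = character(), stringsAsFactors = FALSE)
  coil <- which(segments$type == "coil")
  if (!length(coil)) return(empty)
  rows <- lapply(coil, function(i) {
    st <- segments$start[i]; en <- segments$end[i]
    l <- en - st + 1L
    if (l < minLetters) return(NULL)
    lf <- if (i > 1) segments$type[i - 1] else "terminus"
    rf <- if (i < nrow(segments)) segments$type[i + 1] else "terminus"
    terminal <- lf == "terminus" || rf == "terminus"
    if (terminal && !keepTerminal) return(NULL)
    fc <- if (terminal) "terminal" else
      paste0(ifelse(lf == "helix", "a", "b"), ifelse(rf == "helix", "a", "b"))
    data.frame(loop_id = paste0(chain, ":", st, "-", en), chain = chain,
               start_letter = st, end_letter = en, n_letters = l,
               n_residues = l + 3L,
               letters = substr(letters, st, en),
               res_start = st, res_end = en + 3L,
               left_flank = lf, right_flank = rf, flank_class = fc,
               length_class = if (l + 3L > 12L) "long" else "short",
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Segment and extract loops for a set of encoded chains
#'
#' Convenience wrapper applying [segmentSecondaryStructure()] and
#' [extractLoops()] to a named character vector of letter strings.
#'
#' @param letterStrings named character vector (names = chain ids).
#' @inheritParams segmentSecondaryStructure
#' @inheritParams extractLoops
#' @return combined loop table (see [extractLoops()]).
#' @export
extractLoopsFromStrings <- function(letterStrings,
                                    helixPattern = .default_helix_pattern,
                                    strandPattern = .default_strand_pattern,
                                    minLetters = 4, keepTerminal = FALSE) {
  ids <- names(letterStrings)
  if (is.null(ids)) ids <- paste0("chain", seq_along(letterStrings))
  tabs <- lapply(seq_along(letterStrings), function(i) {
    seg <- segmentSecondaryStructure(letterStrings[[i]], helixPattern,
                                     strandPattern)
    extractLoops(seg, letterStrings[[i]], chain = ids[i],
                 minLetters = minLetters, keepTerminal = keepTerminal)
  })
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  out
}
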