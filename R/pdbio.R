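## Structure input with the survey's data filters: C-alpha traces,
## B-factors, sequence and resolution per chain, with explicit
## accept/reject verdicts.

.aa321 <- function(aa3) {
  map <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
           GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
           LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
           SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
  out <- map[aa3]
  out[is.na(out)] <- "X"
  out
}

.parseResolution <- function(path) {
  hdr <- readLines(path, n = 200, warn = FALSE)
  rl <- grep("^REMARK   2 RESOLUTION", hdr, value = TRUE)
  if (!length(rl)) return(NA_real_)
  tail <- sub(".*RESOLUTION\\.?", "", rl[1])
  m <- regmatches(tail, regexpr("[0-9]+\\.?[0-9]*", tail))
  if (!length(m)) return(NA_real_)   # e.g. "NOT APPLICABLE" (NMR)
  as.numeric(m)
}

#' Read a PDB file into per-chain C-alpha records, with quality filters
#'
#' Parses the file with bio3d, extracts each chain's C-alpha trace,
#' per-residue B-factors and amino-acid sequence, reads the resolution
#' from the `REMARK 2` header, and applies the chain filters of the
#' survey: at least `minResidues` residues (default 30), resolution
#' better than `maxResolution` angstroms (default 2.5; chains from
#' entries without a numeric resolution are rejected while this filter is
#' active), no missing residues (gaps in residue numbering or absent
#' C-alpha atoms) and no alternate conformations on C-alpha atoms.
#' Rejected chains are returned with their reasons, never silently
#' dropped.
#'
#' @param path PDB file.
#' @param minResidues minimum chain length.
#' @param maxResolution resolution cutoff in angstroms; `Inf` disables
#'   the filter.
#' @return list of chain records; each is a list with `id` (pdbid_chain),
#'   `chain`, `ca` (n x 3 matrix), `bfactor`, `sequence`, `resno`
#'   (author residue numbers), `resolution`, `accepted`, `reasons`.
#' @export
readStructure <- function(path, minResidues = 30, maxResolution = 2.5) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e)
                    stop("unparseable PDB file '", path, "': ",
                         conditionMessage(e)))
  resolution <- .parseResolution(path)
  atoms <- pdb$atom
  ca <- atoms[atoms$type == "ATOM" & atoms$elety == "CA", , drop = FALSE]
  if (!nrow(ca))
    stop("unparseable PDB file '", path, "': no C-alpha ATOM records")
  pdbId <- sub("\\.pdb$", "", basename(path))
  lapply(split(ca, ca$chain), function(at) {
    reasons <- character()
    hasAlt <- any(!is.na(at$alt) & at$alt != "")
    if (hasAlt) reasons <- c(reasons, "altloc")
    ## keep one row per residue for coordinates even when rejecting
    dedup <- at[!duplicated(at$resno), , drop = FALSE]
    n <- nrow(dedup)
    if (n < minResidues) reasons <- c(reasons, "min_residues")
    if (n > 1 && any(diff(dedup$resno) != 1))
      reasons <- c(reasons, "missing_residues")
    if (is.finite(maxResolution) &&
        (is.na(resolution) || resolution >= maxResolution))
      reasons <- c(reasons, "resolution")
    list(id = paste0(pdbId, "_", dedup$chain[1]),
         chain = dedup$chain[1],
         ca = unname(as.matrix(dedup[, c("x", "y", "z")])),
         bfactor = dedup$b,
         sequence = paste(.aa321(dedup$resid), collapse = ""),
         resno = dedup$resno,
         resolution = resolution,
         accepted = length(reasons) == 0L,
         reasons = reasons)
  })
}

#' Read several PDB files
#'
#' @param paths PDB file paths.
#' @inheritParams readStructure
#' @return list with `chains` (named list of accepted chain records),
#'   `rejected` (named list of rejected records) and `summary`
#'   (data.frame `id`, `n_residues`, `resolution`, `accepted`,
#'   `reasons`).
#' @export
readStructures <- function(paths, minResidues = 30, maxResolution = 2.5) {
  recs <- unlist(lapply(paths, readStructure, minResidues = minResidues,
                        maxResolution = maxResolution), recursive = FALSE)
  names(recs) <- vapply(recs, `[[`, "", "id")
  acc <- vapply(recs, `[[`, TRUE, "accepted")
  summary <- data.frame(
    id = names(recs),
    n_residues = vapply(recs, function(r) nrow(r$ca), 0L),
    resolution = vapply(recs, `[[`, 0, "resolution"),
    accepted = acc,
    reasons = vapply(recs, function(r) paste(r$reasons, collapse = ";"), ""),
    stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  list(chains = recs[acc], rejected = recs[!acc], summary = summary)
}

## ---- letter-string FASTA I/O ----------------------------------------

#' Read / write structural-letter strings in FASTA dialect
#'
#' One record per chain: a `>chain_id` header line followed by the
#' letter string.
#'
#' @param x named character vector of letter strings.
#' @param path file path.
#' @return `readLetterStrings()` returns a named character vector;
#'   `writeLetterStrings()` returns `path` invisibly.
#' @export
writeLetterStrings <- function(x, path) {
  set <- Biostrings::BStringSet(x)
  names(set) <- names(x)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' @rdname writeLetterStrings
#' @export
readLetterStrings <- function(path) {
  set <- Biostrings::readBStringSet(path)
  out <- as.character(set)
  names(out) <- names(set)
  out
}
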