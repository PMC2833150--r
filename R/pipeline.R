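## End-to-end pipeline: encode -> loops -> words -> per-word statistics
## -> exceptionality, with TSV outputs and a JSON run manifest.

.writeTSV <- function(df, path) {
  df <- df[, !vapply(df, is.list, TRUE), drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.defaultConfig <- function() {
  list(k = 4, minCount = 30, minLoopLetters = 4,
       helixPattern = .default_helix_pattern,
       strandPattern = .default_strand_pattern,
       ssLetters = paste(.default_ss_letters, collapse = ""),
       bfactorCutoff = 40, lpThreshold = 5.94, alpha = 0.05,
       minResidues = 30, maxResolution = 2.5,
       rmsdSample = 30, seed = 1)
}

#' Run the full loop-word mining pipeline
#'
#' Stages: read structures (PDB) or pre-encoded letter strings (FASTA
#' dialect), encode with the alphabet model, segment into secondary
#' structures and extract loops, decompose loops into structural words
#' and cluster the fragments, compute per-word statistics (B-factor
#' flag, intra-word RMSD, Z-score profile, loop-type preferences) for
#' retained words, fit the Markov background on the loop corpus and
#' score every retained word's exceptionality. All tables are written as
#' TSV in `outputDir` together with a JSON manifest recording the
#' configuration, seed and per-stage counts; a rerun with identical
#' config and inputs writes identical tables. Any stage failure aborts
#' with the stage name and removes the partial output directory.
#'
#' @param config list (or path to a JSON file) with elements `model`
#'   (model file path), `input` (character vector of PDB files) and/or
#'   `letters` (FASTA-dialect letter file), `outputDir`, and optional
#'   overrides of the defaults: `k`, `minCount`, `minLoopLetters`,
#'   `helixPattern`, `strandPattern`, `ssLetters`, `bfactorCutoff`,
#'   `lpThreshold`, `alpha`, `minResidues`, `maxResolution`,
#'   `rmsdSample`, `seed`.
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::fromJSON(config)
  cfg <- utils::modifyList(.defaultConfig(), config)
  if (is.null(cfg$outputDir)) stop("config error: outputDir is required")
  if (is.null(cfg$model)) stop("config error: model path is required")
  if (!file.exists(cfg$model))
    stop("config error: model file not found: ", cfg$model)
  if (is.null(cfg$input) && is.null(cfg$letters))
    stop("config error: provide `input` (PDB files) or `letters` (FASTA)")
  created <- !dir.exists(cfg$outputDir)
  dir.create(cfg$outputDir, showWarnings = FALSE, recursive = TRUE)
  stage <- "setup"
  manifest <- list(package = "loopwords",
                   version = as.character(utils::packageVersion("loopwords")),
                   config = cfg[setdiff(names(cfg), "outputDir")],
                   counts = list())
  out <- function(f) file.path(cfg$outputDir, f)
  tryCatch({
    stage <- "encode"
    model <- readAlphabetModel(cfg$model)
    chains <- NULL
    if (!is.null(cfg$input)) {
      stage <- "read-structures"
      rs <- readStructures(cfg$input, minResidues = cfg$minResidues,
                           maxResolution = cfg$maxResolution)
      chains <- rs$chains
      .writeTSV(rs$summary, out("chains.tsv"))
      manifest$counts$chains_input <- nrow(rs$summary)
      manifest$counts$chains_accepted <- length(chains)
      stage <- "encode"
      letterStrings <- vapply(chains, function(ch)
        as.character(encodeStructure(ch, model)), "")
      writeLetterStrings(letterStrings, out("letters.fasta"))
    } else {
      letterStrings <- readLetterStrings(cfg$letters)
    }
    manifest$counts$chains_encoded <- length(letterStrings)
    manifest$counts$total_letters <- sum(nchar(letterStrings))

    stage <- "loops"
    loops <- extractLoopsFromStrings(letterStrings,
                                     helixPattern = cfg$helixPattern,
                                     strandPattern = cfg$strandPattern,
                                     minLetters = cfg$minLoopLetters)
    .writeTSV(loops[, c("chain", "start_letter", "end_letter", "n_letters",
                        "n_residues", "letters", "left_flank", "right_flank",
                        "flank_class", "length_class")],
              out("loops.tsv"))
    manifest$counts$loops <- nrow(loops)

    stage <- "words"
    ssl <- strsplit(cfg$ssLetters, "")[[1]]
    fragments <- buildFragments(loops, chains = chains, k = cfg$k,
                                ssLetters = ssl)
    manifest$counts$fragments_before_exclusion <-
      attr(fragments, "nBeforeExclusion")
    manifest$counts$fragments <- nrow(fragments)
    cw <- clusterWords(fragments, minCount = cfg$minCount)
    manifest$counts$words <- nrow(cw$summary)
    manifest$counts$words_retained <- length(cw$retained)
    manifest$counts$singletons <- cw$nSingletons
    fragOut <- fragments
    .writeTSV(fragOut, out("fragments.tsv"))
    cov <- coverageRate(loops, cw$retained)
    manifest$counts$coverage_rate <- cov$rate
    clusterTab <- cw$summary
    if (length(cw$clusters) && length(cw$clusters[[1]]@bfactors)) {
      bf <- lapply(cw$clusters[clusterTab$word], flagHighBfactor,
                   cutoff = cfg$bfactorCutoff)
      clusterTab$mean_bfactor <- vapply(bf, `[[`, 0, "mean")
      clusterTab$bfactor_flag <- vapply(bf, function(x)
        as.character(x$flag), "")
    }
    .writeTSV(clusterTab, out("clusters.tsv"))

    stage <- "word-stats"
    retained <- cw$retained
    stats <- NULL
    if (length(retained)) {
      haveGeom <- length(cw$clusters[[1]]@coords) > 0
      haveSeq <- length(cw$clusters[[1]]@sequences) > 0
      bg <- if (haveSeq) aaCounts(fragments$aa) else NULL
      kldLen <- loopTypePreference(fragments, loops, "length",
                                   alpha = cfg$alpha, words = retained)
      kldFlk <- loopTypePreference(fragments, loops, "flank",
                                   alpha = cfg$alpha, words = retained)
      kld8 <- loopTypePreference(fragments, loops, "both",
                                 alpha = cfg$alpha, words = retained)
      stats <- data.frame(word = retained,
                          N_w = clusterTab$N_w[match(retained,
                                                     clusterTab$word)],
                          stringsAsFactors = FALSE)
      stats$rmsd_w <- if (haveGeom)
        vapply(cw$clusters[retained], intraWordRMSD,
               nSample = cfg$rmsdSample, seed = cfg$seed, 0) else NA_real_
      if (haveSeq) {
        profs <- lapply(cw$clusters[retained], zscoreProfile,
                        backgroundCounts = bg, N = nrow(fragments))
        stats$z_max <- vapply(profs, function(p) p@zMax, 0)
        stats$nb_pos_sig <- vapply(profs, function(p) p@nbPosSig, 0L)
      } else {
        stats$z_max <- NA_real_; stats$nb_pos_sig <- NA_integer_
      }
      addKLD <- function(df, tab, suf) {
        i <- match(df$word, tab$word)
        df[[paste0("kld_", suf)]] <- tab$kld[i]
        df[[paste0("p_", suf)]] <- tab$p_adj[i]
        df[[paste0("pref_", suf)]] <- tab$preferred[i]
        df
      }
      stats <- addKLD(stats, kldLen, "length")
      stats <- addKLD(stats, kldFlk, "flank")
      stats <- addKLD(stats, kld8, "8type")
      .writeTSV(stats, out("word_stats.tsv"))
    }

    stage <- "exceptionality"
    if (nrow(loops)) {
      background <- fitBackground(loops$letters)
      counts <- setNames(clusterTab$N_w, clusterTab$word)
      if (length(retained)) counts <- counts[retained]
      exc <- wordExceptionality(as.list(counts), background,
                                threshold = cfg$lpThreshold)
      .writeTSV(exc, out("exceptionality.tsv"))
      manifest$counts$words_OR <- sum(exc$class == "OR")
      manifest$counts$words_UR <- sum(exc$class == "UR")
      manifest$counts$words_NS <- sum(exc$class == "NS")
    }

    stage <- "manifest"
    jsonlite::write_json(manifest, out("manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(manifest)
  }, error = function(e) {
    if (created) unlink(cfg$outputDir, recursive = TRUE)
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
}
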