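# End-to-end pipeline driver: synthetic data -> profile search -> pairwise
# alignment -> SSN -> genome neighbourhoods -> cohort report, as a plain
# directory-of-files run with a JSON manifest (versions, seeds, checksums).

#' Default demonstration configuration
#'
#' Two protein families plus decoys and a small genome cohort — sized so
#' an end-to-end run completes in seconds while exercising every stage.
#'
#' @param seed master seed; per-stage seeds are derived from it.
#' @return a configuration list accepted by \code{\link{runPipeline}}.
#' @export
demoConfig <- function(seed = 1) {
  list(
    stages = c("syndata", "profsearch", "pairalign", "ssn",
               "neighborhood"),
    seed = seed,
    families = list(
      list(n = 10, identity = 80, length = 220, prefix = "famA",
           taxonomy = "Actinomycetota"),
      list(n = 10, identity = 80, length = 220, prefix = "famB",
           taxonomy = "Bacteroidota")),
    n_decoys = 10,
    genomes = list(n_per_pathway = 4,
                   pathways = c("sulfo-EMP", "sulfo-ED", "sulfo-SFT",
                                "sulfo-SMO", "sulfo-SDO"),
                   n_background = 24),
    profsearch = list(evalue = 1e-3, max_iters = 6, n_calibrate = 100),
    ssn = list(grid = seq(5, 120, by = 5)))
}

#' @noRd
knownStages <- c("syndata", "profsearch", "pairalign", "ssn",
                 "neighborhood")

#' Run the full pipeline into an output directory
#'
#' Executes the configured stages in order (synthetic data, iterative
#' profile search, all-vs-all alignment, SSN threshold sweep + export,
#' genome-neighbourhood cohort report) and writes a manifest recording the
#' package version, the configuration, all seeds, and an MD5 checksum per
#' output file.  Identical configurations produce identical checksums.
#' A stage failure halts the run; outputs of completed stages remain on
#' disk.
#'
#' @param config configuration list (see \code{\link{demoConfig}}) or the
#'   path to a YAML file holding one.
#' @param outDir output directory (created if needed).
#' @param quiet suppress progress messages?
#' @return the manifest, invisibly (list).
#' @export
runPipeline <- function(config = demoConfig(), outDir, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  bad <- setdiff(config$stages, knownStages)
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (missing(outDir)) stop("'outDir' is required", call. = FALSE)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  t0 <- Sys.time()
  seed <- config$seed

  files <- character(0)
  addFile <- function(f) files <<- union(files, f)

  seqs <- NULL
  genomes <- NULL
  if ("syndata" %in% config$stages) {
    say("stage syndata")
    fams <- lapply(seq_along(config$families), function(i) {
      f <- config$families[[i]]
      makeFamily(f$n, f$identity, f$length, seed = seed + i,
                 prefix = f$prefix, taxonomy = f$taxonomy)
    })
    allFam <- do.call(c, fams)
    decoys <- makeDecoys(allFam, config$n_decoys, seed = seed + 100)
    seqs <- c(allFam, decoys)
    fa <- file.path(outDir, "sequences.fasta")
    Biostrings::writeXStringSet(seqs, fa)
    addFile(fa)

    gcfg <- config$genomes
    genomes <- list()
    gi <- 0
    for (pw in gcfg$pathways) {
      for (k in seq_len(gcfg$n_per_pathway)) {
        gi <- gi + 1
        id <- sprintf("g%03d", gi)
        genomes[[id]] <- makeGenome(pw, nBackground = gcfg$n_background,
                                    seed = seed + 200 + gi,
                                    genomeId = id)
      }
    }
    gdir <- file.path(outDir, "genomes")
    dir.create(gdir, showWarnings = FALSE)
    for (id in names(genomes)) {
      gf <- file.path(gdir, paste0(id, ".gff3"))
      writeFeaturesGFF3(genomes[[id]], gf)
      addFile(gf)
    }
  }

  if ("profsearch" %in% config$stages) {
    say("stage profsearch")
    if (is.null(seqs)) stop("profsearch needs syndata outputs",
                            call. = FALSE)
    fam1 <- seqs[S4Vectors::mcols(seqs)$family ==
                   config$families[[1]]$prefix]
    seedMsa <- as.character(fam1[seq_len(min(5L, length(fam1)))])
    ps <- config$profsearch
    res <- iterateProfileSearch(seedMsa, seqs, evalueCutoff = ps$evalue,
                                maxIters = ps$max_iters,
                                nCalibrate = ps$n_calibrate,
                                calibrationSeed = seed + 300)
    pf <- file.path(outDir, "profile_search.json")
    jsonlite::write_json(res[c("ids", "n_iterations", "set_sizes",
                               "status")], pf, auto_unbox = TRUE,
                         pretty = TRUE)
    addFile(pf)
  }

  edges <- NULL
  if ("pairalign" %in% config$stages) {
    say("stage pairalign")
    if (is.null(seqs)) stop("pairalign needs syndata outputs",
                            call. = FALSE)
    edges <- allVsAll(seqs)
    ef <- file.path(outDir, "edges.tsv")
    writeEdgeTable(edges, ef)
    addFile(ef)
  }

  if ("ssn" %in% config$stages) {
    say("stage ssn")
    if (is.null(edges)) stop("ssn needs pairalign outputs", call. = FALSE)
    sweep <- selectThreshold(edges, config$ssn$grid,
                             nodeIds = names(seqs))
    sf <- file.path(outDir, "threshold_sweep.csv")
    utils::write.csv(sweepTable(sweep), sf, row.names = FALSE)
    addFile(sf)
    th <- selectedThreshold(sweep)
    if (is.na(th)) th <- config$ssn$grid[1]
    net <- buildSSN(edges, th, nodeIds = names(seqs))
    meta <- data.frame(id = names(seqs),
                       taxonomy = S4Vectors::mcols(seqs)$taxonomy,
                       stringsAsFactors = FALSE)
    out <- annotateAndExport(net, meta, scheme = "taxonomy",
                             path = file.path(outDir, "ssn"))
    for (f in out) addFile(f)
  }

  if ("neighborhood" %in% config$stages) {
    say("stage neighborhood")
    if (is.null(genomes)) stop("neighborhood needs syndata outputs",
                               call. = FALSE)
    rep <- cohortReport(genomes)
    cf <- file.path(outDir, "cohort_calls.csv")
    utils::write.csv(rep$calls, cf, row.names = FALSE)
    sf2 <- file.path(outDir, "cohort_summary.csv")
    utils::write.csv(rep$summary, sf2, row.names = FALSE)
    jf <- file.path(outDir, "cohort_report.json")
    jsonlite::write_json(rep, jf, pretty = TRUE)
    addFile(cf); addFile(sf2); addFile(jf)
  }

  manifest <- list(
    package = "sqgsuite",
    version = as.character(utils::packageVersion("sqgsuite")),
    config = config,
    started = format(t0, "%Y-%m-%dT%H:%M:%S"),
    wall_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    checksums = as.list(tools::md5sum(sort(files))))
  names(manifest$checksums) <- basename(sort(files))
  mf <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
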