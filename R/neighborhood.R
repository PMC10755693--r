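# Genome-neighbourhood extraction (ORF +/- k around a seed gene) and
# rule-based classification into sulfoglycolytic / sulfolytic pathways,
# with GH31/GH188 SQase presence calls.

#' Load pathway classification rules
#'
#' Reads a YAML rule file (defaulting to the one shipped with the package)
#' describing, per pathway, the required enzyme groups, their accepted
#' domain tags and minimum hit counts.
#'
#' @param path YAML file; default: the packaged rule set.
#' @return a list with components \code{pathways} and \code{sqase_tags}.
#' @export
loadPathwayRules <- function(path = system.file("extdata",
                                                "pathway_rules.yaml",
                                                package = "sqgsuite")) {
  rules <- yaml::read_yaml(path)
  if (is.null(rules$pathways) || !length(rules$pathways))
    stop("rule file has no pathways", call. = FALSE)
  rules
}

#' @noRd
splitTags <- function(x) {
  unlist(strsplit(as.character(x), "[,;] *"))
}

#' Extract the ORF window around a seed gene
#'
#' Returns the seed plus up to \code{k} ORFs on each side, on the same
#' contig, in genomic order (sorted by start coordinate).  The window is
#' positional, not strand-relative, and never crosses a contig boundary;
#' near contig edges fewer ORFs are returned.
#'
#' @param features a \link[GenomicRanges]{GRanges} of gene features with a
#'   \code{locus_id} metadata column (e.g. from \code{\link{makeGenome}} or
#'   \code{\link{readFeaturesGFF3}}).
#' @param seedLocus locus id of the seed gene.
#' @param k half-window size in ORFs (default 10).
#' @return a \linkS4class{GeneNeighborhood}
#' @export
extractNeighborhood <- function(features, seedLocus, k = 10L) {
  stopifnot(is(features, "GRanges"))
  if (!seedLocus %in% features$locus_id)
    stop("seed locus '", seedLocus, "' not found", call. = FALSE)
  seedContig <- as.character(
    GenomicRanges::seqnames(features))[features$locus_id == seedLocus][1]
  onContig <- features[
    as.character(GenomicRanges::seqnames(features)) == seedContig]
  ord <- order(BiocGenerics::start(onContig))
  onContig <- onContig[ord]
  idx <- which(onContig$locus_id == seedLocus)
  lo <- max(1L, idx - as.integer(k))
  hi <- min(length(onContig), idx + as.integer(k))
  new("GeneNeighborhood", features = onContig[lo:hi],
      seed = seedLocus, k = as.integer(k))
}

#' @noRd
evaluateRuleSet <- function(tags, loci, ruleset) {
  groups <- ruleset$groups
  matched <- list()
  nSat <- 0L
  for (gname in names(groups)) {
    g <- groups[[gname]]
    minHits <- if (is.null(g$min_hits)) 1L else g$min_hits
    hit <- vapply(tags, function(tg) any(tg %in% g$tags), logical(1))
    if (sum(hit) >= minHits) {
      nSat <- nSat + 1L
      matched[[gname]] <- loci[hit]
    }
  }
  forb <- ruleset$forbidden
  forbidden <- !is.null(forb) &&
    any(vapply(tags, function(tg) any(tg %in% forb), logical(1)))
  minGroups <- if (is.null(ruleset$min_groups)) length(groups)
  else ruleset$min_groups
  list(satisfied = !forbidden && nSat >= minGroups,
       n_matched = nSat, matched = matched)
}

#' Classify a gene neighbourhood into a pathway
#'
#' Evaluates every pathway rule set against the domain tags in the window.
#' If exactly one pathway is satisfied it is returned; if several are, the
#' one with the most matched groups wins, and an exact tie yields an
#' \code{"ambiguous"} call listing all candidates.  Degenerate inputs
#' (empty windows, no matching tags) yield \code{"unclassified"}.  GH31 and
#' GH188 SQase presence flags are set from the feature tags.
#'
#' @param nbhd a \linkS4class{GeneNeighborhood} (or a GRanges window).
#' @param rules a rule list from \code{\link{loadPathwayRules}}.
#' @return a \linkS4class{PathwayCall}
#' @export
classifyNeighborhood <- function(nbhd, rules = loadPathwayRules()) {
  feats <- if (is(nbhd, "GeneNeighborhood")) nbhd@features else nbhd
  tags <- if (length(feats)) lapply(feats$domain_tags, splitTags)
  else list()
  loci <- if (length(feats)) feats$locus_id else character(0)
  allTags <- unlist(tags)
  gh31 <- any(allTags %in% rules$sqase_tags$gh31)
  gh188 <- any(allTags %in% rules$sqase_tags$gh188)

  evals <- lapply(rules$pathways, function(rs)
    evaluateRuleSet(tags, loci, rs))
  sat <- names(evals)[vapply(evals, `[[`, logical(1), "satisfied")]

  if (!length(sat))
    return(new("PathwayCall", pathway = "unclassified",
               status = "unclassified", matchedLoci = list(),
               candidates = character(0), gh31Present = gh31,
               gh188Present = gh188))
  if (length(sat) > 1L) {
    nm <- vapply(evals[sat], `[[`, integer(1), "n_matched")
    best <- sat[nm == max(nm)]
    if (length(best) > 1L)
      return(new("PathwayCall", pathway = "ambiguous",
                 status = "ambiguous", matchedLoci = list(),
                 candidates = best, gh31Present = gh31,
                 gh188Present = gh188))
    sat <- best[1L]
  }
  new("PathwayCall", pathway = sat, status = "ok",
      matchedLoci = evals[[sat]]$matched, candidates = sat,
      gh31Present = gh31, gh188Present = gh188)
}

#' Classify a cohort of genomes
#'
#' Extracts the +/-k window around each genome's seed locus, classifies
#' it, and tabulates pathway by SQase-family presence.  Per-genome
#' failures (e.g. a missing seed locus) are reported in the table, not
#' raised.
#'
#' @param genomes list of \link[GenomicRanges]{GRanges} feature tables.
#' @param seeds character vector of per-genome seed locus ids (recycled
#'   from each genome's metadata \code{seed_locus} when missing).
#' @param rules rule list from \code{\link{loadPathwayRules}}.
#' @param k half-window size.
#' @return list with \code{calls} (data.frame: genome, pathway, status,
#'   gh31_present, gh188_present) and \code{summary} (counts per pathway
#'   by SQase-family combination).
#' @export
cohortReport <- function(genomes, seeds = NULL,
                         rules = loadPathwayRules(), k = 10L) {
  if (!length(genomes))
    return(list(calls = data.frame(genome = character(),
                                   pathway = character(),
                                   status = character(),
                                   gh31_present = logical(),
                                   gh188_present = logical()),
                summary = data.frame(pathway = character(),
                                     sqase = character(),
                                     n = integer())))
  nm <- names(genomes)
  if (is.null(nm)) nm <- paste0("genome_", seq_along(genomes))
  rows <- lapply(seq_along(genomes), function(i) {
    g <- genomes[[i]]
    seed <- if (!is.null(seeds)) seeds[[i]]
    else S4Vectors::metadata(g)$seed_locus
    call <- tryCatch({
      nb <- extractNeighborhood(g, seed, k = k)
      classifyNeighborhood(nb, rules)
    }, error = function(e)
      new("PathwayCall", pathway = "error",
          status = conditionMessage(e), matchedLoci = list(),
          candidates = character(0), gh31Present = NA,
          gh188Present = NA))
    data.frame(genome = nm[i], pathway = call@pathway,
               status = call@status, gh31_present = call@gh31Present,
               gh188_present = call@gh188Present,
               stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, rows)
  sqase <- ifelse(is.na(calls$gh31_present), "unknown",
           ifelse(calls$gh31_present & calls$gh188_present, "gh31+gh188",
           ifelse(calls$gh188_present, "gh188-only",
           ifelse(calls$gh31_present, "gh31-only", "none"))))
  summary <- as.data.frame(table(pathway = calls$pathway, sqase = sqase),
                           stringsAsFactors = FALSE)
  names(summary)[3] <- "n"
  summary <- summary[summary$n > 0, , drop = FALSE]
  rownames(summary) <- NULL
  list(calls = calls, summary = summary)
}

#' Write gene features as GFF3
#'
#' Domain tags are stored in the attribute \code{domain} (comma-separated).
#'
#' @param features a \link[GenomicRanges]{GRanges} with \code{locus_id},
#'   \code{domain_tags}, \code{product} metadata columns.
#' @param path output GFF3 path.
#' @return \code{path}, invisibly.
#' @export
writeFeaturesGFF3 <- function(features, path) {
  gr <- features
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = "sqgsuite", type = "gene",
    ID = features$locus_id, domain = features$domain_tags,
    product = features$product, genome_id = features$genome_id)
  rtracklayer::export.gff3(gr, path)
  invisible(path)
}

#' Read gene features from GFF3
#'
#' Inverse of \code{\link{writeFeaturesGFF3}}: re-creates the metadata
#' columns \code{locus_id}, \code{domain_tags}, \code{product},
#' \code{genome_id} from the GFF3 attributes.
#'
#' @param path GFF3 file.
#' @return a \link[GenomicRanges]{GRanges}
#' @export
readFeaturesGFF3 <- function(path) {
  gr <- rtracklayer::import.gff3(path)
  dom <- gr$domain
  if (is(dom, "List") || is.list(dom))
    dom <- vapply(dom, paste, character(1), collapse = ",")
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    locus_id = gr$ID, domain_tags = dom,
    product = gr$product, genome_id = gr$genome_id)
  gr
}
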