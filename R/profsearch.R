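# Iterative profile search: PSSM construction with Henikoff weighting,
# local profile-vs-sequence DP (compiled), Gumbel-calibrated E-values on
# shuffled decoys, and iteration to a stable retrieved set.
#
# This is a deliberate simplification of a full profile HMM: the iterative
# rebuild-to-stability procedure is preserved while the model is a
# position-specific scoring matrix searched with affine-gap local DP.

#' Build a position-specific scoring profile from an alignment
#'
#' Columns with more than 50\% gaps are masked.  Sequences are weighted by
#' the Henikoff position-based scheme (each column distributes one unit of
#' weight equally over its distinct residues, then over the sequences
#' carrying each residue).  Per-column scores are
#' \eqn{\log_2 \frac{(c_a + \alpha p_a)/(N + \alpha)}{p_a}} where
#' \eqn{c_a} is the weighted residue count, \eqn{N} the weighted non-gap
#' total, \eqn{p_a} the background frequency (Robinson-Robinson) and
#' \eqn{\alpha} the pseudocount weight.
#'
#' @param msa aligned sequences: a named character vector or
#'   \link[Biostrings]{AAStringSet}, all of equal aligned length, gaps as
#'   \code{"-"}.
#' @param pseudocount effective pseudo-observations \eqn{\alpha}
#'   (default 0.5).
#' @return a \linkS4class{SequenceProfile}
#' @examples
#' buildProfile(c(a = "ACD", b = "ACD", c = "A-D"))
#' @export
buildProfile <- function(msa, pseudocount = 0.5) {
  if (is(msa, "XStringSet")) {
    ids <- names(msa)
    msa <- as.character(msa)
    names(msa) <- ids
  }
  if (length(msa) < 2L)
    stop("need at least two aligned sequences", call. = FALSE)
  w <- unique(nchar(msa))
  if (length(w) != 1L)
    stop("ragged MSA: aligned lengths differ", call. = FALSE)
  mat <- do.call(rbind, strsplit(toupper(msa), ""))
  mat[mat == "."] <- "-"
  if (any(colSums(mat != "-") == 0L))
    stop("all-gap column in MSA", call. = FALSE)

  keep <- which(colMeans(mat == "-") <= 0.5)
  if (!length(keep))
    stop("no columns left after gap masking", call. = FALSE)

  # Henikoff position-based sequence weights
  nseq <- nrow(mat)
  wts <- numeric(nseq)
  for (j in keep) {
    col <- mat[, j]
    res <- col[col != "-"]
    if (!length(res)) next
    tab <- table(res)
    r <- length(tab)
    contrib <- 1 / (r * as.numeric(tab[match(col, names(tab))]))
    contrib[is.na(contrib)] <- 0
    wts <- wts + contrib
  }
  if (sum(wts) == 0) wts <- rep(1, nseq)
  wts <- wts / sum(wts) * nseq      # mean weight 1

  bg <- AA_BACKGROUND
  scores <- matrix(0, nrow = length(keep), ncol = 20L,
                   dimnames = list(NULL, AA_ALPHABET20))
  for (k in seq_along(keep)) {
    col <- mat[, keep[k]]
    ok <- col %in% AA_ALPHABET20
    cnt <- vapply(AA_ALPHABET20, function(a)
      sum(wts[ok & col == a]), numeric(1))
    n <- sum(cnt)
    f <- (cnt + pseudocount * bg) / (n + pseudocount)
    scores[k, ] <- log2(f / bg)
  }
  new("SequenceProfile", scores = scores, background = bg,
      pseudocount = pseudocount,
      msaIds = if (is.null(names(msa))) character(0) else names(msa),
      keptColumns = as.integer(keep))
}

#' @noRd
encodeSeq <- function(s) {
  ch <- strsplit(toupper(s), "")[[1]]
  code <- match(ch, AA_ALPHABET20) - 1L
  code[is.na(code)] <- -1L          # X and friends score 0
  as.integer(code)
}

#' Score a profile against one sequence
#'
#' Best local affine-gap DP score; optionally the aligned span and the
#' per-column target positions (used for realignment during iteration).
#'
#' @param profile a \linkS4class{SequenceProfile}.
#' @param sequence protein sequence string.
#' @param gapOpen,gapExt affine gap penalties in profile score (bit) units.
#' @param traceback return the per-column alignment?
#' @return list with \code{score}, \code{span_start}, \code{span_end},
#'   \code{aligned} (integer per profile column, NA = not matched).
#' @export
scoreProfile <- function(profile, sequence, gapOpen = 10, gapExt = 1,
                         traceback = FALSE) {
  stopifnot(is(profile, "SequenceProfile"))
  if (nrow(profile@scores) == 0L) stop("empty profile", call. = FALSE)
  .profile_local_dp(profile@scores, encodeSeq(sequence),
                    gapOpen, gapExt, traceback)
}

#' Search a sequence database with a profile
#'
#' Scores every target with local profile DP and converts scores to
#' E-values via a Gumbel (extreme-value) calibration: scores of
#' \code{nCalibrate} composition-preserving shuffles of the database
#' sequences are fitted by the method of moments
#' (\eqn{\lambda = \pi/(\sigma\sqrt 6)},
#' \eqn{\mu = \bar s - \gamma/\lambda}) and
#' \eqn{E(s) = N_{db} \exp(-\lambda (s - \mu))}.
#'
#' @param profile a \linkS4class{SequenceProfile}.
#' @param database a named \link[Biostrings]{AAStringSet}.
#' @param evalueCutoff report hits with \code{evalue <= evalueCutoff}.
#' @param gapOpen,gapExt DP gap penalties.
#' @param nCalibrate number of shuffled decoys for the Gumbel fit
#'   (>= 50 recommended; default 200).
#' @param calibrationSeed RNG seed for the decoy shuffles.
#' @return data.frame of hits sorted by E-value (ties broken by id):
#'   \code{target_id}, \code{score}, \code{evalue}, \code{span_start},
#'   \code{span_end}.
#' @export
profileSearch <- function(profile, database, evalueCutoff = 1e-3,
                          gapOpen = 10, gapExt = 1, nCalibrate = 200,
                          calibrationSeed = 101) {
  stopifnot(is(profile, "SequenceProfile"))
  if (!length(database)) stop("empty database", call. = FALSE)
  ids <- names(database)
  if (is.null(ids) || anyDuplicated(ids))
    stop("database ids must be present and unique", call. = FALSE)

  gum <- calibrateGumbel(profile, database, nCalibrate, gapOpen, gapExt,
                         calibrationSeed)
  res <- lapply(ids, function(id) {
    r <- scoreProfile(profile, as.character(database[[id]]),
                      gapOpen, gapExt, traceback = TRUE)
    data.frame(target_id = id, score = r$score,
               evalue = length(database) *
                 exp(-gum$lambda * (r$score - gum$mu)),
               span_start = r$span_start, span_end = r$span_end,
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, res)
  hits <- hits[hits$evalue <= evalueCutoff, , drop = FALSE]
  hits <- hits[order(hits$evalue, hits$target_id), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' @noRd
calibrateGumbel <- function(profile, database, nCalibrate, gapOpen, gapExt,
                            seed) {
  decoys <- makeDecoys(database, nCalibrate, seed = seed,
                       prefix = "calib")
  s <- vapply(seq_along(decoys), function(i)
    scoreProfile(profile, as.character(decoys[[i]]), gapOpen, gapExt,
                 traceback = FALSE)$score, numeric(1))
  sdv <- sd(s)
  if (!is.finite(sdv) || sdv == 0) sdv <- 1e-6
  lambda <- pi / (sdv * sqrt(6))
  mu <- mean(s) - 0.57721566490153 / lambda
  list(lambda = lambda, mu = mu, scores = s)
}

#' Iterate profile search to a stable sequence set
#'
#' Each round realigns the current hits to the profile via the DP
#' traceback, rebuilds the profile from that alignment, and re-searches
#' the database.  Iteration stops when the retrieved id set equals the
#' previous round's set (convergence: exact set equality), or at
#' \code{maxIters}.  If a set recurs non-consecutively the run is flagged
#' as oscillating.
#'
#' @param seedMsa aligned seed sequences (see \code{\link{buildProfile}}).
#' @param database a named \link[Biostrings]{AAStringSet}.
#' @param evalueCutoff,gapOpen,gapExt,nCalibrate,calibrationSeed passed to
#'   \code{\link{profileSearch}}.
#' @param maxIters maximum number of search rounds (>= 1).
#' @param pseudocount passed to \code{\link{buildProfile}}.
#' @return list with \code{ids} (final retrieved set, sorted),
#'   \code{n_iterations}, \code{set_sizes} (per-round), \code{status}
#'   (\code{"converged"}, \code{"not converged"} or \code{"oscillating"}),
#'   and \code{profile} (the final \linkS4class{SequenceProfile}).
#' @export
iterateProfileSearch <- function(seedMsa, database, evalueCutoff = 1e-3,
                                 maxIters = 10, gapOpen = 10, gapExt = 1,
                                 nCalibrate = 200, calibrationSeed = 101,
                                 pseudocount = 0.5) {
  if (maxIters < 1) stop("'maxIters' must be >= 1", call. = FALSE)
  profile <- buildProfile(seedMsa, pseudocount = pseudocount)
  # the seed set counts as round zero: retrieving exactly the seed
  # sequences is already a fixed point
  seedIds <- if (is(seedMsa, "XStringSet")) names(seedMsa)
  else names(seedMsa)
  history <- if (is.null(seedIds)) list() else list(sort(seedIds))
  sizes <- integer(0)
  status <- "not converged"
  ids <- character(0)

  for (it in seq_len(maxIters)) {
    hits <- profileSearch(profile, database, evalueCutoff, gapOpen,
                          gapExt, nCalibrate, calibrationSeed)
    ids <- sort(hits$target_id)
    sizes <- c(sizes, length(ids))
    if (length(history) && identical(ids, history[[length(history)]])) {
      status <- "converged"
      history <- c(history, list(ids))
      break
    }
    if (length(history) > 1L &&
        any(vapply(history[-length(history)], identical, logical(1),
                   y = ids)))
      status <- "oscillating"
    history <- c(history, list(ids))
    if (!length(ids)) { status <- "converged"; break }

    # realign hits to the profile and rebuild
    aligned <- vapply(ids, function(id) {
      r <- scoreProfile(profile, as.character(database[[id]]),
                        gapOpen, gapExt, traceback = TRUE)
      ch <- strsplit(as.character(database[[id]]), "")[[1]]
      out <- rep("-", nrow(profile@scores))
      hit <- !is.na(r$aligned)
      out[hit] <- ch[r$aligned[hit]]
      paste(out, collapse = "")
    }, character(1))
    if (length(aligned) >= 2L) {
      profile <- buildProfile(aligned, pseudocount = pseudocount)
    }
    # a single retained sequence cannot rebuild a profile; keep current
  }
  list(ids = ids, n_iterations = length(sizes), set_sizes = sizes,
       status = status, profile = profile)
}
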