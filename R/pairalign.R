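# Exact pairwise alignment and the alignment-score (AS) metric used for
# SSN edges.  Dynamic programming is delegated to
# Biostrings::pairwiseAlignment (BLOSUM62, affine gaps); the Karlin-Altschul
# bit-score / E-value / AS arithmetic on top is computed here.

# Standard gapped BLOSUM62-11-1 Karlin-Altschul constants.
#' @noRd
KA_LAMBDA <- 0.267
#' @noRd
KA_K <- 0.041

#' Align two protein sequences and score the pair
#'
#' Computes the optimal affine-gap alignment (BLOSUM62, gap opening 11,
#' gap extension 1 by default; the ambiguity code X scores 0) and derives:
#' \itemize{
#'   \item \code{bit_score} \eqn{= (\lambda \cdot raw - \ln K)/\ln 2} with
#'     the standard gapped BLOSUM62-11-1 constants
#'     \eqn{\lambda = 0.267}, \eqn{K = 0.041};
#'   \item \code{evalue_like} \eqn{= m n \, 2^{-bit}} using the pairwise
#'     search space \eqn{m \times n};
#'   \item the alignment score \code{AS} \eqn{= -\log_{10}} of
#'     \code{evalue_like}, the SSN edge-thresholding metric;
#'   \item \code{pct_identity}: identities over aligned columns in which
#'     neither sequence has a gap, times 100.
#' }
#'
#' @param seqA,seqB protein sequence strings (non-empty; standard residues
#'   plus X).
#' @param mode \code{"local"} (Smith-Waterman) or \code{"global"}
#'   (Needleman-Wunsch).
#' @param idA,idB sequence identifiers carried into the result.
#' @param gapOpening,gapExtension affine gap penalties (positive costs); a
#'   gap of length L costs \code{gapOpening + L * gapExtension}.
#' @param lambda,K Karlin-Altschul constants.
#' @return a one-row data.frame with columns \code{id_a}, \code{id_b},
#'   \code{raw_score}, \code{bit_score}, \code{evalue_like}, \code{AS},
#'   \code{pct_identity}, \code{aligned_length}.
#' @examples
#' alignPair("HEAGAWGHEE", "PAWHEAE", mode = "local")
#' @export
alignPair <- function(seqA, seqB, mode = c("local", "global"),
                      idA = "a", idB = "b",
                      gapOpening = 11, gapExtension = 1,
                      lambda = KA_LAMBDA, K = KA_K) {
  mode <- match.arg(mode)
  checkProteinString(seqA, "seqA")
  checkProteinString(seqB, "seqB")
  # canonical orientation: optimal alignments can be tied, and the DP
  # tie-break depends on argument order; aligning in a fixed orientation
  # makes every reported field symmetric under swap of (a, b)
  if (seqB < seqA) {
    tmp <- seqA; seqA <- seqB; seqB <- tmp
  }
  aln <- Biostrings::pairwiseAlignment(
    seqA, seqB, type = mode, substitutionMatrix = blosum62x(),
    gapOpening = gapOpening, gapExtension = gapExtension)
  raw <- Biostrings::score(aln)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  both <- p != "-" & s != "-"
  pct <- if (any(both)) 100 * sum(p[both] == s[both]) / sum(both) else 0
  m <- nchar(seqA)
  n <- nchar(seqB)
  bit <- (lambda * raw - log(K)) / log(2)
  ev <- m * n * 2^(-bit)
  data.frame(id_a = idA, id_b = idB, raw_score = raw, bit_score = bit,
             evalue_like = ev, AS = -log10(ev), pct_identity = pct,
             aligned_length = length(p), stringsAsFactors = FALSE)
}

#' All-versus-all pairwise alignment
#'
#' One \code{\link{alignPair}} result per unordered pair; the output is
#' independent of input order up to row permutation.
#'
#' @param records a named \link[Biostrings]{AAStringSet} (>= 2 sequences,
#'   unique ids).
#' @param mode,gapOpening,gapExtension,lambda,K passed to
#'   \code{\link{alignPair}}.
#' @return a data.frame edge list, one row per unordered pair, ordered by
#'   (id_a, id_b).
#' @export
allVsAll <- function(records, mode = "local", gapOpening = 11,
                     gapExtension = 1, lambda = KA_LAMBDA, K = KA_K) {
  if (length(records) < 2L)
    stop("need at least two sequences", call. = FALSE)
  ids <- names(records)
  if (is.null(ids) || anyDuplicated(ids))
    stop("sequence ids must be present and unique", call. = FALSE)
  pairs <- utils::combn(sort(ids), 2L)
  res <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1L, k]
    b <- pairs[2L, k]
    alignPair(as.character(records[[a]]), as.character(records[[b]]),
              mode = mode, idA = a, idB = b, gapOpening = gapOpening,
              gapExtension = gapExtension, lambda = lambda, K = K)
  })
  do.call(rbind, res)
}

#' Write an SSN edge list as TSV
#'
#' @param edges a data.frame from \code{\link{allVsAll}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeEdgeTable <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an SSN edge list written by \code{writeEdgeTable}
#'
#' @param path TSV file.
#' @return data.frame
#' @export
readEdgeTable <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
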