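# Internal helpers shared across modules.

#' @noRd
AA_ALPHABET20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Robinson-Robinson amino-acid background frequencies (the standard
# PSI-BLAST background), indexed as AA_ALPHABET20.
#' @noRd
AA_BACKGROUND <- setNames(
  c(0.07805, 0.05129, 0.04487, 0.05364, 0.01925, 0.04264, 0.06295,
    0.07377, 0.02199, 0.05142, 0.09019, 0.05744, 0.02243, 0.03856,
    0.05203, 0.07120, 0.05841, 0.01330, 0.03216, 0.06441),
  AA_ALPHABET20)

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
#' @noRd
withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' @noRd
stopifnotScalarNumber <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("'", name, "' must be a single finite number", call. = FALSE)
  if (positive && x <= 0)
    stop("'", name, "' must be > 0", call. = FALSE)
  invisible(x)
}

# BLOSUM62 with ambiguity code X scored 0 against everything.
#' @noRd
blosum62x <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <- e$BLOSUM62
      m["X", ] <- 0L
      m[, "X"] <- 0L
      cache <<- m
    }
    cache
  }
})

#' @noRd
checkProteinString <- function(x, name) {
  if (!is.character(x) || length(x) != 1L || nchar(x) == 0L)
    stop("'", name, "' must be a non-empty protein sequence string",
         call. = FALSE)
  bad <- setdiff(strsplit(x, "")[[1]], c(AA_ALPHABET20, "X"))
  if (length(bad))
    stop("non-protein characters in '", name, "': ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  invisible(x)
}
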