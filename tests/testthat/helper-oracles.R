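# Independent oracles used to validate the implementations.  Each is a
# direct transcription of a definition (exhaustive enumeration, closed
# form, or an alternative published algorithm), kept deliberately separate
# from the code paths under test.

# BLOSUM62 with X scored 0, as used by alignPair
oracleMatrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62
  m["X", ] <- 0L
  m[, "X"] <- 0L
  m
}

# Exhaustive enumeration of every global alignment of two residue vectors
# under affine gaps (a gap of length L costs open + L * ext).  Pure
# recursion over alignment paths; exponential, so only for tiny inputs.
bfGlobalScore <- function(a, b, mat, open = 11, ext = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  rec <- function(i, j, state) {
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n && j <= m)
      best <- max(best, mat[A[i], B[j]] + rec(i + 1L, j + 1L, 0L))
    if (i <= n)
      best <- max(best, -(if (state == 1L) ext else open + ext) +
                    rec(i + 1L, j, 1L))
    if (j <= m)
      best <- max(best, -(if (state == 2L) ext else open + ext) +
                    rec(i, j + 1L, 2L))
    best
  }
  rec(1L, 1L, 0L)
}

# Affine-gap DP written directly from the three-state recurrences (Gotoh),
# in R.  Validated against bfGlobalScore at tiny sizes; serves as the
# oracle for the compiled/Biostrings implementations up to length ~12.
dpScore <- function(a, b, mat, open = 11, ext = 1,
                    type = c("global", "local")) {
  type <- match.arg(type)
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in B
  Y <- matrix(NEG, n + 1, m + 1)  # gap in A
  M[1, 1] <- 0
  if (type == "global") {
    for (i in 2:(n + 1)) X[i, 1] <- -(open + ext * (i - 1))
    for (j in 2:(m + 1)) Y[1, j] <- -(open + ext * (j - 1))
  } else {
    M[, 1] <- 0
    M[1, ] <- 0
  }
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- mat[A[i - 1], B[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1],
                     Y[i - 1, j - 1]) + s
      if (type == "local") M[i, j] <- max(M[i, j], 0)
      X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext)
      Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext)
      if (type == "local") best <- max(best, M[i, j])
    }
  }
  if (type == "local") best
  else max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Unnormalised betweenness by explicit enumeration of all simple paths
# between every vertex pair (shortest ones only), from the definition.
bfBetweenness <- function(edgeList, vertices) {
  adj <- lapply(vertices, function(v)
    c(edgeList$to[edgeList$from == v], edgeList$from[edgeList$to == v]))
  names(adj) <- vertices
  btw <- setNames(numeric(length(vertices)), vertices)
  allPaths <- function(s, t) {
    paths <- list()
    walk <- function(path) {
      v <- path[length(path)]
      if (v == t) {
        paths[[length(paths) + 1L]] <<- path
        return()
      }
      for (w in adj[[v]])
        if (!w %in% path) walk(c(path, w))
    }
    walk(s)
    paths
  }
  nv <- length(vertices)
  for (si in seq_len(nv - 1)) {
    for (ti in (si + 1):nv) {
      s <- vertices[si]
      t <- vertices[ti]
      paths <- allPaths(s, t)
      if (!length(paths)) next
      lens <- vapply(paths, length, integer(1))
      sp <- paths[lens == min(lens)]
      for (p in sp) {
        inner <- setdiff(p, c(s, t))
        if (length(inner))
          btw[inner] <- btw[inner] + 1 / length(sp)
      }
    }
  }
  btw
}

# Horn's quaternion method for optimal rigid superposition RMSD: the
# eigen-solution of the 4x4 key matrix (no SVD, no Kabsch).
quatRmsd <- function(X, Y) {
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  S <- t(Yc) %*% Xc
  Sxx <- S[1, 1]; Sxy <- S[1, 2]; Sxz <- S[1, 3]
  Syx <- S[2, 1]; Syy <- S[2, 2]; Syz <- S[2, 3]
  Szx <- S[3, 1]; Szy <- S[3, 2]; Szz <- S[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,      -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,      -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE)$values)
  n <- nrow(X)
  sqrt(max(0, sum(Xc^2) + sum(Yc^2) - 2 * lam) / n)
}

# Monte-Carlo SASA with random (seeded) direction sampling — same physical
# definition as Shrake-Rupley but a different point set and code path.
mcSasa <- function(s, probe = 1.4, nPerAtom = 20000, seed = 42) {
  radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20)
  a <- atomData(s)
  a <- a[!a$het, , drop = FALSE]
  r <- radii[a$elesy] + probe
  xyz <- as.matrix(a[, c("x", "y", "z")])
  n <- nrow(xyz)
  set.seed(seed)
  total <- 0
  for (i in seq_len(n)) {
    u <- matrix(stats::rnorm(3 * nPerAtom), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    p <- sweep(u * r[i], 2, xyz[i, ], "+")
    free <- rep(TRUE, nPerAtom)
    for (j in seq_len(n)) {
      if (j == i) next
      dj <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      free <- free & dj > r[j]^2
    }
    total <- total + 4 * pi * r[i]^2 * mean(free)
  }
  total
}

# Brute-force single-label feasibility: test each of the six carbon
# hypotheses against every observation directly.
bfLabelFeasible <- function(fragments, observations) {
  labels <- vapply(fragments, function(f) f@label, character(1))
  feasible <- character(0)
  for (c in paste0("C", 1:6)) {
    ok <- TRUE
    for (i in seq_len(nrow(observations))) {
      key <- observations$fragment[i]
      frag <- if (key %in% names(fragments)) fragments[[key]]
      else fragments[[which(labels == key)[1]]]
      loss <- observations$loss_carbons[i]
      loss <- if (is.na(loss)) character(0) else strsplit(loss, ",")[[1]]
      predicted <- as.integer(c %in% frag@coverage && !(c %in% loss))
      if (predicted != observations$delta_mz[i]) {
        ok <- FALSE
        break
      }
    }
    if (ok) feasible <- c(feasible, c)
  }
  feasible
}

# Shared fixture: two related families plus decoys, with an AS gap between
# intra- and inter-family edges (founders at ~40% identity from a common
# ancestor, members at ~85% within-family identity).
twoFamilyFixture <- function(nPer = 8, len = 200) {
  anc <- as.character(makeFamily(1, 100, len, seed = 11)[[1]])
  fndA <- mutateSequence(anc, 70, seed = 12)
  fndB <- mutateSequence(anc, 55, seed = 13)
  famA <- makeFamily(nPer, 85, len, seed = 14, prefix = "famA",
                     ancestor = fndA)
  famB <- makeFamily(nPer, 85, len, seed = 15, prefix = "famB",
                     ancestor = fndB)
  c(famA, famB)
}
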