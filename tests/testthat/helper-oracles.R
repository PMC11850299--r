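# Independent oracles used by the tests. These deliberately re-derive
# results with different algorithms (quadratic DP, from-scratch averaging,
# raw byte scanning) so they share no code with the implementation paths
# they check.

# Affine-gap Needleman-Wunsch (Gotoh) with match 1 / mismatch 0 /
# gap open 10 / gap extend 1, with traceback. Returns identity over
# alignment columns and per-sequence coverage, like alignment_identity().
nw_oracle <- function(a, b, gap_open = 10, gap_ext = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # match/mismatch state
  X <- matrix(NEG, n + 1, m + 1)   # gap in b (A aligned to -)
  Y <- matrix(NEG, n + 1, m + 1)   # gap in a
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -gap_open - (i - 2) * gap_ext
  for (j in 2:(m + 1)) Y[1, j] <- -gap_open - (j - 2) * gap_ext
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- if (A[i - 1] == B[j - 1]) 1 else 0
    M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
    X[i, j] <- max(M[i - 1, j] - gap_open, X[i - 1, j] - gap_ext)
    Y[i, j] <- max(M[i, j - 1] - gap_open, Y[i, j - 1] - gap_ext)
  }
  # traceback
  i <- n + 1; j <- m + 1
  state <- which.max(c(M[i, j], X[i, j], Y[i, j]))
  cols <- 0; matches <- 0; both <- 0
  while (i > 1 || j > 1) {
    if (state == 1 && i > 1 && j > 1) {
      s <- if (A[i - 1] == B[j - 1]) 1 else 0
      matches <- matches + s; both <- both + 1; cols <- cols + 1
      prev <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      state <- which.max(prev)
      i <- i - 1; j <- j - 1
    } else if (state == 2 || j == 1) {
      cols <- cols + 1
      state <- if (i > 2 && X[i, j] == X[i - 1, j] - gap_ext) 2 else 1
      i <- i - 1
    } else {
      cols <- cols + 1
      state <- if (j > 2 && Y[i, j] == Y[i, j - 1] - gap_ext) 3 else 1
      j <- j - 1
    }
  }
  list(identity = matches / cols, coverage_a = both / n, coverage_b = both / m)
}

# From-scratch UPGMA cophenetic oracle: clusters are merged by the average
# of ORIGINAL distances, recomputed in full at every step.
brute_upgma_cophenetic <- function(D) {
  n <- nrow(D)
  M <- matrix(0, n, n, dimnames = dimnames(D))
  clusters <- as.list(seq_len(n))
  while (length(clusters) > 1) {
    k <- length(clusters)
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_len(k - 1)) for (j in seq.int(i + 1, k)) {
      d <- mean(D[clusters[[i]], clusters[[j]]])
      if (d < bestd - 1e-15) { bestd <- d; best <- c(i, j) }
    }
    a <- clusters[[best[1]]]; b <- clusters[[best[2]]]
    M[a, b] <- bestd
    M[b, a] <- bestd
    clusters[[best[1]]] <- c(a, b)
    clusters[[best[2]]] <- NULL
  }
  M
}

# Pull the text strings out of an (uncompressed) PDF content stream by raw
# tokenizing; independent of the writer.
extract_pdf_labels <- function(path) {
  txt <- rawToChar(readBin(path, "raw", file.size(path)))
  m <- gregexpr("\\(((?:\\\\.|[^\\\\)])*)\\) Tj", txt)[[1]]
  if (m[1] == -1) return(character(0))
  strs <- regmatches(txt, gregexpr("\\(((?:\\\\.|[^\\\\)])*)\\) Tj", txt))[[1]]
  strs <- sub("^\\(", "", sub("\\) Tj$", "", strs))
  gsub("\\\\([()\\\\])", "\\1", strs)
}

# exhaustive pairwise overlap count among label boxes (same tier only;
# tiers sit at different heights by construction)
count_label_overlaps <- function(labels) {
  lb <- labels[labels$placed, , drop = FALSE]
  cnt <- 0L
  if (nrow(lb) > 1) for (i in seq_len(nrow(lb) - 1)) for (j in seq.int(i + 1, nrow(lb))) {
    if (lb$tier[i] == lb$tier[j] &&
        lb$x1[i] < lb$x2[j] && lb$x2[i] > lb$x1[j]) cnt <- cnt + 1L
  }
  cnt
}

# overlaps across all rows of a built layout
layout_label_overlaps <- function(layout) {
  sum(vapply(layout$rows, function(r) {
    if (is.null(r$labels) || !nrow(r$labels)) return(0L)
    count_label_overlaps(r$labels)
  }, integer(1)))
}

# brute-force windowed GC statistics (centred, edge-shrunk windows)
gc_window_oracle <- function(seq, window, stat = c("content", "skew")) {
  stat <- match.arg(stat)
  ch <- strsplit(toupper(seq), "")[[1]]
  n <- length(ch)
  half <- (window - 1) %/% 2
  vapply(seq_len(n), function(i) {
    w <- ch[max(1, i - half):min(n, i + half)]
    g <- sum(w == "G"); c_ <- sum(w == "C")
    if (stat == "content") {
      valid <- sum(w != "N")
      if (valid == 0) 0 else (g + c_) / valid
    } else {
      if (g + c_ == 0) 0 else (g - c_) / (g + c_)
    }
  }, numeric(1))
}

tmpd <- function() {
  d <- tempfile("lvtest_")
  dir.create(d)
  d
}
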