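# Independent brute-force oracles used to cross-check the package's
# implementations. These deliberately use different mechanisms (character
# vectors and explicit loops) from the implementation code paths.

# --- reverse complement ------------------------------------------------

oracle_revcomp <- function(seq) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", seq), "")[[1]]), collapse = "")
}

# --- degenerate protein motif matcher ---------------------------------

# spec$elements as in motif_spec; checks every start position and every
# spacer-length combination character by character
oracle_find_motif <- function(seq, spec) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  els <- spec$elements
  # enumerate spacer-length combinations
  sp_lens <- lapply(els, function(el)
    if (is.null(el$allowed)) seq.int(el$min, el$max) else 0L)
  grid <- do.call(expand.grid, sp_lens)
  hits <- list()
  for (g in seq_len(nrow(grid))) {
    lens <- as.integer(grid[g, ])
    total <- sum(ifelse(vapply(els, function(el) is.null(el$allowed), TRUE),
                        lens, 1L))
    if (total > n) next
    for (s in seq_len(n - total + 1L)) {
      pos <- s
      ok <- TRUE
      for (k in seq_along(els)) {
        el <- els[[k]]
        if (is.null(el$allowed)) {
          pos <- pos + lens[k]
        } else {
          if (!chars[pos] %in% el$allowed) { ok <- FALSE; break }
          pos <- pos + 1L
        }
      }
      if (ok) {
        hits[[length(hits) + 1L]] <- c(start = s, end = s + total - 1L)
      }
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(start = integer(), end = integer()))
  }
  out <- unique(as.data.frame(do.call(rbind, hits)))
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# --- 11-mer pattern check and tandem-run enumeration ------------------

oracle_match_pattern <- function(elevenmer, pattern) {
  b <- strsplit(elevenmer, "")[[1]]
  all(vapply(names(pattern$constraints), function(p)
    b[as.integer(p)] %in% pattern$constraints[[p]], logical(1)))
}

# enumerate every maximal contiguous loose run over all offsets/registers,
# filter by min_repeats and >= 1 strict, then apply the documented
# priority rule (strict count, DR count, leftmost) for overlaps
oracle_scan <- function(seq, patterns, min_repeats = 3L) {
  n <- nchar(seq)
  elevenmer_at <- function(o) substr(seq, o + 1L, o + 11L)  # 0-based offset
  loose_at <- function(o) o >= 0L && o + 11L <= n &&
    oracle_match_pattern(elevenmer_at(o), patterns$loose)
  runs <- list()
  for (o in 0:(n - 11L)) {
    if (!loose_at(o) || loose_at(o - 11L)) next
    offs <- o
    while (loose_at(offs[length(offs)] + 11L))
      offs <- c(offs, offs[length(offs)] + 11L)
    if (length(offs) < min_repeats) next
    units <- vapply(offs, elevenmer_at, "")
    n_strict <- sum(vapply(units, oracle_match_pattern, TRUE,
                           pattern = patterns$strict))
    n_dr <- sum(vapply(units, oracle_match_pattern, TRUE,
                       pattern = patterns$DR_label))
    if (n_strict >= 1L) {
      runs[[length(runs) + 1L]] <-
        list(offset = o, units = units, n_strict = n_strict, n_DR = n_dr)
    }
  }
  if (length(runs) <= 1L) return(runs)
  ord <- order(-vapply(runs, `[[`, 0, "n_strict"),
               -vapply(runs, `[[`, 0, "n_DR"),
               vapply(runs, `[[`, 0, "offset"))
  kept <- list()
  for (i in ord) {
    ri <- runs[[i]]
    span_i <- c(ri$offset, ri$offset + 11L * length(ri$units) - 1L)
    clash <- any(vapply(kept, function(rk) {
      span_k <- c(rk$offset, rk$offset + 11L * length(rk$units) - 1L)
      span_i[1] <= span_k[2] && span_k[1] <= span_i[2]
    }, logical(1)))
    if (!clash) kept[[length(kept) + 1L]] <- ri
  }
  kept[order(vapply(kept, `[[`, 0, "offset"))]
}

# --- affine-gap global alignment (Gotoh) ------------------------------

# BLOSUM62 lookup without pairwiseAlignment machinery
.blosum62 <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      data("BLOSUM62", package = "Biostrings", envir = environment())
      m <<- get("BLOSUM62", envir = environment())
    }
    m
  }
})

oracle_global_align <- function(a, b, go = 10, ge = 0.5) {
  # Gotoh affine-gap global alignment; gap of length L costs go + ge * L.
  # Returns the optimal score and one optimal alignment (diagonal
  # preferred on ties).
  sm <- .blosum62()
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1L, m + 1L)   # ends in match/mismatch
  X <- matrix(NEG, n + 1L, m + 1L)   # ends in gap in b (a consumed)
  Y <- matrix(NEG, n + 1L, m + 1L)   # ends in gap in a (b consumed)
  M[1, 1] <- 0
  for (i in 2:(n + 1L)) X[i, 1] <- -go - ge * (i - 1L)
  for (j in 2:(m + 1L)) Y[1, j] <- -go - ge * (j - 1L)
  for (i in 2:(n + 1L)) {
    for (j in 2:(m + 1L)) {
      s <- sm[av[i - 1L], bv[j - 1L]]
      M[i, j] <- max(M[i - 1L, j - 1L], X[i - 1L, j - 1L],
                     Y[i - 1L, j - 1L]) + s
      X[i, j] <- max(M[i - 1L, j] - go - ge, X[i - 1L, j] - ge)
      Y[i, j] <- max(M[i, j - 1L] - go - ge, Y[i, j - 1L] - ge)
    }
  }
  score <- max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
  # traceback for one optimal alignment
  ai <- character(0); bi <- character(0)
  i <- n + 1L; j <- m + 1L
  state <- c("M", "X", "Y")[which.max(c(M[i, j], X[i, j], Y[i, j]))]
  while (i > 1L || j > 1L) {
    if (state == "M") {
      s <- sm[av[i - 1L], bv[j - 1L]]
      prev <- c(M[i - 1L, j - 1L], X[i - 1L, j - 1L], Y[i - 1L, j - 1L])
      state <- c("M", "X", "Y")[which.max(prev)]
      ai <- c(av[i - 1L], ai); bi <- c(bv[j - 1L], bi)
      i <- i - 1L; j <- j - 1L
    } else if (state == "X") {
      from_m <- M[i - 1L, j] - go - ge
      state <- if (X[i, j] == from_m) "M" else "X"
      ai <- c(av[i - 1L], ai); bi <- c("-", bi)
      i <- i - 1L
    } else {
      from_m <- M[i, j - 1L] - go - ge
      state <- if (Y[i, j] == from_m) "M" else "Y"
      ai <- c("-", ai); bi <- c(bv[j - 1L], bi)
      j <- j - 1L
    }
    if (i == 1L && j > 1L) state <- "Y"
    if (j == 1L && i > 1L) state <- "X"
  }
  gap <- ai == "-" | bi == "-"
  inner <- seq_along(ai) >= min(which(!gap)) & seq_along(ai) <= max(which(!gap))
  list(score = score,
       identity = 100 * sum(ai[inner] == bi[inner]) / sum(inner))
}

# --- random sequence helpers ------------------------------------------

random_dna_str <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

random_protein_str <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}
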