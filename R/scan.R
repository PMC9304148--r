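#' 11-bp repeat pattern
#'
#' A repeat pattern constrains some of the 11 positions of a repeat unit
#' to subsets of \{A, C, G, T\}; unconstrained positions accept any base.
#' The ambiguity base N never satisfies a constrained position.
#'
#' @param name Pattern name.
#' @param constraints Named list mapping position (as character
#'   \code{"1"}..\code{"11"}) to a character vector of allowed bases.
#' @return Object of class \code{repeat_pattern}.
#' @export
repeat_pattern <- function(name, constraints) {
  pos <- as.integer(names(constraints))
  if (any(is.na(pos)) || any(pos < 1L | pos > 11L))
    stop("constraint positions must be in 1..11")
  for (p in constraints) {
    if (length(p) == 0L || !all(p %in% c("A", "C", "G", "T")))
      stop("allowed sets must be non-empty subsets of {A,C,G,T}")
  }
  structure(list(name = name, constraints = constraints),
            class = "repeat_pattern")
}

#' Default and methods-literal repeat pattern sets
#'
#' The default ("nested") preset reconciles the two printed notations for
#' the repeat consensus so that DR implies strict implies loose:
#' \itemize{
#'   \item \code{loose}: T at position 5, C at 9 (run membership).
#'   \item \code{strict}: T5, R8, C9, R10 (R = A or G); at least one
#'     strict unit is required per operator call.
#'   \item \code{DR_label}: T5, A8, C9, A10 -- i.e. TnnACA fully conserved
#'     at positions 5-10. Units matching loose but not DR_label are
#'     labelled dr.
#' }
#' The \code{"methods_literal"} preset reads the bracketed Methods-style
#' patterns N4-T-N3-C[C][G] (loose: T5, C9, C10, G11) and N4-T-N2-RCR[G]
#' (strict: T5, R8, C9, R10, G11) with brackets as literal fixed bases.
#'
#' @param preset \code{"nested"} (default) or \code{"methods_literal"}.
#' @return Named list of \code{repeat_pattern}s: \code{loose},
#'   \code{strict}, \code{DR_label}.
#' @export
repeat_pattern_preset <- function(preset = c("nested", "methods_literal")) {
  preset <- match.arg(preset)
  R <- c("A", "G")
  if (preset == "nested") {
    list(
      loose = repeat_pattern("loose", list(`5` = "T", `9` = "C")),
      strict = repeat_pattern("strict",
                              list(`5` = "T", `8` = R, `9` = "C", `10` = R)),
      DR_label = repeat_pattern("DR_label",
                                list(`5` = "T", `8` = "A", `9` = "C", `10` = "A"))
    )
  } else {
    list(
      loose = repeat_pattern("loose",
                             list(`5` = "T", `9` = "C", `10` = "C", `11` = "G")),
      strict = repeat_pattern("strict",
                              list(`5` = "T", `8` = R, `9` = "C", `10` = R, `11` = "G")),
      DR_label = repeat_pattern("DR_label",
                                list(`5` = "T", `8` = "A", `9` = "C", `10` = "A"))
    )
  }
}

#' Test an 11-mer against a repeat pattern
#'
#' @param elevenmer String of length 11 over A, C, G, T, N (N never
#'   matches a constrained position).
#' @param pattern A \code{repeat_pattern}.
#' @return \code{TRUE} iff every constrained position holds an allowed
#'   base.
#' @export
match_pattern <- function(elevenmer, pattern) {
  elevenmer <- toupper(as.character(elevenmer))
  if (nchar(elevenmer) != 11L) stop("repeat unit must be 11 bp")
  bases <- strsplit(elevenmer, "")[[1]]
  for (p in names(pattern$constraints)) {
    if (!bases[as.integer(p)] %in% pattern$constraints[[p]]) return(FALSE)
  }
  TRUE
}

# Vectorized membership over all start offsets of a window.
.match_offsets <- function(seq, pattern) {
  n <- nchar(seq)
  if (n < 11L) return(logical(0))
  starts <- seq_len(n - 10L)
  ok <- rep(TRUE, length(starts))
  for (p in names(pattern$constraints)) {
    i <- as.integer(p)
    ok <- ok & substring(seq, starts + i - 1L, starts + i - 1L) %in%
      pattern$constraints[[p]]
  }
  ok
}

.label_units <- function(seq, offsets0, patterns) {
  elevenmers <- substring(seq, offsets0 + 1L, offsets0 + 11L)
  strict <- vapply(elevenmers, match_pattern, TRUE,
                   pattern = patterns$strict, USE.NAMES = FALSE)
  is_dr <- vapply(elevenmers, match_pattern, TRUE,
                  pattern = patterns$DR_label, USE.NAMES = FALSE)
  mism <- lapply(elevenmers, function(e) {
    b <- strsplit(e, "")[[1]]
    cons <- patterns$DR_label$constraints
    pos <- as.integer(names(cons))
    pos[!mapply(function(i, allowed) b[i] %in% allowed, pos, cons)]
  })
  data.frame(index = seq_along(offsets0), offset = offsets0,
             elevenmer = elevenmers,
             label = ifelse(is_dr, "DR", "dr"),
             strict_match = strict,
             mismatches = I(mism), stringsAsFactors = FALSE)
}

.make_operator_call <- function(window, seq, offsets0, patterns) {
  units <- .label_units(seq, offsets0, patterns)
  structure(
    list(window = window, repeats = units,
         span_bp = 11L * nrow(units),
         arrangement = paste0(units$label, units$index, collapse = "-"),
         n_DR = sum(units$label == "DR"),
         n_strict = sum(units$strict_match),
         offset = offsets0[1L]),
    class = "operator_call")
}

#' @export
print.operator_call <- function(x, ...) {
  cat(sprintf("operator call: %s (%d bp at window offset %d, %d DR, %d strict)\n",
              x$arrangement, x$span_bp, x$offset, x$n_DR, x$n_strict))
  invisible(x)
}

#' Arrangement string of an operator call
#'
#' Hyphen-joined DR/dr labels with 1-based indices in 5'->3' order, e.g.
#' \code{"DR1-dr2-DR3-DR4-dr5"}.
#'
#' @param call An \code{operator_call}.
#' @return character scalar.
#' @export
arrangement_string <- function(call) {
  if (nrow(call$repeats) == 0L) stop("operator call has no repeats")
  paste0(call$repeats$label, call$repeats$index, collapse = "-")
}

#' Scan a promoter window for tandem 11-bp direct-repeat operators
#'
#' Finds every maximal run of contiguous (11 bp step) 11-mers matching the
#' loose pattern, keeps runs of at least \code{min_repeats} units with at
#' least one strict match, labels each unit DR (TnnACA fully conserved) or
#' dr, and resolves overlapping candidate runs in different registers
#' deterministically: more strict matches, then more DR labels, then
#' leftmost.
#'
#' @param window A \code{promoter_window} or a plain character sequence.
#' @param patterns Pattern set from \code{repeat_pattern_preset()}.
#' @param min_repeats Minimum run length (default 3).
#' @param max_gap Maximum gap in bp between consecutive units (default 0:
#'   repeats must abut).
#' @return list of \code{operator_call}s sorted by window offset (0-based
#'   offsets, as positions within the window sequence).
#' @export
scan_tandem_repeats <- function(window, patterns = repeat_pattern_preset(),
                                min_repeats = 3L, max_gap = 0L) {
  seq <- if (inherits(window, "promoter_window")) window$sequence
         else toupper(as.character(window))
  if (nchar(seq) < 11L * min_repeats)
    stop("window shorter than ", 11L * min_repeats, " bp")
  loose <- .match_offsets(seq, patterns$loose)
  step <- 11L + as.integer(max_gap)
  n <- length(loose)
  runs <- list()
  for (s in which(loose)) {
    if (s - step >= 1L && loose[s - step]) next  # not a run start
    offs <- s
    while (offs[length(offs)] + step <= n && loose[offs[length(offs)] + step])
      offs <- c(offs, offs[length(offs)] + step)
    if (length(offs) >= min_repeats) runs[[length(runs) + 1L]] <- offs - 1L
  }
  calls <- lapply(runs, function(offs0)
    .make_operator_call(window, seq, offs0, patterns))
  calls <- Filter(function(cl) cl$n_strict >= 1L, calls)
  if (length(calls) <= 1L) return(calls)
  # resolve overlaps between registers: greedy in priority order
  spans <- lapply(calls, function(cl) c(cl$offset, cl$offset + cl$span_bp - 1L))
  ord <- order(vapply(calls, function(cl) -cl$n_strict, 0),
               vapply(calls, function(cl) -cl$n_DR, 0),
               vapply(calls, function(cl) cl$offset, 0L))
  kept <- integer(0)
  for (i in ord) {
    clash <- any(vapply(kept, function(j)
      spans[[i]][1] <= spans[[j]][2] && spans[[j]][1] <= spans[[i]][2],
      logical(1)))
    if (!clash) kept <- c(kept, i)
  }
  calls[sort(kept)]
}

#' Position-frequency matrix and consensus of aligned 11-mers
#'
#' @param repeats Character vector of 11-mers (e.g.
#'   \code{call$repeats$elevenmer}).
#' @return list with \code{pfm} (4 x 11 count matrix, rows A/C/G/T; each
#'   column sums to the number of repeats) and \code{consensus} (most
#'   frequent base per column; ties reported as IUPAC ambiguity codes).
#' @export
build_pfm <- function(repeats) {
  if (length(repeats) == 0L) stop("no repeats supplied")
  repeats <- toupper(repeats)
  if (any(nchar(repeats) != 11L)) stop("all repeats must be 11 bp")
  pfm <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(repeats))
  full <- matrix(0L, 4L, 11L, dimnames = list(c("A", "C", "G", "T"), NULL))
  common <- intersect(rownames(pfm), rownames(full))
  full[common, ] <- pfm[common, ]
  amb <- Biostrings::IUPAC_CODE_MAP
  consensus <- vapply(seq_len(11L), function(j) {
    col <- full[, j]
    top <- names(col)[col == max(col)]
    if (length(top) == 1L) top
    else names(amb)[match(paste(sort(top), collapse = ""), amb)]
  }, "")
  list(pfm = full, consensus = paste(consensus, collapse = ""),
       n_sequences = length(repeats))
}

#' Scan every annotated gene of a genome for operators
#'
#' Extracts the promoter window of each feature and runs
#' \code{scan_tandem_repeats}; the scan is performed on the gene's coding
#' strand.
#'
#' @param genome \code{DNAStringSet} or named character vector.
#' @param features data frame from \code{read_gff3}.
#' @param patterns,min_repeats,max_gap Passed to
#'   \code{scan_tandem_repeats}.
#' @param upstream,downstream Window bounds (defaults 150 and 25).
#' @return data frame with one row per operator call (genes without a call
#'   get a row with \code{n_repeats = 0}); columns \code{gene_id},
#'   \code{contig_id}, \code{strand}, \code{n_repeats}, \code{offset},
#'   \code{span_bp}, \code{arrangement}, \code{sequence}, \code{error}.
#' @export
scan_genome <- function(genome, features, patterns = repeat_pattern_preset(),
                        min_repeats = 3L, max_gap = 0L,
                        upstream = 150L, downstream = 25L) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  ids <- make.unique(as.character(features$gene_id))
  rows <- lapply(seq_len(nrow(features)), function(i) {
    feat <- features[i, , drop = FALSE]
    gid <- ids[i]
    base <- data.frame(gene_id = gid, contig_id = feat$contig_id,
                       strand = feat$strand, n_repeats = 0L,
                       offset = NA_integer_, span_bp = NA_integer_,
                       arrangement = NA_character_, sequence = NA_character_,
                       error = NA_character_, stringsAsFactors = FALSE)
    win <- tryCatch(
      extract_promoter_window(genome, feat, upstream, downstream),
      error = function(e) e)
    if (inherits(win, "error")) {
      base$error <- conditionMessage(win)
      return(base)
    }
    calls <- scan_tandem_repeats(win, patterns, min_repeats, max_gap)
    if (length(calls) == 0L) return(base)
    do.call(rbind, lapply(calls, function(cl) {
      out <- base
      out$n_repeats <- nrow(cl$repeats)
      out$offset <- cl$offset
      out$span_bp <- cl$span_bp
      out$arrangement <- cl$arrangement
      out$sequence <- substr(win$sequence, cl$offset + 1L,
                             cl$offset + cl$span_bp)
      out
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
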