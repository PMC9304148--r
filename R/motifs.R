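#' Degenerate protein motif specification
#'
#' A motif is an ordered list of elements: fixed residue sets (one or more
#' allowed amino acids at one position) and spacers of bounded length
#' ("x_n" runs that match any residue). The ambiguity letter X in a query
#' sequence is tolerated by spacers but never matches a fixed residue.
#'
#' @param name Motif name.
#' @param elements List of elements, each either
#'   \code{list(allowed = c("D","E"))} for one constrained position or
#'   \code{list(min = 22, max = 27)} for a bounded-length wildcard spacer.
#' @return Object of class \code{motif_spec}.
#' @export
motif_spec <- function(name, elements) {
  for (el in elements) {
    if (!is.null(el$allowed)) {
      if (length(el$allowed) == 0L) stop("empty allowed set in motif '", name, "'")
    } else {
      if (is.null(el$min) || is.null(el$max) || el$min > el$max || el$min < 0)
        stop("invalid spacer bounds in motif '", name, "'")
    }
  }
  structure(list(name = name, elements = elements), class = "motif_spec")
}

spacer <- function(n, m = n) list(min = as.integer(n), max = as.integer(m))
fixed <- function(...) list(allowed = c(...))

#' Default CarH/CarA signature motifs
#'
#' The three motifs used to classify CarH/CarA homologues, rendered
#' literally from their printed form:
#' \itemize{
#'   \item \code{Wx9EH}: Trp, 9 wildcards, Glu, His. Contacts the upper
#'     axial adenosyl group of AdoCbl; intact only in CarH.
#'   \item \code{B12_binding}: D/E, x, H, x2, G/P, x41, S, x, T/V, x22-27,
#'     G, G. The classic cobalamin-binding motif of the Rossmann module;
#'     its His provides the lower axial ligand.
#'   \item \code{RxWERRY}: Arg, x, Trp, Glu, Arg, Arg, Tyr, in the DNA
#'     recognition helix of the MerR-type winged-helix DBD; conserved in
#'     both CarH and CarA.
#' }
#' Spacer bounds are exactly as printed (x41 exact; x22-27 bounded); they
#' can be overridden by constructing a \code{motif_spec} directly.
#'
#' @return Named list of \code{motif_spec} objects.
#' @export
carh_motifs <- function() {
  list(
    Wx9EH = motif_spec("Wx9EH", list(
      fixed("W"), spacer(9), fixed("E"), fixed("H"))),
    B12_binding = motif_spec("B12_binding", list(
      fixed("D", "E"), spacer(1), fixed("H"), spacer(2), fixed("G", "P"),
      spacer(41), fixed("S"), spacer(1), fixed("T", "V"),
      spacer(22, 27), fixed("G"), fixed("G"))),
    RxWERRY = motif_spec("RxWERRY", list(
      fixed("R"), spacer(1), fixed("W"), fixed("E"), fixed("R"), fixed("R"),
      fixed("Y")))
  )
}

# All concrete (fixed-length) regex renderings of a motif_spec, one per
# combination of admissible spacer lengths, with the total match length.
.motif_variants <- function(spec) {
  lens <- lapply(spec$elements, function(el) {
    if (!is.null(el$allowed)) 0L else seq.int(el$min, el$max)
  })
  varying <- which(vapply(lens, length, 1L) > 1L)
  combos <- if (length(varying) == 0L) {
    list(vapply(lens, `[`, 1L, 1L))
  } else {
    grid <- do.call(expand.grid, lens[varying])
    lapply(seq_len(nrow(grid)), function(i) {
      v <- vapply(lens, `[`, 1L, 1L)
      v[varying] <- as.integer(grid[i, ])
      v
    })
  }
  lapply(combos, function(splens) {
    parts <- character(length(spec$elements))
    for (i in seq_along(spec$elements)) {
      el <- spec$elements[[i]]
      parts[i] <- if (!is.null(el$allowed)) {
        if (length(el$allowed) == 1L) el$allowed else
          paste0("[", paste(el$allowed, collapse = ""), "]")
      } else if (splens[i] > 0L) sprintf(".{%d}", splens[i]) else ""
    }
    list(regex = paste(parts, collapse = ""),
         len = sum(splens) + sum(vapply(spec$elements, function(el)
           if (!is.null(el$allowed)) 1L else 0L, 1L)))
  })
}

#' Find all matches of a degenerate motif in a protein sequence
#'
#' Every admissible spacer-length combination is explored, so overlapping
#' matches and matches of different lengths starting at the same position
#' are all reported. Matches are returned in order of start position, then
#' end position.
#'
#' @param seq A protein sequence (character scalar or \code{AAString}).
#' @param spec A \code{motif_spec}.
#' @return data frame with columns \code{motif}, \code{start}, \code{end}
#'   (1-based inclusive residue positions) and \code{matched_span}.
#' @export
find_motif <- function(seq, spec) {
  if (!inherits(spec, "motif_spec")) stop("spec must be a motif_spec")
  seq <- toupper(as.character(seq))
  empty <- data.frame(motif = character(), start = integer(),
                      end = integer(), matched_span = character(),
                      stringsAsFactors = FALSE)
  if (nchar(seq) == 0L) return(empty)
  hits <- list()
  for (v in .motif_variants(spec)) {
    # zero-width lookahead so overlapping starts are all reported
    m <- gregexpr(paste0("(?=", v$regex, ")"), seq, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    starts <- as.integer(m)
    hits[[length(hits) + 1L]] <- data.frame(
      motif = spec$name, start = starts, end = starts + v$len - 1L,
      matched_span = substring(seq, starts, starts + v$len - 1L),
      stringsAsFactors = FALSE)
  }
  if (length(hits) == 0L) return(empty)
  out <- do.call(rbind, hits)
  out <- unique(out)
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}
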