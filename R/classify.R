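#' Split a homologue into DNA-binding and cobalamin-binding domains
#'
#' CarH/CarA homologues share an N-terminal MerR-type winged-helix DNA
#' binding domain (DBD) and a C-terminal cobalamin-binding domain (CBD).
#' The exact boundary is not annotated per homologue, so a declared
#' heuristic is used: the DBD ends a fixed wing allowance after the
#' RxWERRY recognition-helix motif, and the CBD starts at the next
#' residue.
#'
#' @param seq Protein sequence.
#' @param hits Motif hits for the sequence (data frame from
#'   \code{find_motif}); must contain an RxWERRY hit.
#' @param wing_allowance Residues allotted to the wing after the RxWERRY
#'   motif (default 30), capped at the sequence end.
#' @return list with \code{dbd_end} and \code{cbd_start}.
#' @export
split_domains <- function(seq, hits, wing_allowance = 30L) {
  seq <- as.character(seq)
  rx <- hits[hits$motif == "RxWERRY", , drop = FALSE]
  if (nrow(rx) == 0L) stop("cannot split domains: no RxWERRY hit")
  n <- nchar(seq)
  dbd_end <- rx$end[1L] + as.integer(wing_allowance)
  if (dbd_end >= n) {
    warning("RxWERRY near C-terminus; DBD end capped at sequence end - 1")
    dbd_end <- n - 1L
  }
  list(dbd_end = dbd_end, cbd_start = dbd_end + 1L)
}

#' Classify a protein as a CarH or CarA homologue
#'
#' Applies the motif co-occurrence criterion: a classic cobalamin-binding
#' (B12) motif is required for membership in the family; among members, an
#' intact Wx9EH motif indicates CarH, while its absence together with a
#' conserved RxWERRY DNA-recognition motif indicates CarA (which retains
#' the B12 motif but lost the Trp of Wx9EH). Length outside the accepted
#' homologue size range (286-330 aa) and, when reference sequences are
#' supplied, best pairwise identity below the acceptance threshold are
#' reported as failed filters without changing the label.
#'
#' @param seq Protein sequence.
#' @param motifs Named list of \code{motif_spec}s (default
#'   \code{carh_motifs()}).
#' @param length_range Accepted homologue length range (default
#'   \code{c(286, 330)}).
#' @param references Optional named character vector of reference protein
#'   sequences for the identity filter.
#' @param min_identity Identity acceptance threshold in percent (default
#'   29).
#' @return Object of class \code{homolog_call}: list with \code{label}
#'   (\code{"CarH"}, \code{"CarA"}, \code{"ambiguous"} or
#'   \code{"non_member"}), \code{evidence} (named logical: motif
#'   presence), \code{hits}, \code{passed_filters}, \code{filters} and
#'   \code{length}.
#' @export
classify_homolog <- function(seq, motifs = carh_motifs(),
                             length_range = c(286L, 330L),
                             references = NULL, min_identity = 29) {
  seq <- toupper(as.character(seq))
  hits <- do.call(rbind, lapply(motifs, function(m) find_motif(seq, m)))
  present <- vapply(names(motifs), function(nm)
    any(hits$motif == nm), logical(1))
  has_b12 <- isTRUE(present[["B12_binding"]])
  has_w <- isTRUE(present[["Wx9EH"]])
  has_rx <- isTRUE(present[["RxWERRY"]])
  label <- if (!has_b12) "non_member"
  else if (has_w) "CarH"
  else if (has_rx) "CarA"
  else "ambiguous"
  n <- nchar(seq)
  filters <- c(length_ok = n >= length_range[1] && n <= length_range[2])
  if (!is.null(references)) {
    ids <- vapply(references, function(r) pairwise_identity(seq, r), 0)
    filters <- c(filters, identity_ok = max(ids) >= min_identity)
  }
  structure(
    list(label = label, evidence = present, hits = hits,
         passed_filters = all(filters), filters = filters, length = n),
    class = "homolog_call")
}

#' @export
print.homolog_call <- function(x, ...) {
  cat(sprintf("homologue call: %s (%d aa%s)\n", x$label, x$length,
              if (x$passed_filters) "" else ", FAILED filters"))
  ev <- paste(sprintf("%s=%s", names(x$evidence),
                      ifelse(x$evidence, "yes", "no")), collapse = ", ")
  cat(" motifs:", ev, "\n")
  invisible(x)
}

#' Percent identity from a global pairwise alignment
#'
#' Needleman-Wunsch global alignment with BLOSUM62 and affine gap
#' penalties; identity is the fraction of identical columns over aligned
#' columns, excluding terminal gap columns. Symmetric by construction of
#' the scoring scheme; alignment traceback ties are resolved
#' deterministically by the aligner.
#'
#' @param a,b Protein sequences (character).
#' @param substitution_matrix Scoring matrix name (default
#'   \code{"BLOSUM62"}).
#' @param gap_opening,gap_extension Affine gap penalties (defaults 10 and
#'   0.5).
#' @return Percent identity in [0, 100].
#' @export
pairwise_identity <- function(a, b, substitution_matrix = "BLOSUM62",
                              gap_opening = 10, gap_extension = 0.5) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (nchar(a) == 0L || nchar(b) == 0L) stop("empty sequence")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "global", substitutionMatrix = substitution_matrix,
    gapOpening = gap_opening, gapExtension = gap_extension)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  # drop terminal gap columns on either end
  gap <- pa == "-" | pb == "-"
  keep <- seq_along(pa) >= min(which(!gap)) & seq_along(pa) <= max(which(!gap))
  pa <- pa[keep]; pb <- pb[keep]
  100 * sum(pa == pb) / length(pa)
}

#' Identity matrix of query proteins against reference proteins
#'
#' Whole-protein and, where a domain split is available, DBD-only and
#' CBD-only percent identities against each reference, mirroring the
#' heat-map comparison of homologues against CarA/CarH and their domains.
#'
#' @param records Named character vector (or \code{AAStringSet}) of query
#'   proteins.
#' @param references Named character vector (or \code{AAStringSet}) of
#'   reference proteins.
#' @param splits Optional named list of domain splits (from
#'   \code{split_domains}) for queries and references; proteins without a
#'   split get whole-protein values only (domain cells \code{NA}).
#' @param ... Passed to \code{pairwise_identity}.
#' @return data frame with one row per (query, reference) pair and columns
#'   \code{query}, \code{reference}, \code{whole}, \code{dbd}, \code{cbd}.
#' @export
identity_matrix <- function(records, references, splits = NULL, ...) {
  records <- vapply(as.list(records), as.character, "")
  references <- vapply(as.list(references), as.character, "")
  out <- expand.grid(query = names(records), reference = names(references),
                     stringsAsFactors = FALSE)
  part <- function(seq, sp, which) {
    if (is.null(sp)) return(NULL)
    if (which == "dbd") substr(seq, 1L, sp$dbd_end)
    else substr(seq, sp$cbd_start, nchar(seq))
  }
  res <- t(vapply(seq_len(nrow(out)), function(i) {
    qn <- out$query[i]; rn <- out$reference[i]
    q <- records[[qn]]; r <- references[[rn]]
    whole <- pairwise_identity(q, r, ...)
    qs <- splits[[qn]]; rs <- splits[[rn]]
    dbd <- cbd <- NA_real_
    if (!is.null(qs) && !is.null(rs)) {
      dbd <- pairwise_identity(part(q, qs, "dbd"), part(r, rs, "dbd"), ...)
      cbd <- pairwise_identity(part(q, qs, "cbd"), part(r, rs, "cbd"), ...)
    }
    c(whole = whole, dbd = dbd, cbd = cbd)
  }, c(whole = 0, dbd = 0, cbd = 0)))
  cbind(out, as.data.frame(res))
}
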