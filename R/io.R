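#' Read sequences from a FASTA file
#'
#' Thin wrapper around the Biostrings FASTA readers that upper-cases
#' sequences and validates records. Nucleotide files are returned as a
#' \code{DNAStringSet}, protein files as an \code{AAStringSet}.
#'
#' @param path Path to a FASTA file.
#' @param type One of \code{"dna"} or \code{"protein"}.
#' @return A \code{DNAStringSet} or \code{AAStringSet}; names are record
#'   ids (first whitespace-delimited token of the header), with the full
#'   header retained in the \code{description} metadata column.
#' @export
read_fasta <- function(path, type = c("dna", "protein")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- if (type == "dna") {
    Biostrings::readDNAStringSet(path, format = "fasta")
  } else {
    Biostrings::readAAStringSet(path, format = "fasta")
  }
  if (length(set) == 0L) {
    warning("no records in FASTA file: ", path)
    return(set)
  }
  headers <- names(set)
  empty <- Biostrings::width(set) == 0L
  if (any(empty)) {
    stop("empty sequence for FASTA record: ",
         paste(headers[empty], collapse = ", "))
  }
  up <- toupper(as.character(set))
  set <- if (type == "dna") Biostrings::DNAStringSet(up)
         else Biostrings::AAStringSet(up)
  ids <- sub("\\s.*$", "", headers)
  mcols <- S4Vectors::DataFrame(description = headers)
  names(set) <- ids
  S4Vectors::mcols(set) <- mcols
  set
}

#' Write sequences to a FASTA file
#'
#' @param set An \code{XStringSet} (or named character vector, coerced to
#'   \code{BStringSet}).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(set, path) {
  if (is.character(set)) set <- Biostrings::BStringSet(set)
  Biostrings::writeXStringSet(set, filepath = path, format = "fasta")
  invisible(path)
}

#' Read gene features from a GFF3 file
#'
#' Parses a standard 9-column GFF3 file (1-based inclusive coordinates)
#' through rtracklayer and returns the features of the requested type as a
#' plain data frame suitable for promoter-window extraction.
#'
#' @param path Path to a GFF3 file.
#' @param feature_type Feature types to keep (default \code{c("gene",
#'   "CDS")}); set \code{NULL} to keep everything.
#' @return data frame with columns \code{contig_id}, \code{start},
#'   \code{end}, \code{strand}, \code{gene_id}, \code{type}.
#' @export
read_gff3 <- function(path, feature_type = c("gene", "CDS")) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) stop("failed to parse GFF3 '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  df <- data.frame(
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start     = GenomicRanges::start(gr),
    end       = GenomicRanges::end(gr),
    strand    = as.character(GenomicRanges::strand(gr)),
    type      = as.character(gr$type),
    stringsAsFactors = FALSE
  )
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else rep(NA_character_, nrow(df))
  if (!is.null(gr$Name)) ids <- ifelse(is.na(ids), as.character(gr$Name), ids)
  df$gene_id <- ifelse(is.na(ids), paste0("feature_", seq_len(nrow(df))), ids)
  if (!is.null(feature_type)) df <- df[df$type %in% feature_type, , drop = FALSE]
  if (any(df$strand == "*")) {
    stop("feature(s) without strand in ", path, ": ",
         paste(utils::head(df$gene_id[df$strand == "*"], 3), collapse = ", "))
  }
  bad <- df$start > df$end | df$start < 1L
  if (any(bad)) {
    stop("invalid coordinates (start > end or start < 1) for: ",
         paste(df$gene_id[bad], collapse = ", "))
  }
  rownames(df) <- NULL
  df[, c("contig_id", "start", "end", "strand", "gene_id", "type")]
}

#' Extract a promoter window around an annotated translation start
#'
#' Cuts the region spanning gene-frame positions -upstream..-1 and
#' +1..+downstream relative to the first base of the annotated start codon
#' (there is no position 0, following the biology convention for promoter
#' numbering; the default -150..+25 window is therefore 175 nt). The
#' returned sequence is always written 5'->3' on the gene's coding strand:
#' for minus-strand genes it is the reverse complement of the genomic
#' slice. Windows running off a contig edge are clipped and flagged rather
#' than rejected, so draft genomes are usable.
#'
#' @param genome A \code{DNAStringSet} (e.g. from \code{read_fasta}) or a
#'   named character vector of contig sequences.
#' @param feature One row of the data frame returned by \code{read_gff3}
#'   (or any list with \code{contig_id}, \code{start}, \code{end},
#'   \code{strand}, \code{gene_id}).
#' @param upstream,downstream Number of bases upstream of the start codon
#'   and of coding bases to include (defaults 150 and 25).
#' @return An object of class \code{promoter_window}: a list with
#'   \code{gene_id}, \code{contig_id}, \code{window_start},
#'   \code{window_end} (1-based genomic, inclusive), \code{strand},
#'   \code{sequence}, \code{offset_of_plus1} (1-based index of the first
#'   coding base within \code{sequence}) and \code{truncated}.
#' @export
extract_promoter_window <- function(genome, feature,
                                    upstream = 150L, downstream = 25L) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  contig <- as.character(feature$contig_id)
  if (!contig %in% names(genome)) {
    stop("contig '", contig, "' not present in genome")
  }
  clen <- Biostrings::width(genome)[match(contig, names(genome))]
  start <- as.integer(feature$start)
  end <- as.integer(feature$end)
  strand <- as.character(feature$strand)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (start < 1L || end > clen || start > end) {
    stop("feature '", feature$gene_id, "' lies off contig '", contig, "'")
  }
  if (strand == "+") {
    ws <- start - upstream
    we <- start + downstream - 1L
  } else {
    # +1 is the last genomic base of the feature; upstream extends rightwards
    ws <- end - downstream + 1L
    we <- end + upstream
  }
  truncated <- ws < 1L || we > clen
  ws_c <- max(ws, 1L)
  we_c <- min(we, clen)
  slice <- Biostrings::subseq(genome[[contig]], start = ws_c, end = we_c)
  if (strand == "-") slice <- Biostrings::reverseComplement(slice)
  seq <- as.character(slice)
  offset_of_plus1 <- if (strand == "+") start - ws_c + 1L else we_c - end + 1L
  structure(
    list(gene_id = as.character(feature$gene_id),
         contig_id = contig,
         window_start = ws_c, window_end = we_c,
         strand = strand,
         sequence = seq,
         offset_of_plus1 = offset_of_plus1,
         truncated = truncated),
    class = "promoter_window"
  )
}

#' @export
print.promoter_window <- function(x, ...) {
  cat(sprintf("promoter window for %s (%s:%d-%d, %s strand)%s\n",
              x$gene_id, x$contig_id, x$window_start, x$window_end,
              x$strand, if (x$truncated) " [truncated]" else ""))
  cat(sprintf("  %d nt, +1 at window position %d\n",
              nchar(x$sequence), x$offset_of_plus1))
  invisible(x)
}
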