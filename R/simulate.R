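#' @importFrom withr with_seed
NULL

.random_dna <- function(n, gc = 0.68) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

.random_aa <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# one planted 11-bp unit; DR conserves TnnACA, dr carries exactly
# n_mismatch mutations at TnnACA-constrained positions that keep the loose
# pattern (positions 8/10), mutated breaks the loose pattern outright
.plant_unit <- function(label, gc = 0.68, n_mismatch = 1L) {
  b <- strsplit(.random_dna(11L, gc), "")[[1]]
  b[5] <- "T"; b[8] <- "A"; b[9] <- "C"; b[10] <- "A"
  if (label == "dr") {
    at <- sample(c(8L, 10L), min(n_mismatch, 2L))
    for (i in at) b[i] <- sample(c("C", "G", "T"), 1L)
  } else if (label == "mutated") {
    b[5] <- sample(c("A", "C", "G"), 1L)
    b[9] <- sample(c("A", "G", "T"), 1L)
  } else if (label != "DR") {
    stop("unknown unit label: ", label)
  }
  paste(b, collapse = "")
}

# window with a planted (possibly empty) run; rejection-sampled so that a
# scan of the window yields exactly the calls implied by the planted run
.gen_window <- function(labels, gc, window_length = 175L,
                        patterns = repeat_pattern_preset(),
                        min_repeats = 3L, n_mismatch = 1L,
                        offset = NULL, max_tries = 200L) {
  k <- length(labels)
  span <- 11L * k
  if (span > window_length) stop("planted run longer than the window")
  for (try in seq_len(max_tries)) {
    units <- vapply(labels, .plant_unit, "", gc = gc,
                    n_mismatch = n_mismatch)
    run <- paste(units, collapse = "")
    off <- if (is.null(offset)) {
      if (k == 0L) 0L else sample.int(window_length - span + 1L, 1L) - 1L
    } else as.integer(offset)
    seq <- paste0(.random_dna(off, gc), run,
                  .random_dna(window_length - off - span, gc))
    expected <- if (span >= 11L * min_repeats) {
      scan_tandem_repeats(run, patterns, min_repeats)
    } else list()
    actual <- scan_tandem_repeats(seq, patterns, min_repeats)
    ok <- length(actual) == length(expected) &&
      all(vapply(seq_along(actual), function(i)
        actual[[i]]$offset == expected[[i]]$offset + off &&
          identical(actual[[i]]$repeats$elevenmer,
                    expected[[i]]$repeats$elevenmer), logical(1)))
    if (ok) {
      return(list(sequence = seq, offset = off, units = units,
                  labels = labels, calls = actual))
    }
  }
  stop("rejection budget exceeded while generating a clean window; ",
       "try a different seed")
}

#' Generate a promoter window with a planted tandem-repeat operator
#'
#' Produces a 175-nt GC-matched promoter window containing a contiguous
#' run of planted 11-bp repeat units at a recorded offset. DR units carry
#' a fully conserved TnnACA core; dr units carry exactly
#' \code{n_mismatch} mismatches within TnnACA while still matching the
#' loose run pattern; \code{mutated} units break the run. The background
#' is rejection-sampled so that scanning the window recovers exactly the
#' planted operator (or nothing, when the planted run is shorter than
#' \code{min_repeats}).
#'
#' @param arrangement_spec Character vector of unit labels (\code{"DR"},
#'   \code{"dr"}, \code{"mutated"}), length >= 1, in 5'->3' order.
#' @param gc Background GC content (default 0.68, typical of the GC-rich
#'   66-75\% genomes this emulates).
#' @param seed Integer seed (generation is a pure function of the
#'   arguments).
#' @param n_mismatch Mismatches per dr unit within TnnACA (1-2; default 1).
#' @param offset Optional fixed 0-based offset of the run in the window.
#' @param min_repeats,patterns Scanner settings used for the purity check.
#' @param window_length Window length (default 175, i.e. -150..+25 with no
#'   position 0).
#' @return list with \code{window} (a \code{promoter_window}),
#'   \code{truth} (list: \code{offset} 0-based, \code{labels},
#'   \code{elevenmers}, \code{arrangement}, \code{span_bp}).
#' @export
gen_promoter <- function(arrangement_spec, gc = 0.68, seed = 1L,
                         n_mismatch = 1L, offset = NULL,
                         min_repeats = 3L,
                         patterns = repeat_pattern_preset(),
                         window_length = 175L) {
  if (length(arrangement_spec) < 1L)
    stop("arrangement_spec must have at least one unit")
  withr::with_seed(seed, {
    w <- .gen_window(arrangement_spec, gc, window_length, patterns,
                     min_repeats, n_mismatch, offset)
    window <- structure(
      list(gene_id = "synthetic_gene", contig_id = "synthetic_contig",
           window_start = 1L, window_end = window_length, strand = "+",
           sequence = w$sequence,
           offset_of_plus1 = window_length - 24L, truncated = FALSE),
      class = "promoter_window")
    keep <- w$labels != "mutated"
    list(window = window,
         truth = list(offset = w$offset, labels = w$labels,
                      elevenmers = w$units,
                      arrangement = if (any(keep))
                        paste0(ifelse(w$labels == "DR", "DR", "dr")[keep],
                               seq_len(sum(keep)), collapse = "-")
                      else "",
                      span_bp = 11L * length(w$labels)))
  })
}

#' Generate a CarH-, CarA- or non-member-like protein sequence
#'
#' Plants the RxWERRY, Wx9EH and cobalamin-binding motifs (in DBD->CBD
#' order) in a random background of 286-330 residues. CarA-like sequences
#' carry the Wx9EH motif with its Trp substituted (the hallmark CarA
#' lesion); non-members lack the cobalamin-binding motif. Sequences are
#' rejection-sampled until the classifier recovers the intended label, so
#' accidental background motifs cannot blur the ground truth.
#'
#' @param kind \code{"CarH"}, \code{"CarA"} or \code{"non_member"}.
#' @param seed Integer seed.
#' @param length_range Protein length range (default \code{c(286, 330)}).
#' @param max_tries Rejection budget.
#' @return list with \code{sequence}, \code{kind} and \code{truth}
#'   (planted motif positions).
#' @export
gen_protein <- function(kind = c("CarH", "CarA", "non_member"), seed = 1L,
                        length_range = c(286L, 330L), max_tries = 100L) {
  kind <- match.arg(kind)
  withr::with_seed(seed, {
    for (try in seq_len(max_tries)) {
      n <- sample(length_range[1]:length_range[2], 1L)
      rx_start <- sample(20:40, 1L)
      rxwerry <- paste0("R", .random_aa(1L), "WERRY")
      wx_start <- rx_start + 7L + 30L + sample(0:10, 1L)
      wchar <- if (kind == "CarA") "A" else "W"
      wx9eh <- paste0(wchar, .random_aa(9L), "EH")
      b12_start <- wx_start + 13L + sample(0:10, 1L)
      sp2 <- sample(22:27, 1L)
      b12 <- paste0(sample(c("D", "E"), 1L), .random_aa(1L), "H",
                    .random_aa(2L), sample(c("G", "P"), 1L),
                    .random_aa(41L), "S", .random_aa(1L),
                    sample(c("T", "V"), 1L), .random_aa(sp2), "GG")
      seq <- strsplit(.random_aa(n), "")[[1]]
      put <- function(seq, s, frag) {
        f <- strsplit(frag, "")[[1]]
        seq[s:(s + length(f) - 1L)] <- f
        seq
      }
      seq <- put(seq, rx_start, rxwerry)
      seq <- put(seq, wx_start, wx9eh)
      if (kind != "non_member") seq <- put(seq, b12_start, b12)
      seq <- paste(seq, collapse = "")
      call <- classify_homolog(seq)
      if (call$label == kind && call$passed_filters) {
        return(list(sequence = seq, kind = kind,
                    truth = list(rxwerry = c(rx_start, rx_start + 6L),
                                 wx9eh = c(wx_start, wx_start + 12L),
                                 b12 = if (kind != "non_member")
                                   c(b12_start, b12_start + nchar(b12) - 1L))))
      }
    }
    stop("rejection budget exceeded while generating a ", kind,
         " protein; try a different seed")
  })
}

#' Generate an EMSA titration curve from Hill-model ground truth
#'
#' @param A,kd,h Ground-truth amplitude, apparent KD (nM) and Hill
#'   coefficient.
#' @param concentrations Protein concentrations in nM (defaults to the
#'   titration series 0.1, 0.25, 0.5, 1, 5, 10, 100).
#' @param noise_sigma Additive Gaussian noise standard deviation (default
#'   0: noise-free); values are clipped to [0, 1].
#' @param seed Integer seed (only consumed when \code{noise_sigma > 0}).
#' @return A \code{binding_curve} with the ground-truth parameters in
#'   \code{attr(, "truth")}.
#' @export
gen_emsa_curve <- function(A = 1, kd = 35, h = 2,
                           concentrations = c(0.1, 0.25, 0.5, 1, 5, 10, 100),
                           noise_sigma = 0, seed = 1L) {
  f <- .hill(concentrations, A, kd, h)
  if (noise_sigma > 0) {
    f <- withr::with_seed(seed,
      f + stats::rnorm(length(f), 0, noise_sigma))
    f <- pmin(pmax(f, 0), 1)
  }
  curve <- binding_curve(concentrations, f)
  attr(curve, "truth") <- list(A = A, kd = kd, h = h)
  curve
}

#' Generate a synthetic SEC elution trace with known oligomer peaks
#'
#' Places one Gaussian absorbance peak per requested oligomeric species at
#' the elution volume implied by inverting the calibration line for
#' n x protomer mass.
#'
#' @param oligomers Integer vector of oligomeric states (subset of 1..4).
#' @param protomer_mr Protomer mass in kDa.
#' @param calib A \code{sec_calibration}.
#' @param seed Integer seed (consumed by the noise draw).
#' @param peak_sd Gaussian peak width in ml (default 0.12).
#' @param noise_sigma Baseline noise (default 0.005 of unit peak height).
#' @param ve_step Grid spacing in ml.
#' @return list with \code{trace} (data frame \code{ve},
#'   \code{absorbance}) and \code{truth} (data frame \code{n}, \code{mr},
#'   \code{ve}).
#' @export
gen_sec_trace <- function(oligomers, protomer_mr, calib = sec_calibration(),
                          seed = 1L, peak_sd = 0.12, noise_sigma = 0.005,
                          ve_step = 0.01) {
  if (!all(oligomers %in% 1:4)) stop("oligomers must be a subset of 1..4")
  mr <- oligomers * protomer_mr
  centers <- sec_elution_volume(mr, calib)
  ve <- seq(calib$ve_range[1], calib$ve_range[2], by = ve_step)
  withr::with_seed(seed, {
    abs_ <- rowSums(vapply(centers, function(cc)
      exp(-0.5 * ((ve - cc) / peak_sd)^2), numeric(length(ve))))
    if (noise_sigma > 0)
      abs_ <- pmax(abs_ + stats::rnorm(length(ve), 0, noise_sigma), 0)
    list(trace = data.frame(ve = ve, absorbance = abs_),
         truth = data.frame(n = oligomers, mr = mr, ve = centers))
  })
}

#' Generate a mini genome with planted operators and standard annotation
#'
#' Builds one contig per gene (alternating strands), places each gene so
#' that its -150..+25 promoter window lies fully inside the contig, and
#' plants the requested operator arrangements inside the windows of the
#' selected genes. Backgrounds (and the windows of unplanted genes) are
#' rejection-sampled to contain no spurious tandem-repeat run. Optionally
#' writes standard FASTA and GFF3.
#'
#' @param n_genes Number of genes.
#' @param planted Named list mapping gene ids (\code{"gene1"} ...) to
#'   arrangement specs (character vectors of \code{"DR"}/\code{"dr"}).
#' @param seed Integer seed.
#' @param gc Background GC content.
#' @param dir If non-NULL, directory into which \code{genome.fasta} and
#'   \code{genes.gff3} are written.
#' @param min_repeats,patterns Scanner settings used for the purity check.
#' @return list with \code{genome} (\code{DNAStringSet}), \code{features}
#'   (data frame as from \code{read_gff3}), \code{truth} (data frame
#'   \code{gene_id}, \code{planted}, \code{arrangement},
#'   \code{window_offset}) and \code{paths} (if written).
#' @export
gen_mini_genome <- function(n_genes, planted = list(), seed = 1L, gc = 0.68,
                            dir = NULL, min_repeats = 3L,
                            patterns = repeat_pattern_preset()) {
  gene_ids <- paste0("gene", seq_len(n_genes))
  if (!all(names(planted) %in% gene_ids))
    stop("planted gene ids must be among: ", paste(gene_ids, collapse = ", "))
  withr::with_seed(seed, {
    contig_len <- 700L
    contigs <- character(n_genes)
    feats <- vector("list", n_genes)
    truth <- vector("list", n_genes)
    for (i in seq_len(n_genes)) {
      gid <- gene_ids[i]
      strand <- if (i %% 2L == 1L) "+" else "-"
      labels <- if (gid %in% names(planted)) planted[[gid]] else character(0)
      w <- .gen_window(labels, gc, 175L, patterns, min_repeats)
      if (strand == "+") {
        gstart <- 301L; gend <- 600L
        ws <- gstart - 150L                       # window genomic 151..325
        win_genomic <- w$sequence
      } else {
        gstart <- 101L; gend <- 400L
        ws <- gend - 24L                          # window genomic 376..550
        win_genomic <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(w$sequence)))
      }
      bg <- .random_dna(contig_len, gc)
      contig <- paste0(substr(bg, 1L, ws - 1L), win_genomic,
                       substr(bg, ws + 175L, contig_len))
      contigs[i] <- contig
      feats[[i]] <- data.frame(contig_id = paste0("contig", i),
                               start = gstart, end = gend, strand = strand,
                               gene_id = gid, type = "gene",
                               stringsAsFactors = FALSE)
      truth[[i]] <- data.frame(
        gene_id = gid, planted = length(labels) >= min_repeats,
        arrangement = if (length(labels) >= min_repeats)
          paste0(labels, seq_along(labels), collapse = "-") else NA_character_,
        window_offset = if (length(labels) > 0L) w$offset else NA_integer_,
        stringsAsFactors = FALSE)
    }
    genome <- Biostrings::DNAStringSet(contigs)
    names(genome) <- paste0("contig", seq_len(n_genes))
    features <- do.call(rbind, feats)
    truth <- do.call(rbind, truth)
    # ground-truth closure: the scanner must recover exactly the plants
    rep_ <- scan_genome(genome, features, patterns, min_repeats)
    hit <- rep_[rep_$n_repeats > 0L, , drop = FALSE]
    if (!setequal(hit$gene_id, truth$gene_id[truth$planted]))
      stop("internal error: scan does not recover the planted operators")
    paths <- NULL
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      fasta <- file.path(dir, "genome.fasta")
      gff <- file.path(dir, "genes.gff3")
      write_fasta(genome, fasta)
      gr <- GenomicRanges::GRanges(
        seqnames = features$contig_id,
        ranges = IRanges::IRanges(features$start, features$end),
        strand = features$strand, type = features$type,
        ID = features$gene_id)
      rtracklayer::export(gr, gff, format = "GFF3")
      paths <- list(fasta = fasta, gff3 = gff)
    }
    list(genome = genome, features = features, truth = truth, paths = paths)
  })
}
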