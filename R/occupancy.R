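#' Repeat array of an EMSA probe
#'
#' Compact description of the 11-bp repeat layout of a binding probe:
#' which repeat units are intact and which carry disabling mutations.
#'
#' @param spec Either a character vector of \code{"intact"} /
#'   \code{"mutated"} or a compact string such as \code{"IIMI"} (I =
#'   intact, M = mutated).
#' @return Object of class \code{repeat_array}: logical vector
#'   \code{intact} per unit.
#' @export
repeat_array <- function(spec) {
  if (length(spec) == 1L && !spec[1] %in% c("intact", "mutated")) {
    units <- strsplit(toupper(spec), "")[[1]]
    if (!all(units %in% c("I", "M")))
      stop("compact repeat-array string may only contain I and M")
    intact <- units == "I"
  } else {
    if (!all(spec %in% c("intact", "mutated")))
      stop("units must be 'intact' or 'mutated'")
    intact <- spec == "intact"
  }
  if (length(intact) < 1L) stop("repeat array must have at least one unit")
  structure(list(intact = intact, length = length(intact)),
            class = "repeat_array")
}

#' Enumerate dimer occupancy configurations on a repeat array
#'
#' Each repressor dimer engages DNA with its two DNA-binding domains, one
#' per 11-bp repeat, so a "full" placement occupies two adjacent intact
#' repeats. Optionally a dimer may engage a single intact repeat with one
#' DBD ("partial" placement); partial placements explain the weak upper
#' band on three-repeat probes but never count as stable full engagement.
#'
#' @param array A \code{repeat_array}.
#' @param max_dimers Maximum number of placed dimers.
#' @param allow_partial Allow single-repeat placements (default
#'   \code{FALSE}).
#' @return list of configurations; each is a data frame with columns
#'   \code{start} (first engaged repeat, 1-based) and \code{size} (repeats
#'   engaged, 1 or 2). Only non-empty configurations are returned.
#' @export
enumerate_occupancy <- function(array, max_dimers, allow_partial = FALSE) {
  if (max_dimers < 1L) stop("max_dimers must be >= 1")
  intact <- array$intact
  n <- array$length
  placements <- list()
  for (s in seq_len(n)) {
    if (s < n && intact[s] && intact[s + 1L])
      placements[[length(placements) + 1L]] <- c(start = s, size = 2L)
    if (allow_partial && intact[s])
      placements[[length(placements) + 1L]] <- c(start = s, size = 1L)
  }
  configs <- list()
  recurse <- function(chosen, from) {
    if (length(chosen) > 0L) {
      df <- as.data.frame(do.call(rbind, chosen))
      configs[[length(configs) + 1L]] <<- df
    }
    if (length(chosen) >= max_dimers) return()
    for (k in seq_along(placements)) {
      if (k < from) next
      p <- placements[[k]]
      span <- p["start"]:(p["start"] + p["size"] - 1L)
      occupied <- unlist(lapply(chosen, function(q)
        q["start"]:(q["start"] + q["size"] - 1L)))
      if (length(intersect(span, occupied)) == 0L)
        recurse(c(chosen, list(p)), k + 1L)
    }
  }
  recurse(list(), 1L)
  configs
}

#' Predict the EMSA band category of a repeat-array probe
#'
#' Band categories reflect the maximum stable dimer load of the probe:
#' \code{"double"} if two full dimers can bind simultaneously (requires at
#' least four engageable repeats, e.g. two tandem pairs),
#' \code{"single_plus_weak_upper"} if exactly one full dimer fits but a
#' partial single-DBD placement can join it (three contiguous intact
#' repeats), \code{"single"} if exactly one full dimer and no partial
#' extension, and \code{"none"} if no two adjacent intact repeats exist
#' (a dimer requires its two repeats in tandem).
#'
#' @param array A \code{repeat_array}.
#' @return list with \code{category} and \code{max_full_dimers}.
#' @export
predict_bands <- function(array) {
  full <- enumerate_occupancy(array, max_dimers = array$length,
                              allow_partial = FALSE)
  max_full <- if (length(full) == 0L) 0L else
    max(vapply(full, nrow, 0L))
  category <- if (max_full >= 2L) "double"
  else if (max_full == 0L) "none"
  else {
    mixed <- enumerate_occupancy(array, max_dimers = array$length,
                                 allow_partial = TRUE)
    extendable <- any(vapply(mixed, function(cfg)
      sum(cfg$size == 2L) == 1L && any(cfg$size == 1L), logical(1)))
    if (extendable) "single_plus_weak_upper" else "single"
  }
  list(category = category, max_full_dimers = max_full)
}

#' Predict footprint geometry for an occupancy configuration
#'
#' Maps an occupancy configuration onto probe coordinates (repeat i spans
#' bases (i-1)*11+1 .. i*11, 1-based): one short hydroxyl-radical
#' protection tract per engaged repeat per strand, centred in the repeat
#' and spaced 11 nt apart for adjacent engaged repeats (one helical turn
#' of B-DNA, binding to one face); a DNase I protection span covering the
#' engaged repeats expanded by a margin; and exonuclease III arrest
#' offsets just outside the engaged region (downstream of its 3' edge on
#' the sense strand, upstream of its 5' edge on the antisense strand).
#'
#' @param array A \code{repeat_array}.
#' @param config One configuration from \code{enumerate_occupancy}.
#' @param tract_width Hydroxyl-radical tract width in nt (default 3;
#'   observed tracts are 2-3 nt).
#' @param dnase_margin DNase span margin in nt each side (default 4).
#' @param exo3_sense_offset Sense-strand Exo III stop, nt downstream of
#'   the 3' edge (default +4).
#' @param exo3_antisense_offset Antisense-strand stop, nt upstream of the
#'   5' edge (default 3; the midpoint of the observed 2-4 nt range).
#' @return list with \code{oh_tracts} (data frame \code{strand},
#'   \code{repeat_index}, \code{start}, \code{end}, \code{center}),
#'   \code{dnase_span} (c(start, end)), \code{exo3_sense_stop},
#'   \code{exo3_antisense_stop}.
#' @export
predict_footprints <- function(array, config, tract_width = 3L,
                               dnase_margin = 4L, exo3_sense_offset = 4L,
                               exo3_antisense_offset = 3L) {
  engaged <- sort(unique(unlist(lapply(seq_len(nrow(config)), function(i)
    config$start[i]:(config$start[i] + config$size[i] - 1L)))))
  if (any(engaged < 1L | engaged > array$length))
    stop("configuration engages repeats outside the array")
  if (any(!array$intact[engaged]))
    stop("configuration engages mutated repeats")
  centers <- (engaged - 1L) * 11L + 6L
  half <- (tract_width - 1L) %/% 2L
  tract <- data.frame(repeat_index = engaged,
                      start = centers - half,
                      end = centers - half + tract_width - 1L,
                      center = centers)
  oh <- rbind(cbind(strand = "sense", tract),
              cbind(strand = "antisense", tract))
  left <- (min(engaged) - 1L) * 11L + 1L
  right <- max(engaged) * 11L
  list(oh_tracts = oh,
       dnase_span = c(left - dnase_margin, right + dnase_margin),
       exo3_sense_stop = right + exo3_sense_offset,
       exo3_antisense_stop = left - exo3_antisense_offset)
}
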