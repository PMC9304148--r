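#' Relative expression by the comparative Cq (2^-ddCq) method
#'
#' Normalises target quantification cycles against a reference gene
#' (e.g. rpoD) per sample, then against the mean delta-Cq of a baseline
#' condition (e.g. dark with vitamin B12 present): fold change =
#' 2^-(dCq_sample - mean dCq_baseline). Mean fold change and its standard
#' error over replicates are reported per condition.
#'
#' @param table data frame with columns \code{condition},
#'   \code{target_cq} and \code{reference_cq} (one row per replicate).
#' @param baseline Baseline condition label; must occur in
#'   \code{table$condition}.
#' @return data frame with one row per condition: \code{condition},
#'   \code{n}, \code{mean_fold}, \code{se_fold}.
#' @export
relative_expression <- function(table, baseline) {
  need <- c("condition", "target_cq", "reference_cq")
  if (!all(need %in% names(table)))
    stop("table must have columns: ", paste(need, collapse = ", "))
  if (!baseline %in% table$condition)
    stop("baseline condition '", baseline, "' not present in table")
  if (any(is.na(table$reference_cq)))
    stop("missing reference Cq value(s)")
  dcq <- table$target_cq - table$reference_cq
  base_dcq <- mean(dcq[table$condition == baseline])
  fold <- 2^(-(dcq - base_dcq))
  conds <- unique(table$condition)
  out <- do.call(rbind, lapply(conds, function(cc) {
    f <- fold[table$condition == cc]
    data.frame(condition = cc, n = length(f), mean_fold = mean(f),
               se_fold = if (length(f) > 1) stats::sd(f) / sqrt(length(f)) else 0,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
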