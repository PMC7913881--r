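#' Relative RNA amount from threshold cycles
#'
#' Relative amount of a transcript against the reference gene measured in
#' the same sample: efficiency^(Ct_ref - Ct_gene). With perfect
#' amplification (efficiency 2) each cycle of difference is a factor of two.
#'
#' @param ct_gene threshold cycle(s) of the gene of interest.
#' @param ct_ref threshold cycle(s) of the reference gene (16S here).
#' @param efficiency amplification factor per cycle, in (1, 2].
#' @return dimensionless relative amount(s).
#' @export
#' @examples
#' relative_amount(28, 18)  # 2^-10
relative_amount <- function(ct_gene, ct_ref, efficiency = 2) {
  if (any(efficiency <= 1) || any(efficiency > 2))
    stop("efficiency must be in (1, 2]", call. = FALSE)
  efficiency^(ct_ref - ct_gene)
}

validate_ct_table <- function(table, reference, baseline) {
  need <- c("gene", "condition", "replicate", "ct")
  if (!all(need %in% names(table)))
    stop("Ct table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!reference %in% table$gene)
    stop("reference gene '", reference, "' missing from table",
         call. = FALSE)
  finite <- table$ct[!is.na(table$ct)]
  if (any(!is.finite(finite)))
    stop("Ct values must be finite or NA (undetected)", call. = FALSE)
  invisible(table)
}

# per gene x condition mean Ct (NA if undetected in any replicate kept as
# NA only when all are NA)
mean_ct <- function(table, gene, condition) {
  ct <- table$ct[table$gene == gene & table$condition == condition]
  if (length(ct) == 0) return(NULL)
  if (all(is.na(ct))) return(NA_real_)
  mean(ct, na.rm = TRUE)
}

#' Replicate summary of a Ct table
#'
#' Averages on the Ct scale and transforms (geometric-mean semantics on
#' amounts, matching how triplicate runs are usually reported); dispersion
#' is the SD of the per-replicate amounts, `NA` for single replicates.
#' Genes undetected in every replicate of a condition (all-`NA` Ct) are
#' reported with amount 0 and `detected = FALSE` rather than an imputed Ct.
#'
#' @param table long-format Ct data.frame: columns `gene`, `condition`,
#'   `replicate`, `ct` (`NA` = undetected).
#' @param reference reference gene (default `"16S"`).
#' @param efficiency per-cycle amplification factor.
#' @return data.frame with one row per gene x condition: `mean_amount`,
#'   `sd_amount`, `n`, `detected`.
#' @export
summarize_replicates <- function(table, reference = "16S", efficiency = 2) {
  validate_ct_table(table, reference, baseline = NULL)
  combos <- unique(table[table$gene != reference, c("gene", "condition")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    g <- combos$gene[i]; cond <- combos$condition[i]
    ct <- table$ct[table$gene == g & table$condition == cond]
    ref <- mean_ct(table, reference, cond)
    if (is.null(ref) || is.na(ref))
      stop("no reference measurement for condition '", cond, "'",
           call. = FALSE)
    n <- length(ct)
    if (all(is.na(ct)))
      return(data.frame(gene = g, condition = cond, mean_amount = 0,
                        sd_amount = NA_real_, n = n, detected = FALSE))
    amounts <- relative_amount(ct[!is.na(ct)], ref, efficiency)
    data.frame(gene = g, condition = cond,
               mean_amount = relative_amount(mean(ct, na.rm = TRUE), ref,
                                             efficiency),
               sd_amount = if (length(amounts) > 1) stats::sd(amounts)
               else NA_real_,
               n = n, detected = TRUE)
  })
  do.call(rbind, rows)
}

#' Fold change of a gene in a condition versus baseline
#'
#' Ratio of replicate-mean relative amounts, condition over baseline;
#' since averaging is done on the Ct scale this equals
#' efficiency^(-delta-delta-Ct) computed on Ct means. A gene undetected in
#' the condition gives fold 0; undetected in the baseline gives `Inf`
#' with a warning (no finite fold exists).
#'
#' @param table long-format Ct data.frame (see [summarize_replicates()]).
#' @param gene gene of interest.
#' @param condition induced condition.
#' @param baseline baseline condition (default `"glucose"`).
#' @param reference reference gene (default `"16S"`).
#' @param efficiency per-cycle amplification factor.
#' @return scalar fold change.
#' @export
fold_change <- function(table, gene, condition, baseline = "glucose",
                        reference = "16S", efficiency = 2) {
  validate_ct_table(table, reference, baseline)
  for (cond in c(condition, baseline)) {
    if (!any(table$gene == gene & table$condition == cond))
      stop("gene '", gene, "' has no data in condition '", cond, "'",
           call. = FALSE)
  }
  s <- summarize_replicates(
    table[table$gene %in% c(gene, reference), , drop = FALSE],
    reference = reference, efficiency = efficiency)
  num <- s[s$gene == gene & s$condition == condition, ]
  den <- s[s$gene == gene & s$condition == baseline, ]
  if (!den$detected) {
    if (!num$detected) return(NaN)
    warning("gene undetected at baseline; fold change is unbounded")
    return(Inf)
  }
  num$mean_amount / den$mean_amount
}
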