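#' Per-analyte differential statistics (Welch t-test + BH FDR)
#'
#' Computes, for every analyte carrying replicate intensities for both
#' groups, a two-sample unequal-variance (Welch) t-test between treated
#' and control replicates, re-derives `log2fc` as the difference of group
#' means, and adjusts p-values with Benjamini-Hochberg across all tested
#' analytes of the table.  Records are called significant when
#' `fdr < fdr_threshold`.
#'
#' Degenerate inputs follow two conventions chosen for rank stability:
#' zero variance in both groups gives p = 1 when the means are equal
#' (no evidence of change, not `NaN`) and p = 0 when they differ;
#' analytes with fewer than two replicates in either group are skipped
#' with a warning and keep `NA` p/fdr.
#'
#' @param table A [measurement_table()] with `reps_control` and
#'   `reps_treated` list columns.
#' @param fdr_threshold Significance threshold on the BH FDR, in (0,1).
#'   Default 0.1, the conventional cut for differential omics abundance
#'   at this depth.
#' @return The table with `log2fc`, `p_value`, `fdr`, `significant`
#'   filled in.
#' @export
differential_stats <- function(table, fdr_threshold = 0.1) {
  stopifnot(inherits(table, "measurement_table"))
  if (!is.numeric(fdr_threshold) || fdr_threshold <= 0 || fdr_threshold >= 1) {
    sc_abort("fdr_threshold must be in (0,1)")
  }
  if (!all(c("reps_control", "reps_treated") %in% names(table))) {
    sc_abort("differential_stats needs replicate values for both groups")
  }
  ctrl <- lapply(table$reps_control, function(v) v[!is.na(v)])
  trt <- lapply(table$reps_treated, function(v) v[!is.na(v)])
  n1 <- lengths(ctrl)
  n2 <- lengths(trt)
  testable <- n1 >= 2 & n2 >= 2
  if (any(!testable)) {
    warning(sprintf("%d analyte(s) skipped: fewer than 2 replicates in a group",
                    sum(!testable)), call. = FALSE)
  }
  p <- rep(NA_real_, nrow(table))
  lfc <- table$log2fc
  if (any(testable)) {
    m1 <- vapply(ctrl[testable], mean, 1)
    m2 <- vapply(trt[testable], mean, 1)
    v1 <- vapply(ctrl[testable], function(v) stats::var(v), 1)
    v2 <- vapply(trt[testable], function(v) stats::var(v), 1)
    se2 <- v1 / n1[testable] + v2 / n2[testable]
    pv <- ifelse(se2 == 0,
                 ifelse(m1 == m2, 1, 0),
                 {
                   tt <- (m2 - m1) / sqrt(se2)
                   df <- se2^2 / ((v1 / n1[testable])^2 / (n1[testable] - 1) +
                                    (v2 / n2[testable])^2 / (n2[testable] - 1))
                   2 * pt(-abs(tt), df)
                 })
    p[testable] <- pv
    lfc[testable] <- m2 - m1
  }
  table$log2fc <- lfc
  table$p_value <- p
  table$fdr <- NA_real_
  table$fdr[testable] <- p.adjust(p[testable], method = "BH")
  table$significant <- !is.na(table$fdr) & table$fdr < fdr_threshold
  table$flags <- ifelse(testable, table$flags, "insufficient-replicates")
  table
}

#' Correct phosphosite fold-changes for host-protein abundance
#'
#' A phosphosite can change in apparent abundance simply because its host
#' protein does.  For every site whose host protein is quantified in the
#' protein table, the corrected fold-change is
#' `site log2fc - host protein log2fc`; sites without a quantified host
#' pass through unchanged and are flagged `"uncorrected"`.  Record order
#' is preserved.
#'
#' @param phospho Phosphosite-layer [measurement_table()].
#' @param protein Protein-layer [measurement_table()].
#' @return The phosphosite table with corrected `log2fc` and an
#'   `uncorrected` flag on pass-through sites.
#' @export
normalize_phospho_by_protein <- function(phospho, protein) {
  stopifnot(inherits(phospho, "measurement_table"),
            inherits(protein, "measurement_table"))
  if (mt_layer(phospho) != "phosphosite" || mt_layer(protein) != "protein") {
    sc_abort("normalize_phospho_by_protein needs a phosphosite and a protein table")
  }
  idx <- match(phospho$host_protein, protein$analyte_id)
  has_host <- !is.na(idx)
  phospho$log2fc <- ifelse(has_host,
                           phospho$log2fc - protein$log2fc[idx],
                           phospho$log2fc)
  phospho$flags <- ifelse(has_host, phospho$flags,
                          paste_flag(phospho$flags, "uncorrected"))
  sc_log("phospho normalization: %d site(s) corrected, %d without quantified host",
         sum(has_host), sum(!has_host))
  phospho
}

paste_flag <- function(flags, new) {
  ifelse(is.na(flags) | flags == "", new, paste(flags, new, sep = ";"))
}
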