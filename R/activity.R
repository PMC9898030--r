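#' @title Activity inference from differential measurements
#' @description Internal machinery shared by the footprint statistic and
#'   the regulatory-site score: a signed enrichment statistic compared to
#'   a permutation null built by re-drawing target labels from the
#'   measurement table.
#' @noRd
perm_null <- function(pool, signs, n_perm, statistic) {
  n <- length(signs)
  vapply(seq_len(n_perm), function(i) {
    statistic(pool[sample.int(length(pool), n)], signs)
  }, numeric(1))
}

activity_row <- function(protein, role, method, score = NA_real_, z = NA_real_,
                         p_value = NA_real_, n_evidence = 0L, flags = NA_character_) {
  tibble::tibble(protein = protein, role = role, score = score, z = z,
                 p_value = p_value, fdr = NA_real_, method = method,
                 n_evidence = as.integer(n_evidence), significant = NA,
                 discordant = FALSE, flags = flags)
}

#' Footprint activity of one regulator
#'
#' Estimates the signed activity change of a regulator from the
#' differential abundance of its regulon targets.  The raw statistic is
#' `sum(sign_t * log2fc_t) / sqrt(n)` over the `n` regulon targets
#' quantified in the measurement table; a positive value means the
#' regulator's known program moved in its activating direction.  The null
#' distribution is built by `n_perm` permutations of target labels (the
#' same signs applied to randomly drawn analytes of the table); `z`
#' standardizes the raw score against this null and the two-sided
#' p-value is the empirical tail probability with the +1 correction.
#'
#' @param regulon Rows of a [build_regulons()] table for one regulator.
#' @param measurements A [measurement_table()] of the matching layer.
#' @param n_perm Number of label permutations (>= 100).
#' @param seed Integer seed for the permutation stream (mandatory).
#' @param min_targets Minimum quantified targets to emit a score.
#' @return One-row activity tibble (`method = "footprint"`); when fewer
#'   than `min_targets` targets are quantified the row is flagged
#'   `insufficient-evidence` and carries no score.
#' @export
footprint_activity <- function(regulon, measurements, n_perm = 1000, seed,
                               min_targets = 3) {
  stopifnot(n_perm >= 100)
  regulator <- unique(regulon$regulator)
  stopifnot(length(regulator) == 1)
  role <- regulon$role[1]
  idx <- match(regulon$target, measurements$analyte_id)
  hit <- !is.na(idx)
  n <- sum(hit)
  if (n < min_targets) {
    return(activity_row(regulator, role, "footprint",
                        n_evidence = n, flags = "insufficient-evidence"))
  }
  lfc <- measurements$log2fc[idx[hit]]
  signs <- regulon$sign[hit]
  stat <- function(values, s) sum(s * values) / sqrt(length(s))
  raw <- stat(lfc, signs)
  withr::with_seed(seed, {
    null <- perm_null(measurements$log2fc, signs, n_perm, stat)
  })
  z <- (raw - mean(null)) / sd(null)
  p <- (1 + sum(abs(null) >= abs(raw))) / (n_perm + 1)
  activity_row(regulator, role, "footprint", score = raw, z = z, p_value = p,
               n_evidence = n)
}

#' Regulatory-site activity score of one protein
#'
#' Estimates a protein's activity change from the fold-changes of its own
#' annotated regulatory phosphosites: the score is the mean over
#' quantified sites of `effect * log2fc`, so a rising activating site or
#' a falling inhibitory site both push the score positive.  The classic
#' example is the inhibitory Tyr15 of CDK1 -- hyperphosphorylation there
#' yields a negative activity score.  `z` and the p-value come from the
#' same permutation machinery as the footprint statistic, drawing site
#' labels from the phosphosite table.
#'
#' @param protein Protein identifier.
#' @param sites Regulatory-site tibble (`protein`, `residue`, `effect`),
#'   e.g. `kb$sites`; only rows for `protein` are used.
#' @param phospho Phosphosite-layer [measurement_table()] (typically
#'   protein-normalized).
#' @param n_perm,seed,min_sites Permutation and evidence controls.
#' @return One-row activity tibble (`method = "phosphoscore"`).
#' @export
phospho_score <- function(protein, sites, phospho, n_perm = 1000, seed,
                          min_sites = 1) {
  role <- "other"
  mine <- sites[sites$protein == protein, , drop = FALSE]
  keys <- paste0(mine$protein, "_", mine$residue)
  idx <- match(keys, phospho$analyte_id)
  hit <- !is.na(idx)
  n <- sum(hit)
  if (n < min_sites) {
    return(activity_row(protein, role, "phosphoscore",
                        n_evidence = n, flags = "insufficient-evidence"))
  }
  lfc <- phospho$log2fc[idx[hit]]
  effects <- mine$effect[hit]
  stat <- function(values, s) mean(s * values)
  raw <- stat(lfc, effects)
  withr::with_seed(seed, {
    null <- perm_null(phospho$log2fc, effects, n_perm, stat)
  })
  z <- (raw - mean(null)) / sd(null)
  p <- (1 + sum(abs(null) >= abs(raw))) / (n_perm + 1)
  activity_row(protein, role, "phosphoscore", score = raw, z = z, p_value = p,
               n_evidence = n)
}

#' Combine a footprint and a regulatory-site activity estimate
#'
#' When both methods scored the same protein, the combined `z` is the
#' plain average of the two z-scores and the combined raw score the mean
#' of the raw scores; evidence counts add.  Estimates with opposite
#' z signs are flagged `discordant` (downstream network optimization
#' excludes them by default).  If only one estimate exists it passes
#' through unchanged.  Combination is commutative.
#'
#' @param a,b One-row activity tibbles for the same protein produced by
#'   different methods (either may be `NULL` or an unscored row).
#' @return One-row activity tibble (`method = "combined"` or the
#'   surviving single method).
#' @export
combine_activities <- function(a, b) {
  scored <- function(x) !is.null(x) && nrow(x) == 1 && !is.na(x$z)
  if (!scored(a) && !scored(b)) return(if (is.null(a)) b else a)
  if (!scored(a)) return(b)
  if (!scored(b)) return(a)
  if (a$protein != b$protein) sc_abort("combine_activities: different proteins")
  if (a$method == b$method) sc_abort("combine_activities: same-method pair")
  role <- if (a$role != "other") a$role else b$role
  out <- activity_row(a$protein, role, "combined",
                      score = (a$score + b$score) / 2,
                      z = (a$z + b$z) / 2,
                      p_value = 2 * pnorm(-abs(a$z + b$z) / sqrt(2)),
                      n_evidence = a$n_evidence + b$n_evidence)
  if (sign(a$z) * sign(b$z) < 0) {
    out$discordant <- TRUE
    out$flags <- "discordant"
  }
  out
}

#' Infer activities for every eligible protein in the knowledge base
#'
#' Runs the full step-1 inference: transcription factors are scored by
#' footprint over the transcriptome; kinases and phosphatases by
#' footprint over the (protein-normalized) phosphoproteome *and* by the
#' regulatory-site score, the two being combined; remaining proteins
#' with quantified regulatory sites (substrates) get a site score alone.
#' p-values are BH-adjusted across all scored proteins and significance
#' called at `fdr < fdr_threshold`.
#'
#' @param kb A [causal_kb()].
#' @param transcriptome,proteome,phospho [measurement_table()]s; `proteome`
#'   and `phospho` may be `NULL`, in which case the corresponding scores
#'   are skipped (kinases are then flagged insufficient-evidence).
#' @param n_perm,seed,min_targets Permutation and regulon controls.
#' @param fdr_threshold Activity-significance FDR (default 0.05).
#' @param normalize Subtract host-protein fold-changes from phosphosites
#'   before kinase scoring (default TRUE when a proteome is supplied).
#' @return Tibble of class `activity_table`, one row per scored protein.
#' @export
activity_table <- function(kb, transcriptome = NULL, proteome = NULL,
                           phospho = NULL, n_perm = 1000, seed,
                           min_targets = 3, fdr_threshold = 0.05,
                           normalize = TRUE) {
  regs <- build_regulons(kb, min_targets = min_targets)
  if (!is.null(phospho) && !is.null(proteome) && normalize) {
    phospho <- normalize_phospho_by_protein(phospho, proteome)
  }
  rows <- list()
  split_regs <- split(tibble::as_tibble(regs), regs$regulator)
  seeds <- seed + seq_along(split_regs)  # one reproducible stream per regulon
  names(seeds) <- names(split_regs)

  for (nm in names(split_regs)) {
    r <- split_regs[[nm]]
    if (r$role[1] == "TF") {
      if (is.null(transcriptome)) next
      rows[[length(rows) + 1L]] <-
        footprint_activity(r, transcriptome, n_perm = n_perm,
                           seed = seeds[[nm]], min_targets = min_targets)
    } else {
      fp <- if (is.null(phospho)) {
        activity_row(nm, r$role[1], "footprint", flags = "insufficient-evidence")
      } else {
        footprint_activity(r, phospho, n_perm = n_perm, seed = seeds[[nm]],
                           min_targets = min_targets)
      }
      ps <- if (is.null(phospho)) NULL else {
        phospho_score(nm, kb$sites, phospho, n_perm = n_perm,
                      seed = seeds[[nm]] + 1L)
      }
      if (!is.null(ps)) ps$role <- r$role[1]
      rows[[length(rows) + 1L]] <- combine_activities(fp, ps)
    }
  }
  # substrates: site-annotated proteins without a regulon of their own
  site_prots <- setdiff(unique(kb$sites$protein), names(split_regs))
  site_prots <- site_prots[kb_role(kb, site_prots) %in% c("other", "kinase", "phosphatase")]
  if (!is.null(phospho)) {
    for (i in seq_along(site_prots)) {
      p <- site_prots[i]
      row <- phospho_score(p, kb$sites, phospho, n_perm = n_perm,
                           seed = seed + 100000L + i)
      row$role <- kb_role(kb, p)
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) sc_abort("no protein could be scored")
  tested <- !is.na(out$p_value)
  out$fdr[tested] <- p.adjust(out$p_value[tested], method = "BH")
  out$significant <- !is.na(out$fdr) & out$fdr < fdr_threshold
  structure(out, class = c("activity_table", class(tibble::tibble())))
}

#' Compare two activity profiles across conditions
#'
#' Pearson correlation of the z-scores over proteins scored in both
#' conditions, plus the two discordance lists that matter when
#' contrasting conditions: proteins significant in exactly one condition
#' and proteins significant in both with opposite signs.
#'
#' @param a,b `activity_table` tibbles from two conditions.
#' @return List of class `activity_comparison` with elements `r`,
#'   `n_shared`, `exclusive_a`, `exclusive_b`, `opposite`.
#' @export
compare_activity_profiles <- function(a, b) {
  shared <- dplyr::inner_join(
    tibble::as_tibble(a)[!is.na(a$z), c("protein", "z", "significant")],
    tibble::as_tibble(b)[!is.na(b$z), c("protein", "z", "significant")],
    by = "protein", suffix = c("_a", "_b"))
  if (nrow(shared) < 3) sc_abort("fewer than 3 shared scored proteins")
  r <- cor(shared$z_a, shared$z_b)
  opposite <- shared$protein[shared$significant_a & shared$significant_b &
                               sign(shared$z_a) * sign(shared$z_b) < 0]
  only_a <- shared$protein[shared$significant_a & !shared$significant_b]
  only_b <- shared$protein[shared$significant_b & !shared$significant_a]
  structure(list(r = r, n_shared = nrow(shared), exclusive_a = only_a,
                 exclusive_b = only_b, opposite = opposite, shared = shared),
            class = "activity_comparison")
}

#' @export
print.activity_comparison <- function(x, ...) {
  cat(sprintf("<activity_comparison> R = %.3f over %d shared proteins\n",
              x$r, x$n_shared))
  cat(sprintf("  opposite significant signs: %s\n",
              if (length(x$opposite)) paste(x$opposite, collapse = ", ") else "none"))
  cat(sprintf("  exclusive to a: %d, exclusive to b: %d\n",
              length(x$exclusive_a), length(x$exclusive_b)))
  invisible(x)
}
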