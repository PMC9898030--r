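#' Build signed regulons from a causal knowledge base
#'
#' A regulon is a regulator together with its signed target set, the input
#' of footprint activity inference.  Transcription-factor regulons come
#' from transcriptional edges and carry the edge's activity sign directly,
#' their targets being transcript identifiers.  Kinase and phosphatase
#' regulons come from (de)phosphorylation edges that name a residue; their
#' targets are phosphosite keys `"<TARGET>_<RESIDUE>"` and their sign is
#' the direction of the phospho event itself -- `+1` for phosphorylation,
#' `-1` for dephosphorylation -- because the footprint statistic acts on
#' phosphosite abundance, not on downstream activity (the site's
#' activating/inhibiting role is consumed separately by the
#' regulatory-site score).  Ambiguous-sign edges are excluded.
#'
#' @param kb A [causal_kb()].
#' @param min_targets Regulons with fewer targets are dropped (and
#'   counted in the log).
#' @param keep_ambiguous Retain edges flagged ambiguous (default FALSE).
#' @return A tibble of class `regulon_set` with columns `regulator`,
#'   `role`, `target`, `sign`, one row per regulon member.
#' @export
build_regulons <- function(kb, min_targets = 3, keep_ambiguous = FALSE) {
  stopifnot(min_targets >= 1)
  ed <- kb$edges
  if (!keep_ambiguous) ed <- ed[!ed$ambiguous, , drop = FALSE]
  role <- kb_role(kb, ed$source)

  tf <- ed[role == "TF" & ed$mechanism == "transcriptional", , drop = FALSE]
  tf_reg <- tibble::tibble(regulator = tf$source, role = "TF",
                           target = tf$target, sign = tf$sign)

  kin <- ed[role == "kinase" & ed$mechanism == "phosphorylation" &
              !is.na(ed$residue), , drop = FALSE]
  kin_reg <- tibble::tibble(regulator = kin$source, role = "kinase",
                            target = paste0(kin$target, "_", kin$residue),
                            sign = 1L)
  pho <- ed[role == "phosphatase" & ed$mechanism == "dephosphorylation" &
              !is.na(ed$residue), , drop = FALSE]
  pho_reg <- tibble::tibble(regulator = pho$source, role = "phosphatase",
                            target = paste0(pho$target, "_", pho$residue),
                            sign = -1L)

  reg <- dplyr::bind_rows(tf_reg, kin_reg, pho_reg)
  reg <- dplyr::distinct(reg)
  counts <- dplyr::count(reg, .data$regulator, name = "n_targets")
  small <- counts$regulator[counts$n_targets < min_targets]
  if (length(small) > 0) {
    sc_log("dropped %d regulon(s) with fewer than %d targets", length(small),
           min_targets)
    reg <- reg[!reg$regulator %in% small, , drop = FALSE]
  }
  structure(reg, class = c("regulon_set", class(tibble::tibble())))
}
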