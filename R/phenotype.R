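#' Read a phenotype-marker table
#'
#' TSV with columns `PROTEIN`, `PHENOTYPE` (`pro_survival`,
#' `pro_apoptotic` or `other`) and `ASSOCIATION_SIGN` (+1/-1), the sign
#' linking the marker's activity to the phenotype.  A reconstruction of
#' a typical text-mining derived apoptosis marker panel ships with the
#' package (see `system.file("extdata", "phenotype_markers.tsv",
#' package = "signalcarver")`).
#'
#' @param path TSV path.
#' @return Tibble with columns `protein`, `phenotype`,
#'   `association_sign`.
#' @export
read_phenotype_markers <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  out <- tibble::tibble(protein = raw$PROTEIN,
                        phenotype = raw$PHENOTYPE,
                        association_sign = as.integer(raw$ASSOCIATION_SIGN))
  if (!all(out$phenotype %in% c("pro_survival", "pro_apoptotic", "other"))) {
    sc_abort("unknown phenotype label in %s", path)
  }
  if (!all(out$association_sign %in% c(-1L, 1L))) {
    sc_abort("association_sign must be +1 or -1")
  }
  out
}

#' Predict phenotype-marker activity from an optimized model
#'
#' Step-4 in-silico readout: each marker protein receives the one-hop
#' signed mean of the model states of its upstream regulators, i.e. over
#' all knowledge-base edges `u -> marker` with `u` in the model and
#' `state(u) != 0`, `marker score = mean(state(u) * sign(u -> marker))`.
#' Scores are therefore bounded in \[-1, +1\].  Per-phenotype scores sum
#' `marker score * association_sign` over its predicted markers.
#' Markers with no upstream model regulator are flagged unpredictable.
#'
#' @param model Optimized [causal_network()].
#' @param kb The [causal_kb()] supplying upstream edges.
#' @param markers Marker tibble (see [read_phenotype_markers()]).
#' @return List of class `phenotype_report`: `marker_states` (tibble
#'   with `protein`, `phenotype`, `score`, `predictable`,
#'   `regulators` list column), `phenotype_scores` (tibble).
#' @export
score_markers <- function(model, kb, markers) {
  stopifnot(model$kind == "optimized", nrow(markers) > 0)
  st <- setNames(model$nodes$state, model$nodes$protein)
  ed <- kb$edges[!kb$edges$ambiguous, , drop = FALSE]
  rows <- lapply(seq_len(nrow(markers)), function(i) {
    m <- markers$protein[i]
    up <- ed[ed$target == m & ed$source %in% names(st), , drop = FALSE]
    up <- up[st[up$source] != 0L, , drop = FALSE]
    if (nrow(up) == 0) {
      return(tibble::tibble(protein = m, phenotype = markers$phenotype[i],
                            association_sign = markers$association_sign[i],
                            score = NA_real_, predictable = FALSE,
                            regulators = list(character(0))))
    }
    tibble::tibble(protein = m, phenotype = markers$phenotype[i],
                   association_sign = markers$association_sign[i],
                   score = mean(st[up$source] * up$sign),
                   predictable = TRUE,
                   regulators = list(unique(up$source)))
  })
  marker_states <- dplyr::bind_rows(rows)
  ph <- dplyr::summarise(
    dplyr::group_by(marker_states[marker_states$predictable, , drop = FALSE],
                    .data$phenotype),
    score = sum(.data$score * .data$association_sign), .groups = "drop")
  structure(list(marker_states = marker_states, phenotype_scores = ph),
            class = "phenotype_report")
}

#' @export
print.phenotype_report <- function(x, ...) {
  cat(sprintf("<phenotype_report> %d marker(s), %d predictable\n",
              nrow(x$marker_states), sum(x$marker_states$predictable)))
  for (i in seq_len(nrow(x$phenotype_scores))) {
    cat(sprintf("  %s: %.3f\n", x$phenotype_scores$phenotype[i],
                x$phenotype_scores$score[i]))
  }
  invisible(x)
}

#' Contrast two phenotype reports
#'
#' Per-marker and per-phenotype score differences `b - a` with
#' qualitative calls; markers unpredictable in either report are
#' excluded from the contrast and listed.
#'
#' @param a,b `phenotype_report`s over a shared marker set.
#' @return List of class `phenotype_contrast`: `markers` (tibble with
#'   `delta` and `call`), `phenotypes` (tibble), `excluded`.
#' @export
contrast_phenotypes <- function(a, b) {
  ma <- a$marker_states
  mb <- b$marker_states
  shared <- intersect(ma$protein, mb$protein)
  if (length(shared) == 0) sc_abort("disjoint marker sets")
  ma <- ma[match(shared, ma$protein), ]
  mb <- mb[match(shared, mb$protein), ]
  usable <- ma$predictable & mb$predictable
  excluded <- shared[!usable]
  delta <- mb$score[usable] - ma$score[usable]
  call <- ifelse(delta > 0, "higher", ifelse(delta < 0, "lower", "equal"))
  markers <- tibble::tibble(protein = shared[usable],
                            phenotype = ma$phenotype[usable],
                            score_a = ma$score[usable],
                            score_b = mb$score[usable],
                            delta = delta, call = call)
  ph <- dplyr::summarise(dplyr::group_by(markers, .data$phenotype),
                         delta = sum((.data$score_b - .data$score_a) *
                                       ma$association_sign[match(.data$protein,
                                                                 shared)]),
                         .groups = "drop")
  ph$call <- ifelse(ph$delta > 0, "higher", ifelse(ph$delta < 0, "lower", "equal"))
  structure(list(markers = markers, phenotypes = ph, excluded = excluded),
            class = "phenotype_contrast")
}
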