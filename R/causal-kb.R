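#' Signed causal-interaction knowledge base
#'
#' A `causal_kb` bundles the three flat-file snapshots of prior knowledge
#' the pipeline consumes: signed directed interactions between proteins
#' (and from transcription factors to transcripts), regulatory-phosphosite
#' annotations (which residue activates or inhibits its host protein), and
#' a role map assigning each protein to TF / kinase / phosphatase / other.
#'
#' Edge signs are activity-level effects: `+1` means the source
#' up-regulates the target's activity (or expression, for transcriptional
#' edges), `-1` the opposite.  Duplicate rows that agree in every field
#' collapse to one edge; edges between the same pair with conflicting
#' signs are both kept but flagged `ambiguous`, and ambiguous edges are
#' excluded from regulons and path search unless explicitly retained.
#'
#' @param edges Tibble with columns `source`, `target`, `sign` (+1/-1),
#'   `mechanism` (`phosphorylation`, `dephosphorylation`,
#'   `transcriptional`, `binding`, `other`), `residue` (site string on the
#'   target, only for (de)phosphorylation), `provenance`.
#' @param sites Tibble with columns `protein`, `residue`, `effect`
#'   (+1 activating / -1 inhibiting), `provenance`.
#' @param roles Tibble with columns `protein`, `role`.
#' @return An object of class `causal_kb`.
#' @export
causal_kb <- function(edges,
                      sites = NULL,
                      roles = NULL) {
  edges <- tibble::as_tibble(edges)
  for (col in c("residue", "provenance")) {
    if (!col %in% names(edges)) edges[[col]] <- NA_character_
  }
  if (!"mechanism" %in% names(edges)) edges$mechanism <- "other"
  edges$sign <- as.integer(edges$sign)
  if (!all(edges$sign %in% c(-1L, 1L))) sc_abort("edge sign must be +1 or -1")
  mech_ok <- edges$mechanism %in%
    c("phosphorylation", "dephosphorylation", "transcriptional", "binding", "other")
  if (!all(mech_ok)) {
    sc_abort("unknown mechanism: %s", paste(unique(edges$mechanism[!mech_ok]), collapse = ", "))
  }
  self <- edges$source == edges$target
  if (any(self & edges$mechanism != "other")) {
    sc_abort("self-loop only allowed with mechanism 'other'")
  }
  res_bad <- !is.na(edges$residue) &
    !edges$mechanism %in% c("phosphorylation", "dephosphorylation")
  if (any(res_bad)) sc_abort("residue only allowed on (de)phosphorylation edges")

  # dedup identical rows; conflicting-sign duplicates flagged ambiguous
  edges <- dplyr::distinct(edges, .data$source, .data$target, .data$sign,
                           .data$mechanism, .data$residue, .keep_all = TRUE)
  amb_pairs <- dplyr::summarise(
    dplyr::group_by(edges, .data$source, .data$target),
    ambiguous = dplyr::n_distinct(.data$sign) > 1, .groups = "drop")
  edges <- dplyr::left_join(edges, amb_pairs, by = c("source", "target"))

  sites <- tibble::as_tibble(sites %||%
    tibble::tibble(protein = character(), residue = character(),
                   effect = integer(), provenance = character()))
  if (!"provenance" %in% names(sites)) sites$provenance <- NA_character_
  sites$effect <- as.integer(sites$effect)
  if (!all(sites$effect %in% c(-1L, 1L))) sc_abort("site effect must be +1 or -1")
  if (anyDuplicated(sites[c("protein", "residue")]) > 0) {
    sc_abort("duplicate (protein, residue) in regulatory-site table")
  }

  prots <- unique(c(edges$source, edges$target))
  roles <- tibble::as_tibble(roles %||% tibble::tibble(protein = character(),
                                                       role = character()))
  role_ok <- roles$role %in% c("TF", "kinase", "phosphatase", "other")
  if (!all(role_ok)) sc_abort("role must be TF/kinase/phosphatase/other")
  missing_roles <- setdiff(prots, roles$protein)
  if (length(missing_roles) > 0) {
    roles <- dplyr::bind_rows(roles,
                              tibble::tibble(protein = missing_roles, role = "other"))
  }
  orphan <- !sites$protein %in% prots
  if (any(orphan)) {
    sc_log("%d regulatory site(s) on proteins absent from the edge set (kept, orphan)",
           sum(orphan))
  }
  structure(list(edges = edges, sites = sites, roles = roles),
            class = "causal_kb")
}

#' @export
print.causal_kb <- function(x, ...) {
  cat(sprintf("<causal_kb> %d edges (%d ambiguous), %d regulatory sites, %d proteins\n",
              nrow(x$edges), sum(x$edges$ambiguous), nrow(x$sites),
              nrow(x$roles)))
  invisible(x)
}

kb_proteins <- function(kb) {
  unique(c(kb$edges$source, kb$edges$target, kb$roles$protein))
}

kb_role <- function(kb, proteins) {
  out <- kb$roles$role[match(proteins, kb$roles$protein)]
  out[is.na(out)] <- "other"
  out
}

# igraph view of the edge set (multigraph; edge attr 'row' indexes kb$edges)
kb_igraph <- function(kb, exclude_ambiguous = TRUE) {
  ed <- kb$edges
  if (exclude_ambiguous) ed <- ed[!ed$ambiguous, , drop = FALSE]
  verts <- unique(c(ed$source, ed$target, kb_proteins(kb)))
  igraph::graph_from_data_frame(
    data.frame(from = ed$source, to = ed$target, sign = ed$sign,
               row = seq_len(nrow(ed)), stringsAsFactors = FALSE),
    directed = TRUE, vertices = verts)
}

#' Load a causal knowledge base from flat files
#'
#' Two dialects are supported.  `signor_tsv` expects columns `ENTITYA`,
#' `ENTITYB`, `EFFECT` (any token starting with `up-regulates` maps to
#' +1, `down-regulates` to -1), and optionally `MECHANISM`, `RESIDUE`,
#' `PROVENANCE`.  `sif` expects three whitespace-separated columns
#' `source relation target` with relation tokens `+1` / `-1`; mechanism
#' defaults to `other`.
#'
#' @param edges_path Path of the interaction file.
#' @param sites_path Optional path of the regulatory-site TSV
#'   (`PROTEIN`, `RESIDUE`, `EFFECT` with values `activating` /
#'   `inhibiting`, optional `PROVENANCE`).
#' @param roles_path Optional path of the role TSV (`PROTEIN`, `ROLE`).
#' @param dialect `"signor_tsv"` or `"sif"`.
#' @return A [causal_kb()].
#' @export
load_causal_kb <- function(edges_path, sites_path = NULL, roles_path = NULL,
                           dialect = c("signor_tsv", "sif")) {
  dialect <- match.arg(dialect)
  if (!file.exists(edges_path)) sc_abort("file not found: %s", edges_path)
  if (dialect == "signor_tsv") {
    raw <- readr::read_tsv(edges_path, show_col_types = FALSE, progress = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
    for (need in c("ENTITYA", "ENTITYB", "EFFECT")) {
      if (!need %in% names(raw)) sc_abort("missing column '%s' in %s", need, edges_path)
    }
    sign <- ifelse(startsWith(raw$EFFECT, "up-regulates"), 1L,
                   ifelse(startsWith(raw$EFFECT, "down-regulates"), -1L, NA_integer_))
    if (anyNA(sign)) {
      bad <- which(is.na(sign))[1]
      sc_abort("unknown EFFECT token '%s' at line %d of %s",
               raw$EFFECT[bad], bad + 1L, edges_path)
    }
    edges <- tibble::tibble(
      source = raw$ENTITYA, target = raw$ENTITYB, sign = sign,
      mechanism = if ("MECHANISM" %in% names(raw)) raw$MECHANISM else "other",
      residue = if ("RESIDUE" %in% names(raw)) raw$RESIDUE else NA_character_,
      provenance = if ("PROVENANCE" %in% names(raw)) raw$PROVENANCE else NA_character_)
    edges$mechanism[is.na(edges$mechanism)] <- "other"
  } else {
    lines <- readLines(edges_path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    parts <- stringr::str_split(trimws(lines), "\\s+")
    bad <- which(lengths(parts) != 3)
    if (length(bad) > 0) sc_abort("malformed SIF line %d in %s", bad[1], edges_path)
    rel <- vapply(parts, `[[`, "", 2)
    if (!all(rel %in% c("+1", "-1"))) {
      bad <- which(!rel %in% c("+1", "-1"))[1]
      sc_abort("unknown relation token '%s' at line %d of %s", rel[bad], bad, edges_path)
    }
    edges <- tibble::tibble(source = vapply(parts, `[[`, "", 1),
                            target = vapply(parts, `[[`, "", 3),
                            sign = as.integer(rel),
                            mechanism = "other",
                            residue = NA_character_,
                            provenance = NA_character_)
  }
  sites <- NULL
  if (!is.null(sites_path)) {
    sr <- readr::read_tsv(sites_path, show_col_types = FALSE, progress = FALSE,
                          col_types = readr::cols(.default = readr::col_character()))
    eff <- ifelse(sr$EFFECT == "activating", 1L,
                  ifelse(sr$EFFECT == "inhibiting", -1L, NA_integer_))
    if (anyNA(eff)) {
      bad <- which(is.na(eff))[1]
      sc_abort("unknown EFFECT token '%s' at line %d of %s", sr$EFFECT[bad],
               bad + 1L, sites_path)
    }
    sites <- tibble::tibble(protein = sr$PROTEIN, residue = sr$RESIDUE,
                            effect = eff,
                            provenance = if ("PROVENANCE" %in% names(sr))
                              sr$PROVENANCE else NA_character_)
  }
  roles <- NULL
  if (!is.null(roles_path)) {
    rr <- readr::read_tsv(roles_path, show_col_types = FALSE, progress = FALSE,
                          col_types = readr::cols(.default = readr::col_character()))
    roles <- tibble::tibble(protein = rr$PROTEIN, role = rr$ROLE)
  }
  kb <- causal_kb(edges, sites, roles)
  sc_log("loaded %d edge(s) (%d ambiguous), %d site(s), %d role(s) from %s",
         nrow(kb$edges), sum(kb$edges$ambiguous), nrow(kb$sites),
         nrow(kb$roles), edges_path)
  kb
}

#' Serialize a causal knowledge base to canonical TSV files
#'
#' Writes the edge set in the `signor_tsv` dialect plus the site and role
#' tables.  `load_causal_kb()` on the written files reproduces the KB
#' (load -> write -> load is a fixed point).
#'
#' @param kb A [causal_kb()].
#' @param edges_path,sites_path,roles_path Output paths.
#' @return `edges_path`, invisibly.
#' @export
write_causal_kb <- function(kb, edges_path, sites_path = NULL, roles_path = NULL) {
  ed <- kb$edges
  readr::write_tsv(tibble::tibble(
    ENTITYA = ed$source, ENTITYB = ed$target,
    EFFECT = ifelse(ed$sign > 0, "up-regulates", "down-regulates"),
    MECHANISM = ed$mechanism, RESIDUE = ed$residue,
    PROVENANCE = ed$provenance), edges_path, progress = FALSE)
  if (!is.null(sites_path)) {
    readr::write_tsv(tibble::tibble(
      PROTEIN = kb$sites$protein, RESIDUE = kb$sites$residue,
      EFFECT = ifelse(kb$sites$effect > 0, "activating", "inhibiting"),
      PROVENANCE = kb$sites$provenance), sites_path, progress = FALSE)
  }
  if (!is.null(roles_path)) {
    readr::write_tsv(tibble::tibble(PROTEIN = kb$roles$protein,
                                    ROLE = kb$roles$role),
                     roles_path, progress = FALSE)
  }
  invisible(edges_path)
}

#' Extract the downstream subnetwork around seed proteins
#'
#' Returns the induced knowledge base on all nodes within at most
#' `radius` directed hops downstream of any seed.  An edge is retained
#' when its source endpoint lies strictly within the radius, i.e. exactly
#' the edges a breadth-first search traverses; at `radius = 0` the result
#' contains the seeds and no edges.
#'
#' @param kb A [causal_kb()].
#' @param seeds Character vector of seed proteins.
#' @param radius Non-negative hop count.
#' @return A [causal_kb()] restricted to the downstream neighbourhood.
#' @export
extract_subnetwork <- function(kb, seeds, radius) {
  stopifnot(radius >= 0)
  present <- seeds %in% kb_proteins(kb)
  if (any(!present)) {
    warning(sprintf("seed(s) absent from kb, ignored: %s",
                    paste(seeds[!present], collapse = ", ")), call. = FALSE)
  }
  seeds <- seeds[present]
  if (length(seeds) == 0) sc_abort("all seeds absent from the knowledge base")
  g <- kb_igraph(kb, exclude_ambiguous = FALSE)
  d <- igraph::distances(g, v = seeds, mode = "out")
  dist_min <- apply(d, 2, min)
  keep_nodes <- names(dist_min)[is.finite(dist_min) & dist_min <= radius]
  ed <- kb$edges
  src_d <- dist_min[ed$source]
  keep_edges <- !is.na(src_d) & is.finite(src_d) & src_d < radius &
    ed$target %in% keep_nodes
  out_edges <- ed[keep_edges, , drop = FALSE]
  out_edges$ambiguous <- NULL
  causal_kb(out_edges,
            sites = kb$sites[kb$sites$protein %in% keep_nodes, , drop = FALSE],
            roles = kb$roles[kb$roles$protein %in% keep_nodes, , drop = FALSE])
}
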