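#' Causal network objects
#'
#' A `causal_network` couples a node table (protein, ternary state,
#' measurement annotation, tier) with the subset of knowledge-base edges
#' connecting them.  `kind = "naive"` networks are the union of all
#' minimal-length causal paths between the perturbation, inferred
#' regulators and transcription factors; `kind = "optimized"` networks
#' additionally satisfy the sign-consistency invariants of
#' [solve_network()].
#'
#' @param nodes Tibble with columns `protein`, `state` (-1/0/+1),
#'   `measured`, `measured_sign`, `tier`.
#' @param edges Tibble of knowledge-base edges among the nodes.
#' @param kind `"naive"` or `"optimized"`.
#' @param source_node The perturbed protein.
#' @param metadata Free-form run-parameter list.
#' @return An object of class `causal_network`.
#' @export
causal_network <- function(nodes, edges, kind = c("naive", "optimized"),
                           source_node, metadata = list()) {
  kind <- match.arg(kind)
  nodes <- tibble::as_tibble(nodes)
  edges <- tibble::as_tibble(edges)
  if (!source_node %in% nodes$protein) sc_abort("source node not in node table")
  ok <- edges$source %in% nodes$protein & edges$target %in% nodes$protein
  if (!all(ok)) sc_abort("edge endpoint missing from node table")
  if (!all(nodes$state %in% c(-1L, 0L, 1L))) sc_abort("node states must be -1/0/+1")
  structure(list(nodes = nodes, edges = edges, kind = kind,
                 source_node = source_node, metadata = metadata),
            class = "causal_network")
}

#' @export
print.causal_network <- function(x, ...) {
  cat(sprintf("<causal_network:%s> %d nodes, %d edges, source=%s\n",
              x$kind, nrow(x$nodes), nrow(x$edges), x$source_node))
  invisible(x)
}

new_node_table <- function(proteins, tiers) {
  tibble::tibble(protein = proteins, state = 0L, measured = FALSE,
                 measured_sign = NA_integer_, tier = tiers)
}

# Union of all shortest directed paths for each ordered (from, to) pair,
# where the pairwise shortest length must not exceed max_len.  Returns the
# kb edge rows on any included path plus the incident node set.
naive_paths <- function(kb, from_set, to_set, max_len) {
  g <- kb_igraph(kb, exclude_ambiguous = TRUE)
  verts <- igraph::V(g)$name
  from_set <- intersect(unique(from_set), verts)
  to_set <- intersect(unique(to_set), verts)
  edge_keep <- logical(nrow(kb$edges))
  node_keep <- character(0)
  unreachable <- character(0)
  ed <- kb$edges
  ed_nonamb <- which(!ed$ambiguous)
  # lookup of non-ambiguous kb edge rows by vertex pair
  pair_key <- paste(ed$source, ed$target, sep = "\r")
  for (f in from_set) {
    targets <- setdiff(to_set, f)
    if (length(targets) == 0) next
    d <- igraph::distances(g, v = f, to = targets, mode = "out")[1, ]
    ok <- is.finite(d) & d <= max_len & d > 0
    unreachable <- c(unreachable, targets[!ok & !(d == 0)])
    for (t in targets[ok]) {
      sp <- igraph::all_shortest_paths(g, from = f, to = t, mode = "out")
      vpaths <- unique(lapply(sp$vpaths %||% sp$res, names))
      for (vp in vpaths) {
        node_keep <- c(node_keep, vp)
        keys <- paste(vp[-length(vp)], vp[-1], sep = "\r")
        edge_keep[ed_nonamb[pair_key[ed_nonamb] %in% keys]] <- TRUE
      }
    }
  }
  list(edges = ed[edge_keep, , drop = FALSE],
       nodes = unique(node_keep),
       unreachable = unique(unreachable))
}

#' Build the naive network of minimal-length causal paths
#'
#' Connects (i) the perturbed source, (ii) the inferred kinases,
#' phosphatases and substrates ("regulators"), and (iii) the inferred
#' transcription factors through every possible causal path of minimal
#' length: for each ordered pair in source->regulator,
#' regulator->regulator and regulator->TF, the directed shortest-path
#' length `L` is computed in the knowledge base and, when `L <= max_len`,
#' *all* paths of length exactly `L` are included.  The naive network is
#' the union of the included paths; intermediates enter with state 0.
#' Ambiguous-sign edges never participate in path search.
#'
#' @param kb A [causal_kb()].
#' @param source Perturbed protein (must be in the kb).
#' @param regulators Character vector of regulator proteins (or an
#'   `activity_table`, from which significant non-TF, non-discordant
#'   proteins are taken).
#' @param tfs Character vector of transcription factors (or an
#'   `activity_table`; may be `NULL` for the regulator-only stage).
#' @param max_len Maximum admissible shortest-path length (default 4).
#' @return A `kind = "naive"` [causal_network()]; unreachable targets are
#'   recorded in `metadata$unreachable`.
#' @export
build_naive_network <- function(kb, source, regulators, tfs = NULL, max_len = 4) {
  stopifnot(max_len >= 1)
  if (!source %in% kb_proteins(kb)) sc_abort("source '%s' absent from kb", source)
  if (inherits(regulators, "activity_table")) {
    regulators <- significant_proteins(regulators, roles = c("kinase", "phosphatase", "other"))
  }
  if (inherits(tfs, "activity_table")) {
    tfs <- significant_proteins(tfs, roles = "TF")
  }
  regulators <- setdiff(unique(regulators), source)
  tfs <- setdiff(unique(tfs %||% character(0)), source)

  p1 <- naive_paths(kb, source, regulators, max_len)
  p2 <- naive_paths(kb, regulators, regulators, max_len)
  p3 <- naive_paths(kb, regulators, tfs, max_len)
  edges <- dplyr::distinct(dplyr::bind_rows(p1$edges, p2$edges, p3$edges))
  nodes <- unique(c(source, p1$nodes, p2$nodes, p3$nodes))
  unreachable <- setdiff(unique(c(p1$unreachable, p3$unreachable)),
                         c(nodes))
  if (length(nodes) <= 1 && nrow(edges) == 0) {
    warning("no target reachable from the source: empty naive network",
            call. = FALSE)
  }
  tier <- dplyr::case_when(
    nodes == source ~ "source",
    nodes %in% tfs ~ "TF",
    nodes %in% regulators & kb_role(kb, nodes) %in% c("kinase", "phosphatase") ~
      "kinase_phosphatase",
    TRUE ~ "substrate")
  if (length(unreachable) > 0) {
    sc_log("%d target(s) unreachable within max_len=%d", length(unreachable), max_len)
  }
  causal_network(new_node_table(nodes, tier), edges, kind = "naive",
                 source_node = source,
                 metadata = list(max_len = max_len, unreachable = unreachable,
                                 regulators = regulators, tfs = tfs))
}

significant_proteins <- function(activities, roles) {
  a <- tibble::as_tibble(activities)
  a$protein[a$significant & !a$discordant & a$role %in% roles]
}

#' Annotate naive-network nodes with measured activity signs
#'
#' Measured nodes receive `measured_sign = sign(z)` of their significant
#' (non-discordant) activity score; the perturbed source is fixed to
#' `source_state` (e.g. -1 for a receptor silenced by a kinase
#' inhibitor).  Activities for proteins absent from the network are
#' ignored and counted.
#'
#' @param net A naive [causal_network()].
#' @param activities An `activity_table`.
#' @param source_state Fixed state of the perturbation (default -1).
#' @return The network with `measured`/`measured_sign` filled and the
#'   source state fixed in `metadata$fixed`.
#' @export
annotate_states <- function(net, activities, source_state = -1L) {
  a <- tibble::as_tibble(activities)
  a <- a[a$significant & !a$discordant & !is.na(a$z), , drop = FALSE]
  known <- a$protein %in% net$nodes$protein
  if (any(!known)) {
    sc_log("%d measured protein(s) not in the network, ignored", sum(!known))
  }
  a <- a[known, , drop = FALSE]
  idx <- match(a$protein, net$nodes$protein)
  net$nodes$measured[idx] <- TRUE
  net$nodes$measured_sign[idx] <- sgn(a$z)
  net$nodes$weight <- NA_real_
  net$nodes$weight[idx] <- abs(a$z)
  src <- net$nodes$protein == net$source_node
  net$nodes$measured[src] <- TRUE
  net$nodes$measured_sign[src] <- as.integer(source_state)
  net$nodes$tier[src] <- "source"
  net$metadata$fixed <- setNames(as.integer(source_state), net$source_node)
  net
}

#' Export a network's edges in SIF format
#'
#' One line per edge: `source <sign> target` with `+1`/`-1` relation
#' tokens.
#'
#' @param net A [causal_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(net, path) {
  writeLines(sprintf("%s %+d %s", net$edges$source, net$edges$sign,
                     net$edges$target), path)
  invisible(path)
}

#' Export node attributes as TSV
#'
#' Columns `name`, `state`, `measured`, `measured_sign`, `tier` using
#' GraphML-compatible attribute names; states follow the usual colour
#' semantics (+1 activated/red, -1 inhibited/blue).
#'
#' @param net A [causal_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_node_attributes <- function(net, path) {
  out <- tibble::tibble(name = net$nodes$protein, state = net$nodes$state,
                        measured = net$nodes$measured,
                        measured_sign = net$nodes$measured_sign,
                        tier = net$nodes$tier)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
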