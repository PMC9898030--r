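# Shared fixtures: everything is built in code at test time.

mt <- function(ids, lfc, layer = "transcript", ...) {
  measurement_table(tibble::tibble(analyte_id = ids, log2fc = lfc, ...),
                    layer = layer)
}

# replicate-carrying table from two matrices (rows = analytes)
mt_reps <- function(ids, ctrl, trt, layer = "protein") {
  measurement_table(tibble::tibble(
    analyte_id = ids,
    log2fc = rowMeans(trt) - rowMeans(ctrl),
    reps_control = lapply(seq_len(nrow(ctrl)), function(i) ctrl[i, ]),
    reps_treated = lapply(seq_len(nrow(trt)), function(i) trt[i, ])),
    layer = layer)
}

edge_row <- function(source, target, sign, mechanism = "other",
                     residue = NA_character_) {
  tibble::tibble(source = source, target = target, sign = as.integer(sign),
                 mechanism = mechanism, residue = residue,
                 provenance = "fixture")
}

# small receptor -> enzymes -> TF cascade with known roles
fixture_kb <- function() {
  causal_kb(
    dplyr::bind_rows(
      edge_row("R", "K1", 1, "phosphorylation", "Y10"),
      edge_row("R", "K2", 1, "phosphorylation", "S20"),
      edge_row("K1", "P1", -1, "phosphorylation", "T30"),
      edge_row("K1", "S1", 1, "phosphorylation", "S40"),
      edge_row("K2", "S1", 1, "phosphorylation", "S41"),
      edge_row("K2", "S2", -1, "phosphorylation", "Y50"),
      edge_row("P1", "S2", 1, "dephosphorylation", "Y51"),
      edge_row("S1", "T1", 1, "binding"),
      edge_row("S2", "T1", -1, "binding"),
      edge_row("T1", "G1", 1, "transcriptional"),
      edge_row("T1", "G2", -1, "transcriptional"),
      edge_row("T1", "G3", 1, "transcriptional")),
    sites = tibble::tibble(
      protein = c("K1", "K2", "P1", "S1", "S1", "S2"),
      residue = c("Y10", "S20", "T30", "S40", "S41", "Y50"),
      effect = c(1L, 1L, -1L, 1L, 1L, -1L),
      provenance = "fixture"),
    roles = tibble::tibble(
      protein = c("R", "K1", "K2", "P1", "S1", "S2", "T1"),
      role = c("other", "kinase", "kinase", "phosphatase", "other", "other", "TF")))
}

# random small sign-consistency instance for engine-equivalence sweeps
random_problem <- function(seed, n_range = 4:8, lambda = 0.1) {
  set.seed(seed)
  n <- sample(n_range, 1)
  prot <- c("S", paste0("N", seq_len(n - 1)))
  pairs <- expand.grid(u = prot, v = prot, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$u != pairs$v, ]
  m <- sample(2:min(12, nrow(pairs)), 1)
  pairs <- pairs[sample(nrow(pairs), m), ]
  edges <- tibble::tibble(source = pairs$u, target = pairs$v,
                          sign = sample(c(-1L, 1L), m, TRUE),
                          mechanism = "other", residue = NA_character_,
                          provenance = NA_character_, ambiguous = FALSE)
  meas <- sample(prot[-1], sample(1:(n - 1), 1))
  nodes <- tibble::tibble(
    protein = prot, state = 0L, measured = prot %in% meas,
    measured_sign = ifelse(prot %in% meas, sample(c(-1L, 1L), n, TRUE),
                           NA_integer_),
    tier = "substrate",
    weight = ifelse(prot %in% meas, runif(n, 0.5, 3), NA_real_))
  net <- causal_network(nodes, edges, kind = "naive", source_node = "S",
                        metadata = list(fixed = c(S = sample(c(-1L, 1L), 1))))
  optimization_problem(net, lambda = lambda)
}

# brute-force all-minimal-paths oracle (independent of the package's
# shortest-path code): enumerate every simple path up to max_len with
# igraph::all_simple_paths and keep the per-pair minimal ones
oracle_naive <- function(kb, from_set, to_set, max_len) {
  ed <- kb$edges[!kb$edges$ambiguous, , drop = FALSE]
  g <- igraph::graph_from_data_frame(ed[, c("source", "target")],
                                     directed = TRUE,
                                     vertices = unique(c(ed$source, ed$target,
                                                         from_set, to_set)))
  nodes <- character(0)
  edges <- character(0)
  for (f in intersect(from_set, igraph::V(g)$name)) {
    for (t in setdiff(intersect(to_set, igraph::V(g)$name), f)) {
      paths <- igraph::all_simple_paths(g, from = f, to = t, mode = "out",
                                        cutoff = max_len)
      if (length(paths) == 0) next
      lens <- lengths(paths) - 1
      for (p in paths[lens == min(lens)]) {
        vp <- names(p)
        nodes <- c(nodes, vp)
        edges <- c(edges, paste(vp[-length(vp)], vp[-1]))
      }
    }
  }
  list(nodes = sort(unique(nodes)), edges = sort(unique(edges)))
}

# run the full pipeline in memory on a synthetic truth
run_truth <- function(truth, seed, engine = "auto", lambda = 0.1,
                      fdr_diff = 0.1, fdr_activity = 0.05, n_perm = 1000) {
  tabs <- suppressWarnings(lapply(truth$tables, differential_stats,
                                  fdr_threshold = fdr_diff))
  acts <- suppressMessages(activity_table(
    truth$kb, tabs$transcriptome, tabs$proteome, tabs$phospho,
    n_perm = n_perm, seed = seed, fdr_threshold = fdr_activity))
  model <- suppressMessages(two_run_optimize(
    truth$kb, truth$source, acts, engine = engine, lambda = lambda,
    seed = seed))
  list(tables = tabs, activities = acts, model = model)
}
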