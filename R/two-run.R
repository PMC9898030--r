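#' Two-run sign-consistent network optimization
#'
#' The full step-3 scheme.  Run 1 builds and solves the naive network
#' connecting the perturbed source to the significant kinases,
#' phosphatases and substrates.  Run 2 builds a second naive network from
#' every node retained (nonzero) in run 1 to the significant
#' transcription factors and solves it with the run-1 states as hard
#' constraints; the retained run-1 nodes act as grounded signal entry
#' points.  The merged model is the union of the two active-edge sets and
#' satisfies the solution invariants globally, which is verified with the
#' independent checker before returning.
#'
#' @param kb A [causal_kb()].
#' @param source Perturbed protein.
#' @param activities An `activity_table` ([activity_table()]).
#' @param source_state Fixed perturbation state (default -1, an inhibited
#'   receptor).
#' @param max_len Maximum minimal-path length (default 4).
#' @param lambda Edge penalty (default 0.1).
#' @param engine,seed Passed to [solve_network()].
#' @return A `kind = "optimized"` [causal_network()]; node states carry
#'   the merged assignment, `metadata$solutions` the two run solutions.
#' @export
two_run_optimize <- function(kb, source, activities, source_state = -1L,
                             max_len = 4, lambda = 0.1, engine = "auto",
                             seed = 1L) {
  regs <- significant_proteins(activities, roles = c("kinase", "phosphatase", "other"))
  tfs <- significant_proteins(activities, roles = "TF")

  net1 <- build_naive_network(kb, source, regulators = regs, tfs = NULL,
                              max_len = max_len)
  net1 <- annotate_states(net1, activities, source_state = source_state)
  prob1 <- optimization_problem(net1, lambda = lambda)
  sol1 <- solve_network(prob1, engine = engine, seed = seed)
  if (sol1$status == "infeasible" || sol1$fit_count == 0) {
    sc_abort("no explainable regulators: run-1 optimization matched nothing")
  }
  check_solution(sol1, prob1)
  retained <- names(sol1$assignment)[sol1$assignment != 0L]

  paths2 <- naive_paths(kb, from_set = retained, to_set = tfs,
                        max_len = max_len)
  nodes2 <- unique(c(retained, paths2$nodes))
  tier2 <- dplyr::case_when(
    nodes2 == source ~ "source",
    nodes2 %in% tfs ~ "TF",
    kb_role(kb, nodes2) %in% c("kinase", "phosphatase") ~ "kinase_phosphatase",
    TRUE ~ "substrate")
  net2 <- causal_network(new_node_table(nodes2, tier2),
                         dplyr::distinct(paths2$edges),
                         kind = "naive", source_node = source,
                         metadata = list(max_len = max_len,
                                         unreachable = paths2$unreachable))
  net2 <- annotate_states(net2, activities, source_state = source_state)
  fixed2 <- sol1$assignment[intersect(retained, nodes2)]
  prob2 <- optimization_problem(net2, lambda = lambda, fixed = fixed2)
  sol2 <- solve_network(prob2, engine = engine, seed = seed + 1L)
  check_solution(sol2, prob2)

  assignment <- sol1$assignment
  assignment[names(sol2$assignment)] <- sol2$assignment
  active <- dplyr::distinct(dplyr::bind_rows(sol1$active_edges,
                                             sol2$active_edges))
  keep <- names(assignment)[assignment != 0L]
  nodes <- tibble::tibble(
    protein = keep,
    state = as.integer(assignment[keep]),
    measured = FALSE, measured_sign = NA_integer_,
    tier = dplyr::case_when(
      keep == source ~ "source",
      keep %in% tfs ~ "TF",
      kb_role(kb, keep) %in% c("kinase", "phosphatase") ~ "kinase_phosphatase",
      TRUE ~ "substrate"))
  a <- tibble::as_tibble(activities)
  a <- a[a$significant & !a$discordant & !is.na(a$z), , drop = FALSE]
  idx <- match(nodes$protein, a$protein)
  nodes$measured <- !is.na(idx)
  nodes$measured_sign[!is.na(idx)] <- sgn(a$z[idx[!is.na(idx)]])
  merged <- causal_network(nodes, active, kind = "optimized",
                           source_node = source,
                           metadata = list(
                             max_len = max_len, lambda = lambda,
                             fixed = setNames(as.integer(source_state), source),
                             solutions = list(run1 = sol1, run2 = sol2)))
  # global invariant audit on the merged graph
  merged_prob <- optimization_problem(
    causal_network(tibble::tibble(protein = names(assignment),
                                  state = 0L, measured = FALSE,
                                  measured_sign = NA_integer_, tier = "substrate",
                                  weight = NA_real_),
                   active, kind = "naive", source_node = source,
                   metadata = list(fixed = setNames(as.integer(source_state),
                                                    source))),
    lambda = lambda)
  check_solution(structure(list(assignment = assignment,
                                active_edges = active,
                                objective = -lambda * nrow(active),
                                fit_count = 0L, status = "feasible",
                                engine = "merge"),
                           class = "network_solution"),
                 merged_prob)
  merged
}

#' Compare two optimized models node by node
#'
#' Pearson correlation of the ternary node states over nodes present in
#' both models, plus the discordance lists: nodes with opposite nonzero
#' states (the interesting, condition-flipped regulators) and nodes
#' exclusive to either model.
#'
#' @param a,b Optimized [causal_network()]s.
#' @return List of class `model_comparison` with `r`, `n_shared`,
#'   `opposite`, `exclusive_a`, `exclusive_b`.
#' @export
compare_models <- function(a, b) {
  sa <- setNames(a$nodes$state, a$nodes$protein)
  sb <- setNames(b$nodes$state, b$nodes$protein)
  shared <- intersect(names(sa), names(sb))
  if (length(shared) < 3) sc_abort("fewer than 3 shared nodes")
  va <- sa[shared]; vb <- sb[shared]
  r <- if (sd(va) == 0 || sd(vb) == 0) NA_real_ else cor(va, vb)
  opposite <- shared[va * vb < 0]
  structure(list(r = r, n_shared = length(shared), opposite = opposite,
                 exclusive_a = setdiff(names(sa), names(sb)),
                 exclusive_b = setdiff(names(sb), names(sa))),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("<model_comparison> R = %.3f over %d shared nodes\n",
              x$r, x$n_shared))
  cat(sprintf("  oppositely regulated: %s\n",
              if (length(x$opposite)) paste(x$opposite, collapse = ", ") else "none"))
  cat(sprintf("  exclusive to a: %d, to b: %d\n",
              length(x$exclusive_a), length(x$exclusive_b)))
  invisible(x)
}

#' Fraction of model node states matching a ground truth
#'
#' Accuracy of an optimized model against known true states: the share
#' of model nodes carrying a nonzero state whose state equals the truth.
#' Nodes the model leaves out (state 0 / unexplainable under the prior)
#' do not enter the denominator.
#'
#' @param model Optimized [causal_network()].
#' @param true_states Named vector of true node states (-1/+1).
#' @return List with `accuracy` and `n` (nodes scored).
#' @export
state_recovery <- function(model, true_states) {
  st <- setNames(model$nodes$state, model$nodes$protein)
  st <- st[st != 0L]
  st <- st[names(st) %in% names(true_states)]
  if (length(st) == 0) return(list(accuracy = NA_real_, n = 0L))
  list(accuracy = mean(st == true_states[names(st)]), n = length(st))
}
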