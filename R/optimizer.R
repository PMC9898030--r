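#' Define a sign-consistency optimization problem
#'
#' Packages an annotated naive network into the optimization problem of
#' step 3: choose a ternary state for every node and a set of active
#' edges maximizing
#' `sum over measured v of w_v * [state(v) == measured_sign(v)]  -
#'  lambda * |active edges|`
#' subject to sign consistency (along every active edge `u -> v` with
#' sign `s`, `state(v) = s * state(u)` and `state(u) != 0`) and causal
#' grounding: every nonzero node must receive signal from a fixed
#' ("root") node through active edges -- a stricter reading of the usual
#' local support condition that rules out self-sustaining loops detached
#' from the perturbation.
#'
#' @param network An annotated naive [causal_network()] (see
#'   [annotate_states()]).
#' @param lambda Edge-count penalty weight (>= 0, default 0.1).
#' @param node_weights Optional named vector of weights for measured
#'   nodes; defaults to `|z|` recorded by [annotate_states()], or 1.
#' @param fixed Named integer vector of hard node states; defaults to
#'   the fixed source recorded in the network metadata.
#' @return Object of class `optimization_problem`.
#' @export
optimization_problem <- function(network, lambda = 0.1, node_weights = NULL,
                                 fixed = NULL) {
  stopifnot(inherits(network, "causal_network"), lambda >= 0)
  nodes <- network$nodes
  fixed <- fixed %||% network$metadata$fixed
  if (is.null(fixed) || length(fixed) == 0) {
    sc_abort("no fixed node states; annotate the network or pass `fixed`")
  }
  if (!all(names(fixed) %in% nodes$protein)) {
    sc_abort("fixed node(s) absent from network: %s",
             paste(setdiff(names(fixed), nodes$protein), collapse = ", "))
  }
  msign <- ifelse(nodes$measured & !is.na(nodes$measured_sign),
                  nodes$measured_sign, 0L)
  w <- rep(0, nrow(nodes))
  if ("weight" %in% names(nodes)) {
    w <- ifelse(is.na(nodes$weight), 0, nodes$weight)
  }
  w[msign != 0 & w == 0] <- 1
  if (!is.null(node_weights)) {
    idx <- match(names(node_weights), nodes$protein)
    w[idx[!is.na(idx)]] <- node_weights[!is.na(idx)]
  }
  # fixed nodes are constraints, not part of the fit reward
  msign[match(names(fixed), nodes$protein)] <- 0L
  structure(list(network = network, lambda = lambda, weights = w,
                 measured_sign = as.integer(msign), fixed = fixed),
            class = "optimization_problem")
}

problem_arrays <- function(problem) {
  net <- problem$network
  prot <- net$nodes$protein
  n <- length(prot)
  fixed_vec <- rep(-9L, n)
  fixed_vec[match(names(problem$fixed), prot)] <- as.integer(problem$fixed)
  list(n = n, proteins = prot,
       efrom = match(net$edges$source, prot),
       eto = match(net$edges$target, prot),
       esign = as.integer(net$edges$sign),
       fixed = fixed_vec, msign = problem$measured_sign, w = problem$weights,
       lambda = problem$lambda)
}

#' Solve a sign-consistency problem
#'
#' Three engines share identical problem semantics.  `exact` is a
#' branch-and-bound search with sound pruning, guaranteed optimal at any
#' size it completes.  `exhaustive` enumerates all `3^k` assignments of
#' the `k` free nodes (capped at 12 free nodes) and is kept as an
#' independent verification oracle.  `anneal` seeds a solution from
#' greedy signed-path covering and refines it by simulated annealing; it
#' returns a feasible, reproducible, but not necessarily optimal
#' solution and is intended for instances beyond exact reach.  `auto`
#' picks `exact` up to `max_exact_free` free nodes, `anneal` above.
#'
#' @param problem An [optimization_problem()].
#' @param engine `"auto"`, `"exact"`, `"exhaustive"` or `"anneal"`.
#' @param seed Integer seed (used by the anneal engine; exact engines
#'   are deterministic regardless).
#' @param max_exact_free Free-node threshold for `auto` (default 26).
#' @param anneal_control List of annealing parameters: `n_iter`,
#'   `t0`, `t_min` (geometric cooling).
#' @return Object of class `network_solution`: `assignment` (named
#'   ternary vector), `active_edges` (tibble), `objective`, `fit_count`,
#'   `status`, `engine`.
#' @export
solve_network <- function(problem, engine = c("auto", "exact", "exhaustive",
                                              "anneal"),
                          seed = 1L, max_exact_free = 26,
                          anneal_control = list()) {
  engine <- match.arg(engine)
  stopifnot(inherits(problem, "optimization_problem"))
  arr <- problem_arrays(problem)
  if (arr$n == 0) sc_abort("empty network")
  roots <- arr$fixed != -9L & arr$fixed != 0L
  if (!any(roots)) {
    return(structure(list(assignment = NULL, active_edges = NULL,
                          objective = NA_real_, fit_count = 0L,
                          status = "infeasible", engine = engine,
                          certificate = "no fixed nonzero node: nothing can ground the signal"),
                     class = "network_solution"))
  }
  n_free <- sum(arr$fixed == -9L)
  if (engine == "auto") {
    engine <- if (n_free <= max_exact_free) "exact" else "anneal"
  }
  res <- switch(engine,
                exact = solve_exact(arr),
                exhaustive = solve_exhaustive_arrays(arr),
                anneal = solve_anneal(arr, seed, anneal_control))
  states <- setNames(res$states, arr$proteins)
  finish_solution(problem, arr, states, status = res$status, engine = engine)
}

#' Exhaustively enumerate a small problem (verification oracle)
#'
#' Provably optimal by enumeration of all ternary assignments of the
#' free nodes, filtered by the feasibility invariants.  Refuses
#' instances with more than 12 free nodes.
#'
#' @param problem An [optimization_problem()].
#' @return A `network_solution` (see [solve_network()]).
#' @export
exhaustive_solve <- function(problem) {
  solve_network(problem, engine = "exhaustive")
}

solve_exact <- function(arr) {
  # greedy signed-path incumbent: lets the search prune every branch
  # that cannot strictly improve on a known feasible solution
  inc <- greedy_states(arr)
  inc_eval <- evaluate_states(arr, inc)
  out <- solve_bnb_cpp(arr$n, arr$efrom - 1L, arr$eto - 1L, arr$esign,
                       arr$fixed, arr$msign, arr$w, arr$lambda,
                       lower_bound = inc_eval$obj)
  if (identical(out$status, "infeasible")) {
    return(list(states = inc_eval$states, status = "optimal"))
  }
  list(states = as.integer(out$states), status = "optimal")
}

evaluate_states <- function(arr, st) {
  cl <- closure_states(arr, st)
  roots <- sum(arr$fixed != -9L & arr$fixed != 0L)
  meas <- arr$msign != 0L
  list(states = cl,
       obj = sum(arr$w[meas & cl == arr$msign]) -
         arr$lambda * (sum(cl != 0L) - roots))
}

solve_exhaustive_arrays <- function(arr) {
  free <- which(arr$fixed == -9L)
  k <- length(free)
  if (k > 12) sc_abort("exhaustive engine limited to 12 free nodes (got %d)", k)
  n_rows <- 3L^k
  S <- matrix(rep(arr$fixed, each = n_rows), nrow = n_rows)
  S[S == -9L] <- 0L
  vals <- c(0L, 1L, -1L)
  if (k > 0) {
    idx <- seq_len(n_rows) - 1L
    for (j in seq_len(k)) {
      S[, free[j]] <- vals[(idx %/% 3L^(j - 1L)) %% 3L + 1L]
    }
  }
  roots <- which(arr$fixed != -9L & arr$fixed != 0L)
  reach <- matrix(FALSE, n_rows, arr$n)
  reach[, roots] <- TRUE
  repeat {
    changed <- FALSE
    for (i in seq_along(arr$efrom)) {
      u <- arr$efrom[i]; v <- arr$eto[i]; s <- arr$esign[i]
      cand <- reach[, u] & S[, u] != 0L & S[, v] == s * S[, u] & !reach[, v]
      if (any(cand)) {
        reach[cand, v] <- TRUE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  feasible <- rowSums(S != 0L & !reach) == 0L
  meas <- which(arr$msign != 0L)
  matched <- if (length(meas) > 0) {
    (S[, meas, drop = FALSE] == rep(arr$msign[meas], each = n_rows)) %*%
      arr$w[meas]
  } else matrix(0, n_rows, 1)
  n_on <- rowSums(S[, -roots, drop = FALSE] != 0L)
  obj <- as.numeric(matched) - arr$lambda * n_on
  obj[!feasible] <- -Inf
  best <- order(-obj, n_on, seq_len(n_rows))[1]
  list(states = S[best, ], status = "optimal")
}

# deterministic greedy cover: walk each measured node's shortest
# sign-consistent path from a root, highest weight first, skipping
# targets whose path conflicts with states already chosen
greedy_states <- function(arr) {
  n <- arr$n
  roots <- which(arr$fixed != -9L & arr$fixed != 0L)
  init <- rep(0L, n)
  init[arr$fixed != -9L] <- arr$fixed[arr$fixed != -9L]

  # signed BFS: which (node, sign) pairs are reachable, with parents
  enc <- function(v, s) v + n * (s < 0)  # 2n signed-node indices
  dist <- rep(NA_integer_, 2L * n)
  parent <- rep(NA_integer_, 2L * n)
  queue <- integer(0)
  for (r in roots) {
    id <- enc(r, arr$fixed[r])
    dist[id] <- 0L
    queue <- c(queue, id)
  }
  qi <- 1L
  while (qi <= length(queue)) {
    id <- queue[qi]; qi <- qi + 1L
    v <- (id - 1L) %% n + 1L
    s <- if (id > n) -1L else 1L
    out_e <- which(arr$efrom == v)
    for (i in out_e) {
      t <- arr$eto[i]
      ts <- arr$esign[i] * s
      tid <- enc(t, ts)
      if (is.na(dist[tid])) {
        dist[tid] <- dist[id] + 1L
        parent[tid] <- id
        queue <- c(queue, tid)
      }
    }
  }
  meas <- which(arr$msign != 0L)
  meas <- meas[order(-arr$w[meas])]
  st <- init
  for (v in meas) {
    tid <- enc(v, arr$msign[v])
    if (is.na(dist[tid])) next
    # walk the parent chain; abandon on conflict with already-chosen states
    chain <- integer(0)
    id <- tid
    ok <- TRUE
    while (!is.na(id)) {
      nv <- (id - 1L) %% n + 1L
      ns <- if (id > n) -1L else 1L
      if (st[nv] != 0L && st[nv] != ns) { ok <- FALSE; break }
      if (arr$fixed[nv] != -9L && arr$fixed[nv] != ns) { ok <- FALSE; break }
      chain <- c(chain, id)
      id <- parent[id]
    }
    if (ok) {
      for (id2 in chain) {
        st[(id2 - 1L) %% n + 1L] <- if (id2 > n) -1L else 1L
      }
    }
  }
  st
}

# greedy signed-path cover + simulated-annealing refinement
solve_anneal <- function(arr, seed, control) {
  ctl <- modifyList(list(n_iter = 20000L, t0 = 1.0, t_min = 0.01), control)
  roots <- which(arr$fixed != -9L & arr$fixed != 0L)
  st <- greedy_states(arr)

  eval_repaired <- function(st) {
    cl <- closure_states(arr, st)
    meas_all <- arr$msign != 0L
    matched <- sum(arr$w[meas_all & cl == arr$msign])
    on <- sum(cl != 0L) - length(roots)
    list(states = cl, obj = matched - arr$lambda * on)
  }
  cur <- eval_repaired(st)
  best <- cur
  withr::with_seed(seed, {
    n_iter <- ctl$n_iter
    cool <- (ctl$t_min / ctl$t0)^(1 / max(1, n_iter - 1))
    temp <- ctl$t0
    free <- which(arr$fixed == -9L)
    if (length(free) > 0) {
      for (it in seq_len(n_iter)) {
        v <- free[sample.int(length(free), 1)]
        old <- st[v]
        st[v] <- sample(setdiff(c(0L, 1L, -1L), old), 1)
        prop <- eval_repaired(st)
        if (prop$obj >= cur$obj ||
            runif(1) < exp((prop$obj - cur$obj) / temp)) {
          cur <- prop
          if (cur$obj > best$obj) best <- cur
        } else {
          st[v] <- old
        }
        temp <- temp * cool
      }
    }
  })
  list(states = best$states, status = "feasible")
}

# restrict a raw state vector to its root-grounded consistent closure
closure_states <- function(arr, st) {
  roots <- which(arr$fixed != -9L & arr$fixed != 0L)
  reached <- rep(FALSE, arr$n)
  reached[roots] <- TRUE
  repeat {
    changed <- FALSE
    for (i in seq_along(arr$efrom)) {
      u <- arr$efrom[i]; v <- arr$eto[i]
      if (reached[u] && !reached[v] && st[u] != 0L &&
          st[v] == arr$esign[i] * st[u]) {
        reached[v] <- TRUE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- st
  out[!reached] <- 0L
  out[roots] <- st[roots]
  out
}

# derive the canonical active-edge set: one support edge per grounded
# nonzero non-root node, chosen in BFS rounds with the lowest canonical
# edge index (reproducible tie-break)
finish_solution <- function(problem, arr, states, status, engine) {
  net <- problem$network
  ord <- order(net$edges$source, net$edges$target, net$edges$sign,
               net$edges$mechanism)
  rank <- integer(nrow(net$edges))
  rank[ord] <- seq_along(ord)
  roots <- which(arr$fixed != -9L & arr$fixed != 0L)
  supported <- rep(FALSE, arr$n)
  supported[roots] <- TRUE
  chosen <- integer(0)
  need <- which(states != 0L & !supported)
  while (length(need) > 0) {
    progress <- FALSE
    for (v in need) {
      inc <- which(arr$eto == v & supported[arr$efrom] &
                     states[arr$efrom] != 0L &
                     states[v] == arr$esign * states[arr$efrom])
      if (length(inc) > 0) {
        chosen <- c(chosen, inc[which.min(rank[inc])])
        supported[v] <- TRUE
        progress <- TRUE
      }
    }
    need <- which(states != 0L & !supported)
    if (!progress) break
  }
  if (length(need) > 0) {
    sc_abort("internal error: ungrounded nonzero node(s) in solution: %s",
             paste(arr$proteins[need], collapse = ", "))
  }
  active <- net$edges[sort(chosen), , drop = FALSE]
  meas <- arr$msign != 0L
  fit <- sum(states[meas] == arr$msign[meas])
  matched <- sum(arr$w[meas & states == arr$msign])
  objective <- matched - arr$lambda * nrow(active)
  structure(list(assignment = states, active_edges = active,
                 objective = objective, fit_count = as.integer(fit),
                 status = status, engine = engine),
            class = "network_solution")
}

#' @export
print.network_solution <- function(x, ...) {
  if (x$status == "infeasible") {
    cat("<network_solution> infeasible:", x$certificate, "\n")
    return(invisible(x))
  }
  cat(sprintf("<network_solution:%s> status=%s objective=%.4f fit=%d nonzero=%d edges=%d\n",
              x$engine, x$status, x$objective, x$fit_count,
              sum(x$assignment != 0), nrow(x$active_edges)))
  invisible(x)
}

#' Independently verify a solution's sign-consistency invariants
#'
#' A deliberately separate code path from every solver: checks, with
#' plain loops over the returned structures, that (i) states are
#' ternary and fixed states are respected, (ii) every active edge
#' `u -> v` has `state(u) != 0` and `state(v) = sign * state(u)`,
#' (iii) every nonzero non-root node has at least one incoming active
#' edge, (iv) every nonzero node is reachable from a root through
#' active edges, and (v) the reported objective equals the recomputed
#' one.
#'
#' @param solution A `network_solution`.
#' @param problem The [optimization_problem()] it solves.
#' @return `TRUE` invisibly; aborts with the violated invariant
#'   otherwise.
#' @export
check_solution <- function(solution, problem) {
  if (solution$status == "infeasible") sc_abort("solution is infeasible")
  st <- solution$assignment
  nodes <- problem$network$nodes$protein
  if (!all(st %in% c(-1L, 0L, 1L))) sc_abort("non-ternary state")
  for (nm in names(problem$fixed)) {
    if (st[[nm]] != problem$fixed[[nm]]) sc_abort("fixed state violated at %s", nm)
  }
  ae <- solution$active_edges
  for (i in seq_len(nrow(ae))) {
    u <- ae$source[i]; v <- ae$target[i]; s <- ae$sign[i]
    if (st[[u]] == 0L) sc_abort("active edge from zero-state node %s", u)
    if (st[[v]] != s * st[[u]]) sc_abort("sign inconsistency on edge %s -> %s", u, v)
  }
  roots <- names(problem$fixed)[problem$fixed != 0L]
  for (nm in nodes) {
    if (st[[nm]] != 0L && !nm %in% roots) {
      if (!any(ae$target == nm)) sc_abort("nonzero node %s has no incoming active edge", nm)
    }
  }
  # reachability from roots through active edges
  reached <- roots[st[roots] != 0L]
  repeat {
    grow <- unique(ae$target[ae$source %in% reached])
    grow <- setdiff(grow, reached)
    if (length(grow) == 0) break
    reached <- c(reached, grow)
  }
  detached <- setdiff(names(st)[st != 0L], reached)
  if (length(detached) > 0) {
    sc_abort("nonzero node(s) not grounded in a root: %s",
             paste(detached, collapse = ", "))
  }
  meas <- problem$measured_sign != 0L
  matched <- sum(problem$weights[meas & st[nodes] == problem$measured_sign])
  if (abs(matched - problem$lambda * nrow(ae) - solution$objective) > 1e-8) {
    sc_abort("objective mismatch")
  }
  invisible(TRUE)
}
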