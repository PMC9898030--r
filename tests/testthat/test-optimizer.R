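chain_problem <- function(measured_sign, lambda = 0.1) {
  # S(-1) -(+1)-> A -(-1)-> B, with B measured
  edges <- dplyr::bind_rows(edge_row("S", "A", 1), edge_row("A", "B", -1))
  edges$ambiguous <- FALSE
  nodes <- tibble::tibble(protein = c("S", "A", "B"), state = 0L,
                          measured = c(FALSE, FALSE, TRUE),
                          measured_sign = c(NA, NA, measured_sign),
                          tier = "substrate",
                          weight = c(NA, NA, 2))
  net <- causal_network(nodes, edges, kind = "naive", source_node = "S",
                        metadata = list(fixed = c(S = -1L)))
  optimization_problem(net, lambda = lambda)
}

test_that("a consistent chain is explained and an inconsistent one is not", {
  pr <- chain_problem(+1L)
  for (eng in c("exact", "exhaustive")) {
    sol <- solve_network(pr, engine = eng)
    expect_equal(sol$assignment[["A"]], -1L)   # -1 * +1
    expect_equal(sol$assignment[["B"]], 1L)    # -1 * -1
    expect_equal(sol$fit_count, 1L)
    expect_equal(nrow(sol$active_edges), 2)
    expect_equal(sol$objective, 2 - 0.1 * 2)
    check_solution(sol, pr)
  }
  # no sign-consistent path can produce B = -1: nothing worth activating
  pr2 <- chain_problem(-1L)
  sol2 <- solve_network(pr2, engine = "exhaustive")
  expect_equal(sol2$fit_count, 0L)
  expect_equal(nrow(sol2$active_edges), 0)
})

test_that("lambda = 0 on a fully consistent fixture matches every measured node", {
  kb <- fixture_kb()
  net <- suppressMessages(build_naive_network(kb, "R",
                                              regulators = c("K1", "K2", "S1"),
                                              max_len = 3))
  idx <- match(c("K1", "K2", "S1"), net$nodes$protein)
  net$nodes$measured[idx] <- TRUE
  net$nodes$measured_sign[idx] <- c(-1L, -1L, -1L)  # -1 source * +1 edges
  net$metadata$fixed <- c(R = -1L)
  pr <- optimization_problem(net, lambda = 0)
  sol <- solve_network(pr, engine = "exact")
  expect_equal(sol$fit_count, 3L)
})

test_that("single free unmeasured node stays off and empty fixes are infeasible", {
  edges <- edge_row("S", "A", 1)
  edges$ambiguous <- FALSE
  nodes <- tibble::tibble(protein = c("S", "A"), state = 0L,
                          measured = FALSE, measured_sign = NA_integer_,
                          tier = "substrate", weight = NA_real_)
  net <- causal_network(nodes, edges, kind = "naive", source_node = "S",
                        metadata = list(fixed = c(S = 1L)))
  sol <- solve_network(optimization_problem(net), engine = "exhaustive")
  expect_equal(sol$assignment[["A"]], 0L)
  expect_equal(sol$objective, 0)

  net0 <- net
  net0$metadata$fixed <- c(S = 0L)
  sol0 <- solve_network(optimization_problem(net0), engine = "exact")
  expect_equal(sol0$status, "infeasible")
  expect_match(sol0$certificate, "ground")
})

test_that("exact branch-and-bound equals exhaustive enumeration on 100 instances", {
  for (seed in 0:99) {
    pr <- random_problem(seed)
    a <- solve_network(pr, engine = "exact")
    b <- solve_network(pr, engine = "exhaustive")
    expect_equal(a$objective, b$objective, tolerance = 1e-9)
    check_solution(a, pr)
    check_solution(b, pr)
  }
})

test_that("objective is monotone non-increasing in lambda and edges vanish at large lambda", {
  for (seed in c(3, 17, 41)) {
    objs <- c()
    for (lam in c(0, 0.1, 0.5, 2, 100)) {
      pr <- random_problem(seed, lambda = lam)
      sol <- solve_network(pr, engine = "exact")
      objs <- c(objs, sol$objective)
      if (lam == 100) expect_equal(nrow(sol$active_edges), 0)
    }
    expect_true(all(diff(objs) <= 1e-9))
  }
})

test_that("solutions are deterministic for a fixed problem, engine and seed", {
  pr <- random_problem(7)
  for (eng in c("exact", "exhaustive", "anneal")) {
    s1 <- solve_network(pr, engine = eng, seed = 5)
    s2 <- solve_network(pr, engine = eng, seed = 5)
    expect_identical(s1$assignment, s2$assignment)
    expect_identical(s1$objective, s2$objective)
  }
})

test_that("annealing attains the exact optimum on small instances", {
  for (seed in c(2, 9, 23)) {
    pr <- random_problem(seed)
    opt <- solve_network(pr, engine = "exact")$objective
    ann <- solve_network(pr, engine = "anneal", seed = 1,
                         anneal_control = list(n_iter = 3000))
    expect_equal(ann$status, "feasible")
    check_solution(ann, pr)
    expect_equal(ann$objective, opt, tolerance = 1e-9)
  }
})

test_that("two-run optimization recovers a noiseless synthetic truth exactly", {
  p <- generator_params(seed = 8, n_nodes = 30, n_tfs = 6, n_kinases = 8,
                        n_phosphatases = 2, noise_sd = 0,
                        frac_inconsistent = 0)
  tr <- generate_truth(p)
  res <- run_truth(tr, seed = 13, n_perm = 200)
  rec <- state_recovery(res$model, tr$true_states)
  expect_equal(rec$accuracy, 1.0)
  expect_gt(rec$n, 5)
  # TFs reachable only through retained kinases are present
  expect_true(any(res$model$nodes$tier == "TF"))
})

test_that("run-2 additions never alter run-1 fixed states", {
  p <- generator_params(seed = 14, n_nodes = 30, n_tfs = 6, n_kinases = 8,
                        n_phosphatases = 2, noise_sd = 0.3)
  tr <- generate_truth(p)
  res <- run_truth(tr, seed = 19, n_perm = 200)
  sols <- res$model$metadata$solutions
  r1 <- sols$run1$assignment
  r1 <- r1[r1 != 0L]
  r2 <- sols$run2$assignment
  shared <- intersect(names(r1), names(r2))
  expect_identical(r2[shared], r1[shared])
})

test_that("model comparison reports planted opposite regulation", {
  mk_model <- function(states) {
    nodes <- tibble::tibble(protein = names(states),
                            state = as.integer(states), measured = FALSE,
                            measured_sign = NA_integer_, tier = "substrate")
    causal_network(nodes, edge_row(names(states)[1], names(states)[2], 1),
                   kind = "optimized", source_node = names(states)[1])
  }
  s <- c(S = -1L, A = 1L, B = -1L, C = 1L)
  ident <- compare_models(mk_model(s), mk_model(s))
  expect_equal(ident$r, 1)
  expect_length(ident$opposite, 0)

  s2 <- s; s2[["B"]] <- 1L
  flip <- compare_models(mk_model(s), mk_model(s2))
  expect_equal(flip$opposite, "B")
  expect_error(compare_models(mk_model(s[1:2]), mk_model(s[1:2])),
               "fewer than 3")
})
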