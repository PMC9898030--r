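test_that("all co-minimal paths are kept and longer paths excluded", {
  # two parallel length-2 routes: both kept
  kb <- causal_kb(dplyr::bind_rows(
    edge_row("A", "B", 1), edge_row("B", "C", 1),
    edge_row("A", "D", 1), edge_row("D", "C", -1)))
  net <- build_naive_network(kb, "A", regulators = "C", max_len = 4)
  expect_setequal(net$nodes$protein, c("A", "B", "C", "D"))
  expect_equal(nrow(net$edges), 4)

  # a direct edge beats a length-2 detour
  kb2 <- causal_kb(dplyr::bind_rows(
    edge_row("A", "C", 1), edge_row("A", "B", 1), edge_row("B", "C", 1)))
  net2 <- build_naive_network(kb2, "A", regulators = "C", max_len = 4)
  expect_setequal(net2$nodes$protein, c("A", "C"))
  expect_equal(nrow(net2$edges), 1)

  expect_error(build_naive_network(kb, "ZZ", regulators = "C"), "absent")
})

test_that("naive network equals the brute-force minimal-path oracle", {
  for (seed in 1:12) {
    set.seed(seed)
    n <- sample(8:16, 1)
    prot <- c("SRC", paste0("N", seq_len(n - 1)))
    m <- sample((n - 1):(3 * n), 1)
    pairs <- expand.grid(u = prot, v = prot, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$u != pairs$v, ]
    pairs <- pairs[sample(nrow(pairs), min(m, nrow(pairs))), ]
    kb <- causal_kb(edge_row(pairs$u, pairs$v,
                             sample(c(-1L, 1L), nrow(pairs), TRUE)))
    targets <- sample(setdiff(unique(c(pairs$u, pairs$v)), "SRC"),
                      min(3, n - 1))
    if (!"SRC" %in% c(pairs$u, pairs$v)) next
    max_len <- 4
    net <- suppressWarnings(suppressMessages(
      build_naive_network(kb, "SRC", regulators = targets, max_len = max_len)))
    # oracle over the same pair classes: source->reg and reg->reg
    o1 <- oracle_naive(kb, "SRC", targets, max_len)
    o2 <- oracle_naive(kb, targets, targets, max_len)
    onodes <- sort(unique(c("SRC", o1$nodes, o2$nodes)))
    oedges <- sort(unique(c(o1$edges, o2$edges)))
    expect_equal(sort(net$nodes$protein), onodes)
    expect_equal(sort(paste(net$edges$source, net$edges$target)), oedges)
  }
})

test_that("naive networks grow monotonically with max_len", {
  set.seed(33)
  n <- 14
  prot <- c("SRC", paste0("N", 1:(n - 1)))
  pairs <- expand.grid(u = prot, v = prot, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$u != pairs$v, ]
  pairs <- pairs[sample(nrow(pairs), 30), ]
  kb <- causal_kb(edge_row(pairs$u, pairs$v, sample(c(-1L, 1L), 30, TRUE)))
  targets <- c("N1", "N2", "N3")
  prev <- character(0)
  for (L in 1:5) {
    net <- suppressWarnings(suppressMessages(
      build_naive_network(kb, "SRC", regulators = targets, max_len = L)))
    expect_true(all(prev %in% net$nodes$protein))
    prev <- net$nodes$protein
  }
})

test_that("every naive-network edge lies on a minimal path (no decorations)", {
  kb <- fixture_kb()
  net <- suppressMessages(build_naive_network(kb, "R",
                                              regulators = c("K1", "K2", "S1", "S2"),
                                              tfs = "T1", max_len = 4))
  o <- list(
    oracle_naive(kb, "R", c("K1", "K2", "S1", "S2"), 4),
    oracle_naive(kb, c("K1", "K2", "S1", "S2"), c("K1", "K2", "S1", "S2"), 4),
    oracle_naive(kb, c("K1", "K2", "S1", "S2"), "T1", 4))
  allowed <- unique(unlist(lapply(o, `[[`, "edges")))
  expect_true(all(paste(net$edges$source, net$edges$target) %in% allowed))
})

test_that("state annotation marks significant activities and fixes the source", {
  kb <- fixture_kb()
  net <- suppressMessages(build_naive_network(kb, "R",
                                              regulators = c("K1", "K2"),
                                              max_len = 3))
  acts <- structure(tibble::tibble(
    protein = c("K1", "K2", "ELSEWHERE"), role = "kinase",
    score = c(1, -1, 1), z = c(2.5, -3, 2), p_value = 0.01, fdr = 0.01,
    method = "combined", n_evidence = 4L,
    significant = c(TRUE, FALSE, TRUE), discordant = FALSE,
    flags = NA_character_), class = c("activity_table", class(tibble::tibble())))
  ann <- suppressMessages(annotate_states(net, acts, source_state = -1L))
  k1 <- ann$nodes[ann$nodes$protein == "K1", ]
  expect_true(k1$measured)
  expect_equal(k1$measured_sign, 1L)       # sign of z = +2.5
  k2 <- ann$nodes[ann$nodes$protein == "K2", ]
  expect_false(k2$measured)                # non-significant stays unmeasured
  expect_equal(ann$metadata$fixed, c(R = -1L))
})

test_that("network exports are readable text formats", {
  kb <- fixture_kb()
  net <- suppressMessages(build_naive_network(kb, "R", regulators = c("K1", "K2"),
                                              max_len = 3))
  sif <- withr::local_tempfile(fileext = ".sif")
  nodes <- withr::local_tempfile(fileext = ".tsv")
  write_sif(net, sif)
  write_node_attributes(net, nodes)
  lines <- readLines(sif)
  expect_true(all(grepl("^\\S+ [+-]1 \\S+$", lines)))
  back <- readr::read_tsv(nodes, show_col_types = FALSE)
  expect_setequal(back$name, net$nodes$protein)
})
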