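#' Parameters of the synthetic ground-truth generator
#'
#' Bundles and validates the knobs of [generate_truth()].  Defaults
#' describe the benchmark regime used throughout the package's own
#' validation: a 40-node signed signaling network downstream of one
#' inhibited receptor, strong but noisy effects (mean |log2FC| 2.0,
#' replicate noise SD 0.5, 4 replicates per group), and a prior
#' containing 10% sign-corrupted edges.
#'
#' @param n_nodes Total protein nodes including the receptor.
#' @param n_tfs,n_kinases,n_phosphatases Role counts; the remainder
#'   (minus the receptor) become substrates.
#' @param edge_density Directed edge density of the knowledge base; the
#'   spanning arborescence is always present, extra edges fill up to the
#'   density.
#' @param effect_size Mean |log2FC| induced on a true target.
#' @param noise_sd Replicate noise SD on log2 intensities.
#' @param n_replicates Replicates per group.
#' @param seed Mandatory integer seed.
#' @param frac_inconsistent Fraction of extra edges whose annotated sign
#'   contradicts the true states (curation-noise edges; they contribute
#'   no real signal).
#' @param n_tf_targets Transcript targets per TF.
#' @param n_null_genes,n_null_sites Unregulated analytes mixed into the
#'   tables (permutation-null background).
#' @param protein_shift_sd SD of host-protein abundance shifts (exercises
#'   phospho-by-protein normalization).
#' @param dropout Fraction of transcript/phosphosite analytes randomly
#'   removed from the emitted tables (MS coverage gaps).
#' @return A validated list of class `generator_params`.
#' @export
generator_params <- function(n_nodes = 40, n_tfs = 8, n_kinases = 10,
                             n_phosphatases = 4, edge_density = 0.05,
                             effect_size = 2.0, noise_sd = 0.5,
                             n_replicates = 4, seed,
                             frac_inconsistent = 0.1, n_tf_targets = 8,
                             n_null_genes = 200, n_null_sites = 150,
                             protein_shift_sd = 0.5, dropout = 0) {
  if (missing(seed)) sc_abort("generator seed is mandatory")
  n_sub <- n_nodes - 1 - n_tfs - n_kinases - n_phosphatases
  stopifnot(n_nodes > 3, n_tfs >= 1, n_kinases >= 1, n_phosphatases >= 0,
            n_sub >= 0, edge_density > 0, edge_density <= 1,
            effect_size > 0, noise_sd >= 0, n_replicates >= 2,
            frac_inconsistent >= 0, frac_inconsistent <= 1,
            dropout >= 0, dropout < 1)
  structure(list(n_nodes = n_nodes, n_tfs = n_tfs, n_kinases = n_kinases,
                 n_phosphatases = n_phosphatases, n_substrates = n_sub,
                 edge_density = edge_density, effect_size = effect_size,
                 noise_sd = noise_sd, n_replicates = n_replicates,
                 seed = as.integer(seed),
                 frac_inconsistent = frac_inconsistent,
                 n_tf_targets = n_tf_targets, n_null_genes = n_null_genes,
                 n_null_sites = n_null_sites,
                 protein_shift_sd = protein_shift_sd, dropout = dropout),
            class = "generator_params")
}

# --- skeleton: topology, signs, sites, gene map; no measurement noise ----

build_skeleton <- function(params) {
  p <- params
  withr::with_seed(p$seed, {
    receptor <- "RCPT"
    kinases <- sprintf("KIN%02d", seq_len(p$n_kinases))
    phosphatases <- if (p$n_phosphatases > 0)
      sprintf("PHO%02d", seq_len(p$n_phosphatases)) else character(0)
    tfs <- sprintf("TF%02d", seq_len(p$n_tfs))
    subs <- if (p$n_substrates > 0)
      sprintf("SUB%02d", seq_len(p$n_substrates)) else character(0)
    enzymes <- sample(c(kinases, phosphatases))
    nodes <- c(receptor, enzymes, sample(c(subs, tfs)))
    role <- c("other",
              ifelse(startsWith(enzymes, "KIN"), "kinase", "phosphatase"),
              ifelse(startsWith(nodes[-seq_len(1 + length(enzymes))], "TF"),
                     "TF", "other"))
    names(role) <- nodes

    site_counter <- setNames(integer(length(nodes)), nodes)
    next_residue <- function(v) {
      site_counter[[v]] <<- site_counter[[v]] + 1L
      paste0(c("S", "T", "Y")[(site_counter[[v]] - 1L) %% 3L + 1L],
             100L + site_counter[[v]])
    }

    edges <- list()
    sites <- list()
    parent <- setNames(rep(NA_character_, length(nodes)), nodes)
    # spanning arborescence: enzymes hang off the receptor or earlier
    # enzymes; substrates and TFs hang off enzymes
    seen_enzymes <- character(0)
    add_edge <- function(u, v, mechanism, sign, residue = NA_character_) {
      edges[[length(edges) + 1L]] <<- tibble::tibble(
        source = u, target = v, sign = as.integer(sign),
        mechanism = mechanism, residue = residue,
        provenance = "synthetic")
    }
    for (v in nodes[-1]) {
      if (role[[v]] %in% c("kinase", "phosphatase")) {
        u <- if (length(seen_enzymes) == 0) receptor else
          sample(c(receptor, seen_enzymes), 1)
        seen_enzymes <- c(seen_enzymes, v)
      } else {
        u <- sample(seen_enzymes, 1)
      }
      parent[[v]] <- u
      mech <- if (role[[u]] == "phosphatase") "dephosphorylation" else "phosphorylation"
      site_effect <- sample(c(-1L, 1L), 1)
      e_sign <- if (mech == "phosphorylation") site_effect else -site_effect
      res <- next_residue(v)
      add_edge(u, v, mech, e_sign, res)
      sites[[length(sites) + 1L]] <- tibble::tibble(
        protein = v, residue = res, effect = site_effect,
        provenance = "synthetic")
    }
    tree <- dplyr::bind_rows(edges)

    # true states: inhibited receptor, signs telescope down the tree
    state <- setNames(rep(NA_integer_, length(nodes)), nodes)
    state[[receptor]] <- -1L
    depth <- setNames(rep(NA_integer_, length(nodes)), nodes)
    depth[[receptor]] <- 0L
    pending <- nodes[-1]
    while (length(pending) > 0) {
      for (v in pending) {
        u <- parent[[v]]
        if (!is.na(state[[u]])) {
          e <- tree$sign[tree$source == u & tree$target == v][1]
          state[[v]] <- e * state[[u]]
          depth[[v]] <- depth[[u]] + 1L
        }
      }
      pending <- nodes[is.na(state)]
    }

    # extra edges up to the requested density; TFs are never targets so
    # transcription-factor regulation stays on the curated route
    n_total <- round(p$edge_density * length(nodes) * (length(nodes) - 1))
    n_extra <- max(0, n_total - nrow(tree))
    candidates_u <- nodes[role[nodes] != "TF"]
    have <- paste(tree$source, tree$target)
    extra <- list()
    extra_sites <- list()
    tries <- 0
    while (length(extra) < n_extra && tries < 50 * n_extra + 100) {
      tries <- tries + 1
      u <- sample(candidates_u, 1)
      v <- sample(nodes[role[nodes] != "TF" & nodes != receptor], 1)
      if (u == v || paste(u, v) %in% have) next
      have <- c(have, paste(u, v))
      consistent <- runif(1) >= p$frac_inconsistent
      e_sign <- if (consistent) state[[u]] * state[[v]] else
        -state[[u]] * state[[v]]
      if (role[[u]] %in% c("kinase", "phosphatase")) {
        mech <- if (role[[u]] == "kinase") "phosphorylation" else "dephosphorylation"
        site_effect <- if (mech == "phosphorylation") e_sign else -e_sign
        res <- next_residue(v)
        extra[[length(extra) + 1L]] <- tibble::tibble(
          source = u, target = v, sign = e_sign, mechanism = mech,
          residue = res, provenance = "synthetic",
          real = consistent)
        extra_sites[[length(extra_sites) + 1L]] <- tibble::tibble(
          protein = v, residue = res, effect = site_effect,
          provenance = "synthetic")
      } else {
        extra[[length(extra) + 1L]] <- tibble::tibble(
          source = u, target = v, sign = e_sign, mechanism = "binding",
          residue = NA_character_, provenance = "synthetic",
          real = consistent)
      }
    }
    extra <- if (length(extra)) dplyr::bind_rows(extra) else
      tibble::tibble(source = character(), target = character(),
                     sign = integer(), mechanism = character(),
                     residue = character(), provenance = character(),
                     real = logical())

    # transcriptional programs: fresh genes per TF
    gene_id <- 0L
    tf_edges <- list()
    for (tf in tfs) {
      for (j in seq_len(p$n_tf_targets)) {
        gene_id <- gene_id + 1L
        tf_edges[[length(tf_edges) + 1L]] <- tibble::tibble(
          source = tf, target = sprintf("G%04d", gene_id),
          sign = sample(c(-1L, 1L), 1), mechanism = "transcriptional",
          residue = NA_character_, provenance = "synthetic")
      }
    }
    tf_edges <- dplyr::bind_rows(tf_edges)

    # host-protein abundance shifts (state-independent nuisance)
    delta <- setNames(rnorm(length(nodes), 0, p$protein_shift_sd), nodes)

    # null phosphosites: extra unregulated residues on random proteins
    null_sites <- character(0)
    null_hosts <- character(0)
    hostable <- setdiff(nodes, receptor)
    for (i in seq_len(p$n_null_sites)) {
      v <- sample(hostable, 1)
      null_hosts <- c(null_hosts, v)
      null_sites <- c(null_sites, paste0(v, "_", next_residue(v)))
    }

    list(nodes = nodes, role = role, parent = parent, depth = depth,
         state = state, tree = tree, extra = extra, tf_edges = tf_edges,
         sites = dplyr::bind_rows(c(sites, extra_sites)),
         delta = delta, null_sites = null_sites, null_hosts = null_hosts,
         receptor = receptor, tfs = tfs, params = p)
  })
}

# re-propagate states, negating each flip node after its parent signal
propagate_states <- function(sk, flips = character(0)) {
  state <- setNames(rep(NA_integer_, length(sk$nodes)), sk$nodes)
  state[[sk$receptor]] <- -1L
  if (sk$receptor %in% flips) sc_abort("cannot flip the source node")
  pending <- sk$nodes[-1]
  while (length(pending) > 0) {
    for (v in pending) {
      u <- sk$parent[[v]]
      if (!is.na(state[[u]])) {
        e <- sk$tree$sign[sk$tree$source == u & sk$tree$target == v][1]
        s <- e * state[[u]]
        state[[v]] <- if (v %in% flips) -s else s
      }
    }
    pending <- sk$nodes[is.na(state)]
  }
  state
}

skeleton_kb <- function(sk, augment = NULL) {
  protein_edges <- dplyr::bind_rows(
    sk$tree,
    sk$extra[, setdiff(names(sk$extra), "real"), drop = FALSE],
    augment)
  causal_kb(dplyr::bind_rows(protein_edges, sk$tf_edges),
            sites = sk$sites,
            roles = tibble::tibble(protein = sk$nodes,
                                   role = unname(sk$role[sk$nodes])))
}

emit_tables <- function(sk, state, params) {
  p <- params
  k <- p$n_replicates
  reps <- function(true_lfc) {
    n <- length(true_lfc)
    eps_c <- matrix(rnorm(n * k, 0, p$noise_sd), n, k)
    eps_t <- matrix(rnorm(n * k, 0, p$noise_sd), n, k)
    list(ctrl = lapply(seq_len(n), function(i) unname(eps_c[i, ])),
         trt = lapply(seq_len(n), function(i) unname(true_lfc[i] + eps_t[i, ])))
  }
  drop_some <- function(tab) {
    if (p$dropout <= 0) return(tab)
    keep <- runif(nrow(tab)) >= p$dropout
    tab[keep, , drop = FALSE]
  }
  withr::with_seed(p$seed + 1L, {
    # transcriptome: TF programs + unregulated genes
    te <- sk$tf_edges
    tr_true <- state[te$source] * te$sign * p$effect_size
    null_genes <- sprintf("N%04d", seq_len(p$n_null_genes))
    tr_ids <- c(te$target, null_genes)
    tr_true <- c(tr_true, rep(0, p$n_null_genes))
    rr <- reps(tr_true)
    transcriptome <- drop_some(tibble::tibble(
      analyte_id = tr_ids, log2fc = tr_true,
      reps_control = rr$ctrl, reps_treated = rr$trt))

    # proteome: every protein node with its abundance shift
    pr_true <- unname(sk$delta[sk$nodes])
    rr <- reps(pr_true)
    proteome <- tibble::tibble(analyte_id = sk$nodes, log2fc = pr_true,
                               reps_control = rr$ctrl, reps_treated = rr$trt)

    # phosphoproteome: one analyte per annotated phospho event (real
    # edges carry upstream signal, curation-noise edges do not) plus
    # unregulated sites; all ride on the host-protein shift
    pe <- dplyr::bind_rows(
      dplyr::mutate(sk$tree, real = TRUE),
      sk$extra)
    pe <- pe[pe$mechanism %in% c("phosphorylation", "dephosphorylation"), ,
             drop = FALSE]
    event_dir <- ifelse(pe$mechanism == "phosphorylation", 1L, -1L)
    ph_true <- ifelse(pe$real, event_dir * state[pe$source] * p$effect_size, 0) +
      sk$delta[pe$target]
    ph_ids <- paste0(pe$target, "_", pe$residue)
    ph_ids <- c(ph_ids, sk$null_sites)
    ph_true <- unname(c(ph_true, sk$delta[sk$null_hosts]))
    rr <- reps(ph_true)
    phospho <- drop_some(tibble::tibble(
      analyte_id = ph_ids, log2fc = ph_true,
      reps_control = rr$ctrl, reps_treated = rr$trt))
  })
  list(
    transcriptome = measurement_table(transcriptome, "transcript", "synthetic"),
    proteome = measurement_table(proteome, "protein", "synthetic"),
    phospho = measurement_table(phospho, "phosphosite", "synthetic"))
}

#' Generate a synthetic ground truth
#'
#' Samples a connected signed digraph rooted at an inhibited receptor
#' (state -1), propagates true node states along its spanning
#' arborescence, adds extra prior edges (a configurable fraction with
#' corrupted signs), and emits replicate-level transcriptome, proteome
#' and phosphoproteome tables whose expected fold-changes follow the
#' stated effect model: every real regulatory event moves its readout by
#' `state * effect_size` (direction set by edge sign or phospho event
#' direction), phosphosites additionally ride on state-independent
#' host-protein abundance shifts, and replicate noise is Gaussian.
#'
#' @param params A [generator_params()].
#' @return List of class `synthetic_truth`: `kb` ([causal_kb()]),
#'   `true_states` (named -1/+1 vector over protein nodes), `tables`
#'   (list of three [measurement_table()]s), `source`, `params`.
#' @export
generate_truth <- function(params) {
  sk <- build_skeleton(params)
  state <- sk$state
  kb <- skeleton_kb(sk)
  tables <- emit_tables(sk, state, params)
  structure(list(kb = kb, true_states = state, tables = tables,
                 source = sk$receptor, params = params, skeleton = sk),
            class = "synthetic_truth")
}

#' Generate a matched condition pair with planted state flips
#'
#' Produces two ground truths over one shared knowledge base and one
#' shared noise stream: the second condition's states equal the first's
#' except that each listed node is negated (and its descendants
#' re-propagated -- flip leaf-tier nodes such as TFs when the planted
#' difference should be exactly the listed set).  For every flipped node
#' the shared prior is augmented with one depth-matched alternative
#' route of the opposite sign, so the flipped state is reachable
#' sign-consistently in both conditions, as contradictory
#' context-dependent routes in curated resources are.
#'
#' @param params A [generator_params()].
#' @param flip_nodes Protein nodes to flip (not the receptor).
#' @return List with `a` and `b` (`synthetic_truth`s), `flipped` (the
#'   planted list) and `diff_nodes` (all nodes whose true states
#'   differ, including re-propagated descendants).
#' @export
make_condition_pair <- function(params, flip_nodes) {
  sk <- build_skeleton(params)
  missing_nodes <- setdiff(flip_nodes, sk$nodes)
  if (length(missing_nodes) > 0) {
    sc_abort("flip node(s) not in network: %s", paste(missing_nodes, collapse = ", "))
  }
  state1 <- propagate_states(sk)
  state2 <- propagate_states(sk, flips = flip_nodes)
  diff_nodes <- sk$nodes[state1[sk$nodes] != state2[sk$nodes]]
  stable <- setdiff(sk$nodes, diff_nodes)

  base_kb <- skeleton_kb(sk)
  g <- kb_igraph(base_kb, exclude_ambiguous = TRUE)
  dist0 <- igraph::distances(g, v = sk$receptor, mode = "out")[1, ]
  have <- paste(base_kb$edges$source, base_kb$edges$target)
  augment <- list()
  for (v in flip_nodes) {
    d_v <- dist0[[v]]
    cand <- stable[!is.na(dist0[stable]) & is.finite(dist0[stable]) &
                     dist0[stable] == d_v - 1 & stable != sk$parent[[v]] &
                     !paste(stable, v) %in% have]
    if (length(cand) == 0) {
      sc_abort("no depth-matched alternative parent for flip node %s", v)
    }
    u <- cand[1]
    have <- c(have, paste(u, v))
    augment[[length(augment) + 1L]] <- tibble::tibble(
      source = u, target = v, sign = as.integer(state2[[v]] * state2[[u]]),
      mechanism = "binding", residue = NA_character_,
      provenance = "synthetic-alt-route")
  }
  augment <- dplyr::bind_rows(augment)
  kb <- skeleton_kb(sk, augment = augment)

  truth <- function(state) {
    structure(list(kb = kb, true_states = state,
                   tables = emit_tables(sk, state, params),
                   source = sk$receptor, params = params, skeleton = sk),
              class = "synthetic_truth")
  }
  list(a = truth(state1), b = truth(state2), flipped = flip_nodes,
       diff_nodes = diff_nodes)
}

#' Write a synthetic truth as a self-contained run directory
#'
#' Emits the exact TSV dialects the package readers consume:
#' measurement tables with replicate columns, the knowledge base in the
#' `signor_tsv` dialect with site and role tables, the true states and
#' the generator parameters.
#'
#' @param truth A `synthetic_truth`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_truth_dir <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_measurement_table(truth$tables$transcriptome,
                          file.path(dir, "transcriptome.tsv"))
  write_measurement_table(truth$tables$proteome, file.path(dir, "proteome.tsv"))
  write_measurement_table(truth$tables$phospho, file.path(dir, "phospho.tsv"))
  write_causal_kb(truth$kb, file.path(dir, "kb_edges.tsv"),
                  file.path(dir, "kb_sites.tsv"), file.path(dir, "kb_roles.tsv"))
  readr::write_tsv(tibble::tibble(PROTEIN = names(truth$true_states),
                                  STATE = unname(truth$true_states)),
                   file.path(dir, "true_states.tsv"), progress = FALSE)
  yaml::write_yaml(c(list(source = truth$source),
                     unclass(truth$params)),
                   file.path(dir, "params.yaml"))
  invisible(dir)
}
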