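test_that("footprint raw score follows the signed-mean formula", {
  tab <- mt(paste0("g", 1:20), c(rep(1, 4), rnorm(16)))
  reg <- tibble::tibble(regulator = "TF1", role = "TF",
                        target = paste0("g", 1:4), sign = 1L)
  a <- footprint_activity(reg, tab, n_perm = 100, seed = 1)
  expect_equal(a$score, 4 / sqrt(4))        # +2.0 exactly
  reg$sign <- -1L
  b <- footprint_activity(reg, tab, n_perm = 100, seed = 1)
  expect_equal(b$score, -2.0)               # antisymmetry in edge signs
  expect_equal(a$n_evidence, 4L)

  few <- footprint_activity(reg[1:2, ], tab, n_perm = 100, seed = 1,
                            min_targets = 3)
  expect_true(is.na(few$score))
  expect_match(few$flags, "insufficient-evidence")
})

test_that("footprint score is linear in measurements and ignores non-targets", {
  set.seed(3)
  tab <- mt(paste0("g", 1:50), rnorm(50))
  reg <- tibble::tibble(regulator = "X", role = "TF",
                        target = paste0("g", 1:6),
                        sign = sample(c(-1L, 1L), 6, TRUE))
  s1 <- footprint_activity(reg, tab, n_perm = 100, seed = 9)$score
  tab2 <- tab; tab2$log2fc <- tab2$log2fc * 2
  expect_equal(footprint_activity(reg, tab2, n_perm = 100, seed = 9)$score,
               2 * s1)
  tab3 <- tab; tab3$log2fc[7:50] <- rnorm(44)  # perturb non-targets only
  expect_equal(footprint_activity(reg, tab3, n_perm = 100, seed = 9)$score, s1)
})

test_that("footprint detects a planted regulator effect in most repetitions", {
  hits <- 0
  for (rep in 1:100) {
    set.seed(rep)
    tab <- mt(paste0("g", 1:1000), rnorm(1000))
    targets <- sample(tab$analyte_id, 10)
    tab$log2fc[match(targets, tab$analyte_id)] <-
      tab$log2fc[match(targets, tab$analyte_id)] + 1
    reg <- tibble::tibble(regulator = "X", role = "TF", target = targets,
                          sign = 1L)
    z <- footprint_activity(reg, tab, n_perm = 100, seed = rep)$z
    if (z > 0) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("regulatory-site score signs follow site effects", {
  ph <- mt(c("X_S1", "CDK1_Y15", "Y_S2", "Y_T3"), c(2, 1.5, 1, 1),
           layer = "phosphosite")
  sites <- tibble::tibble(protein = c("X", "CDK1", "Y", "Y"),
                          residue = c("S1", "Y15", "S2", "T3"),
                          effect = c(1L, -1L, 1L, -1L))
  expect_equal(phospho_score("X", sites, ph, n_perm = 100, seed = 1)$score, 2)
  # hyperphosphorylation of an inhibitory site lowers activity
  expect_equal(phospho_score("CDK1", sites, ph, n_perm = 100, seed = 1)$score,
               -1.5)
  # opposite-effect sites at equal fold-change cancel
  expect_equal(phospho_score("Y", sites, ph, n_perm = 100, seed = 1)$score, 0)
  none <- phospho_score("Z", sites, ph, n_perm = 100, seed = 1)
  expect_match(none$flags, "insufficient-evidence")

  # antisymmetry: flipping every site effect flips the score exactly
  set.seed(11)
  for (i in 1:20) {
    n <- sample(1:5, 1)
    ids <- paste0("P", i, "_S", seq_len(n))
    ph2 <- mt(c(ids, paste0("bg_", i, "_S", 1:30)), rnorm(n + 30),
              layer = "phosphosite")
    st <- tibble::tibble(protein = paste0("P", i), residue = paste0("S", seq_len(n)),
                         effect = sample(c(-1L, 1L), n, TRUE))
    st_flip <- dplyr::mutate(st, effect = -effect)
    s1 <- phospho_score(paste0("P", i), st, ph2, n_perm = 100, seed = i)$score
    s2 <- phospho_score(paste0("P", i), st_flip, ph2, n_perm = 100, seed = i)$score
    expect_equal(s2, -s1)
  }
})

test_that("score combination averages z, is commutative and flags discordance", {
  mk <- function(z, method) {
    out <- footprint_activity(
      tibble::tibble(regulator = "K", role = "kinase",
                     target = paste0("s", 1:4), sign = 1L),
      mt(paste0("s", 1:4), rep(1, 4)),
      n_perm = 100, seed = 1)
    out$z <- z; out$method <- method; out
  }
  ab <- combine_activities(mk(2, "footprint"), mk(2, "phosphoscore"))
  expect_equal(ab$z, 2)
  expect_equal(ab$method, "combined")
  expect_false(ab$discordant)

  disc <- combine_activities(mk(2, "footprint"), mk(-2, "phosphoscore"))
  expect_equal(disc$z, 0)
  expect_true(disc$discordant)

  # commutativity over an exhaustive small sweep
  for (za in c(-2, -0.5, 0.5, 2)) {
    for (zb in c(-2, -0.5, 0.5, 2)) {
      x <- combine_activities(mk(za, "footprint"), mk(zb, "phosphoscore"))
      y <- combine_activities(mk(zb, "phosphoscore"), mk(za, "footprint"))
      expect_equal(x$z, y$z)
      expect_equal(x$p_value, y$p_value)
      expect_equal(x$discordant, y$discordant)
    }
  }
  # pass-through when only one method scored
  solo <- mk(1.3, "footprint")
  expect_equal(combine_activities(solo, NULL)$method, "footprint")
  expect_error(combine_activities(solo, solo), "same-method")
})

test_that("activity_table scores every eligible protein with correct roles", {
  p <- generator_params(seed = 21, n_nodes = 25, n_tfs = 5, n_kinases = 6,
                        n_phosphatases = 2, noise_sd = 0.2)
  tr <- generate_truth(p)
  tabs <- suppressWarnings(lapply(tr$tables, differential_stats))
  acts <- suppressMessages(activity_table(
    tr$kb, tabs$transcriptome, tabs$proteome, tabs$phospho,
    n_perm = 200, seed = 4))
  expect_true(all(acts$role[startsWith(acts$protein, "TF")] == "TF"))
  expect_true(all(acts$role[startsWith(acts$protein, "KIN")] == "kinase"))
  expect_true(all(acts$role[startsWith(acts$protein, "PHO")] == "phosphatase"))
  expect_true(any(acts$method == "combined"))
  expect_true(all(acts$fdr[!is.na(acts$fdr)] >= acts$p_value[!is.na(acts$fdr)] - 1e-12))

  # degradation path: no phospho layer -> only TFs carry scores,
  # kinases/phosphatases are flagged insufficient-evidence
  tf_only <- suppressMessages(activity_table(
    tr$kb, tabs$transcriptome, NULL, NULL, n_perm = 200, seed = 4))
  expect_true(all(tf_only$role[!is.na(tf_only$z)] == "TF"))
  kin_rows <- tf_only[tf_only$role %in% c("kinase", "phosphatase"), ]
  expect_true(all(kin_rows$flags == "insufficient-evidence"))
})

test_that("profile comparison recovers correlation and discordance lists", {
  mk_acts <- function(z, sig) {
    structure(tibble::tibble(
      protein = paste0("P", seq_along(z)), role = "kinase", score = z, z = z,
      p_value = 0.01, fdr = 0.01, method = "combined",
      n_evidence = 5L, significant = sig, discordant = FALSE,
      flags = NA_character_),
      class = c("activity_table", class(tibble::tibble())))
  }
  z <- c(1, -2, 3, -1.5)
  ident <- compare_activity_profiles(mk_acts(z, TRUE), mk_acts(z, TRUE))
  expect_equal(ident$r, 1)
  expect_length(ident$opposite, 0)

  z2 <- z; z2[2] <- -z2[2]
  flip <- compare_activity_profiles(mk_acts(z, TRUE), mk_acts(z2, TRUE))
  expect_equal(flip$opposite, "P2")

  sig2 <- c(TRUE, TRUE, FALSE, TRUE)
  excl <- compare_activity_profiles(mk_acts(z, TRUE), mk_acts(z, sig2))
  expect_equal(excl$exclusive_a, "P3")

  # sampling behaviour at known correlation 0.9, n = 100
  set.seed(99)
  za <- rnorm(100)
  zb <- 0.9 * za + sqrt(1 - 0.81) * rnorm(100)
  est <- compare_activity_profiles(mk_acts(za, TRUE), mk_acts(zb, TRUE))$r
  expect_lt(abs(est - 0.9), 0.06)
  expect_error(compare_activity_profiles(mk_acts(z[1:2], TRUE),
                                         mk_acts(z[1:2], TRUE)),
               "fewer than 3")
})

test_that("permutation p-values are calibrated on pure noise", {
  set.seed(5)
  tab <- mt(paste0("g", 1:800), rnorm(800))
  ps <- vapply(1:200, function(i) {
    set.seed(2000 + i)
    reg <- tibble::tibble(regulator = "R", role = "TF",
                          target = sample(tab$analyte_id, 8),
                          sign = sample(c(-1L, 1L), 8, TRUE))
    footprint_activity(reg, tab, n_perm = 200, seed = i)$p_value
  }, numeric(1))
  # loose 3-sigma binomial band around 0.05 at n = 200
  expect_lt(abs(mean(ps <= 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 200) + 0.005)
})
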