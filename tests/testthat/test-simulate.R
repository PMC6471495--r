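test_that("simulation is deterministic under a fixed seed and varies across seeds", {
  cfg <- sim_config(n_per_group = c(M = 4, G = 4, WI = 4), n_loci = 100,
                    missing_rate = 0.05, n_diagnostic_per_race = 2, seed = 11)
  a <- simulate_panel(cfg)
  b <- simulate_panel(cfg)
  expect_identical(a$gm$dosage, b$gm$dosage)
  expect_identical(a$truth$race_freqs, b$truth$race_freqs)
  cfg2 <- cfg; cfg2$seed <- 12L
  expect_false(identical(simulate_panel(cfg2)$gm$dosage, a$gm$dosage))
})

test_that("divergence_F = 0 collapses the race frequencies onto the ancestral", {
  sim <- simulate_panel(sim_config(n_per_group = c(M = 3, G = 3, WI = 3),
                                   n_loci = 50, divergence_F = 0, seed = 2))
  f <- sim$truth$race_freqs
  expect_equal(f[, "M"], f[, "G"])
  expect_equal(f[, "M"], f[, "WI"])
})

test_that("planted diagnostic loci are fixed differences with the stated pattern", {
  sim <- simulate_panel(sim_config(
    n_per_group = c(M = 4, G = 4, WI = 4, GxM = 4, GxWI = 4), n_loci = 200,
    n_diagnostic_per_race = 3, hybrid_mode = "f1", seed = 3))
  dl <- sim$truth$diagnostic_loci
  expect_equal(nrow(dl), 9)
  expect_equal(unname(table(dl$race)[c("M", "G", "WI")]), rep(3L, 3),
               ignore_attr = TRUE)
  d <- dosage(sim$gm)
  for (k in seq_len(nrow(dl))) {
    own_dose <- if (dl$allele[k] == "alt") 2L else 0L
    own <- d[grepl(paste0("^", dl$race[k], "_"), rownames(d)), dl$locus_id[k]]
    expect_true(all(own == own_dose))
    pure_other <- grepl("^(M|G|WI)_", rownames(d)) &
      !grepl(paste0("^", dl$race[k], "_"), rownames(d))
    expect_true(all(d[pure_other, dl$locus_id[k]] == 2L - own_dose))
    # freq-level invariant: fixed at 1 for the race, 0 elsewhere
    f <- sim$truth$race_freqs[dl$locus_id[k], ]
    target <- if (dl$allele[k] == "alt") 1 else 0
    expect_equal(unname(f[dl$race[k]]), target)
    expect_equal(unname(f[setdiff(c("M", "G", "WI"), dl$race[k])]),
                 rep(1 - target, 2))
  }
})

test_that("realised missingness is within 3 binomial SDs of the nominal rate", {
  rate <- 0.07
  sim <- simulate_panel(sim_config(n_per_group = c(M = 10, G = 10),
                                   n_loci = 500, missing_rate = rate, seed = 4))
  n <- length(sim$gm$dosage)
  expect_lt(abs(mean(is.na(sim$gm$dosage)) - rate),
            3 * sqrt(rate * (1 - rate) / n))
})

test_that("realised divergence tracks divergence_F monotonically and matches F=0.2", {
  Fs <- c(0.05, 0.1, 0.2, 0.4)
  mean_fst <- vapply(Fs, function(Fv) {
    mean(vapply(1:3, function(s) {
      sim <- simulate_panel(sim_config(n_per_group = c(M = 20, G = 20, WI = 20),
                                       n_loci = 800, divergence_F = Fv,
                                       seed = s, guard_diagnostic = FALSE))
      wc_fst(sim$gm, setNames(sim$panel$race_label, sim$panel$sample_id))
    }, 0))
  }, 0)
  expect_equal(order(mean_fst), 1:4)  # strictly increasing in F
  # spec-level recovery at F = 0.2: WC estimate within binomial tolerance
  sim <- simulate_panel(sim_config(n_per_group = c(M = 30, G = 30, WI = 30),
                                   n_loci = 5000, divergence_F = 0.2, seed = 1))
  fst <- wc_fst(sim$gm, setNames(sim$panel$race_label, sim$panel$sample_id))
  expect_gt(fst, 0.17)
  expect_lt(fst, 0.23)
})

test_that("mimic_paper_panel reproduces the 21-accession design", {
  sim <- mimic_paper_panel(seed = 9, n_loci = 300)
  expect_equal(n_samples(sim$gm), 21)
  expect_equal(as.vector(table(sim$panel$race_label)[c("M", "G", "WI", "GxM", "GxWI")]),
               c(2L, 2L, 3L, 7L, 7L))
  expect_true(all(c("Hass", "Fuerte", "Simmonds", "Duke7") %in%
                  sim$panel$sample_id))
  # every GxWI accession is WI-dominant, within the sampled range
  q_wi <- sim$truth$sample_q[sim$panel$race_label == "GxWI", "WI"]
  expect_true(all(q_wi > 0.5 & q_wi <= 0.84))
  # reproducibility
  sim2 <- mimic_paper_panel(seed = 9, n_loci = 300)
  expect_identical(sim$gm$dosage, sim2$gm$dosage)
})

test_that("unknown accessions are appended as truly-GxWI samples", {
  sim <- mimic_paper_panel(seed = 5, n_loci = 200, n_unknown = 4)
  expect_equal(n_samples(sim$gm), 25)
  unk <- sim$panel$sample_id[sim$panel$race_label == "UNKNOWN"]
  expect_equal(length(unk), 4)
  expect_true(all(sim$truth$sample_q[unk, "WI"] > 0.5))
  expect_true(all(sim$truth$sample_q[unk, "M"] == 0))
})

test_that("infeasible configurations are rejected", {
  expect_error(sim_config(n_loci = 5, n_diagnostic_per_race = 2), "exceeds")
  expect_error(sim_config(divergence_F = 1), "divergence_F")
  expect_error(sim_config(ancestral_freq_range = c(0, 0.5)), "interval")
  expect_error(sim_config(n_per_group = c(X = 3)), "classes among")
})
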