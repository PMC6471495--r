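test_that("reference frequencies are clamped pure-accession tallies", {
  d <- rbind(M1 = c(2L, 0L, 1L), M2 = c(2L, 0L, 1L),
             G1 = c(0L, 1L, 0L), G2 = c(0L, 0L, 0L),
             W1 = c(0L, 2L, 2L), W2 = c(0L, 2L, NA))
  colnames(d) <- paste0("l", 1:3)
  gm <- genotype_matrix(d)
  panel <- sample_panel(rownames(d), c("M", "M", "G", "G", "WI", "WI"))
  rf <- reference_freqs(gm, panel)
  expect_equal(unname(rf[, "M"]), c(0.999, 0.001, 0.5))   # fixed loci clamped
  expect_equal(unname(rf["l2", "G"]), 0.25)
  expect_equal(unname(rf["l3", "WI"]), 0.999)              # one typed sample
  expect_error(reference_freqs(gm, sample_panel(rownames(d),
               c("G", "G", "G", "G", "WI", "WI"))), "race M")
})

test_that("reference frequencies track the simulation truth", {
  sim <- simulate_panel(sim_config(n_per_group = c(M = 25, G = 25, WI = 25),
                                   n_loci = 400, divergence_F = 0.2, seed = 6))
  rf <- reference_freqs(sim$gm, sim$panel)
  # binomial error at 2n = 50 draws: RMSE well under 0.1
  err <- abs(rf - pmin(pmax(sim$truth$race_freqs, 1e-3), 1 - 1e-3))
  expect_lt(mean(err), 0.06)
  expect_lt(max(err), 0.35)
})

test_that("EM recovers pure and F1 ancestry and is monotone", {
  sim <- simulate_panel(sim_config(
    n_per_group = c(M = 8, G = 8, WI = 8, GxM = 8, GxWI = 8), n_loci = 2000,
    divergence_F = 0.2, hybrid_mode = "f1", seed = 13))
  rf <- reference_freqs(sim$gm, sim$panel)
  e_pure <- estimate_q(sim$gm, rf, "M_01")
  expect_gte(e_pure$q[["M"]], 0.95)
  expect_true(e_pure$monotone)
  expect_equal(sum(e_pure$q), 1, tolerance = 1e-8)
  e_hyb <- estimate_q(sim$gm, rf, "GxWI_01")
  expect_equal(unname(e_hyb$q[c("G", "WI")]), c(0.5, 0.5), tolerance = 0.1)
  expect_lt(e_hyb$q[["M"]], 0.1)
})

test_that("q estimates are locus-order invariant and label-equivariant", {
  sim <- simulate_panel(sim_config(
    n_per_group = c(M = 6, G = 6, WI = 6, GxWI = 6), n_loci = 600,
    divergence_F = 0.25, seed = 14))
  rf <- reference_freqs(sim$gm, sim$panel)
  e1 <- estimate_q(sim$gm, rf, "GxWI_03")
  set.seed(4)
  perm <- sample(locus_ids(sim$gm))
  e2 <- estimate_q(subset_gm(sim$gm, loci = perm), rf[perm, ], "GxWI_03")
  expect_equal(e2$q, e1$q, tolerance = 1e-6)
  # permuting the reference columns permutes q
  e3 <- estimate_q(sim$gm, rf[, c("WI", "M", "G")], "GxWI_03")
  expect_equal(unname(e3$q[c("M", "G", "WI")]), unname(e1$q[c("M", "G", "WI")]),
               tolerance = 1e-6)
})

test_that("identical references give the uniform (unidentifiable) solution", {
  set.seed(5)
  L <- 200
  p <- runif(L, 0.2, 0.8)
  rf <- cbind(M = p, G = p, WI = p)
  rownames(rf) <- sprintf("L%03d", 1:L)
  d <- matrix(rbinom(L, 2, p), 1, L,
              dimnames = list("s1", rownames(rf)))
  gm <- genotype_matrix(d)
  e <- estimate_q(gm, rf, "s1")
  expect_equal(unname(e$q), rep(1 / 3, 3), tolerance = 1e-9)
  expect_error(estimate_q(gm, rf[1:30, ], "s1"), "usable loci")
})

test_that("recovery error shrinks as loci are added", {
  errs <- vapply(c(200, 500, 2000), function(L) {
    e <- numeric(0)
    for (s in 1:6) {  # enough replication for the directional comparison
      sim <- simulate_panel(sim_config(
        n_per_group = c(M = 8, G = 8, WI = 8, GxWI = 8), n_loci = L,
        divergence_F = 0.2, hybrid_mode = "f1", seed = 500 + s))
      rf <- reference_freqs(sim$gm, sim$panel)
      qt <- estimate_q_all(sim$gm, rf, samples = sprintf("GxWI_%02d", 1:8))
      e <- c(e, abs(as.matrix(qt[, c("q_M", "q_G", "q_WI")]) -
                    sim$truth$sample_q[qt$sample_id, ]))
    }
    mean(e)
  }, 0)
  expect_equal(order(errs), c(3, 2, 1))  # monotone decrease with n_loci
})

test_that("delta-K reproduces the worked example and degenerate cases", {
  # replicate sets with means (-1000, -800, -790, -785) and sd 5
  mk <- function(m) c(m - 5, m, m + 5)  # mean m, sd 5
  tab <- list(`1` = mk(-1000), `2` = mk(-800), `3` = mk(-790), `4` = mk(-785))
  dk <- delta_k(tab)
  expect_equal(dk$table$d2_abs[2], 190)
  expect_equal(dk$table$delta_k[2], 38)
  expect_equal(dk$table$d2_abs[3], 5)
  expect_equal(dk$table$delta_k[3], 1)
  expect_equal(dk$best_k, 2)
  expect_true(is.na(dk$table$delta_k[1]) && is.na(dk$table$delta_k[4]))

  # linear L in K: all second differences zero
  lin <- list(`1` = c(-30, -29), `2` = c(-20, -19), `3` = c(-10, -9))
  expect_equal(delta_k(lin)$table$d2_abs[2], 0)

  # zero replicate sd excluded from the argmax
  z <- list(`1` = c(-100, -100), `2` = c(-50, -50), `3` = c(-45, -44))
  expect_message(dz <- delta_k(z), "zero replicate sd")
  expect_true(is.na(dz$table$delta_k[2]))

  expect_error(delta_k(list(`1` = 1:2, `3` = 1:2, `4` = 1:2)), "consecutive")
  expect_error(delta_k(list(`1` = 1:2, `2` = 1:2)), "3 consecutive")
  expect_error(delta_k(list(`1` = 1, `2` = 1:2, `3` = 1:2)), "replicates")
})
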