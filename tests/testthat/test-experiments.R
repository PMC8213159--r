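test_that("replicate summaries bracket the mean and collapse for n = 1", {
  cfg <- cea_config("50:50", max_in = 1, max_out = 1)
  prot <- generate_protocol("constant", 30)
  one <- run_replicates(cfg, prot, n = 1, base_seed = 3)
  expect_equal(one$summary$mean, one$summary$min)
  expect_equal(one$summary$mean, one$summary$max)
  few <- run_replicates(cfg, prot, n = 4, base_seed = 3,
                        observe_at = c(10L, 25L))
  expect_true(all(few$summary$min <= few$summary$mean + 1e-12))
  expect_true(all(few$summary$mean <= few$summary$max + 1e-12))
  expect_equal(nrow(few$observed), 8)
  # summary statistics do not depend on replicate order
  perm <- few$pain[, c(3, 1, 4, 2)]
  expect_equal(rowMeans(perm), few$summary$mean)
  expect_equal(apply(perm, 1, sd), few$summary$sd)
  expect_error(run_replicates(cfg, prot, n = 0), ">= 1")
})

test_that("standardized effect sizes match hand-computed values", {
  expect_equal(cohens_d(1, 1, 5, 0, 1, 5), 1)
  expect_equal(cohens_d(3, 2, 8, 3, 1, 9), 0)
  # small-sample correction: d = 1, n1 = n2 = 5 gives g = 28/31
  g <- hedges_g(1, 1, 5, 0, 1, 5)
  expect_equal(g$hedges_g, 28 / 31)
  # antisymmetry under group exchange
  g2 <- hedges_g(0, 1, 5, 1, 1, 5)
  expect_equal(g2$hedges_g, -g$hedges_g)
  expect_equal(g2$ci_low, -g$ci_high)
  # zero-SD group borrows the comparison group's SD
  expect_equal(cohens_d(2, 0, 5, 0, 1, 5), 2)
  expect_error(cohens_d(2, 0, 5, 0, 0, 5), "zero")
  # correction factor lies in (0, 1) and approaches 1 with n
  for (n in c(3, 5, 20, 200)) {
    corr <- hedges_g(1, 1, n, 0, 1, n)$hedges_g
    expect_gt(corr, 0)
    expect_lt(corr, 1)
  }
  expect_gt(hedges_g(1, 1, 200, 0, 1, 200)$hedges_g,
            hedges_g(1, 1, 5, 0, 1, 5)$hedges_g)
})

test_that("sensitivity formula and perturbation rebalancing are exact", {
  s <- compute_sensitivity(100, 90, 100)
  expect_equal(unname(s["S_plus"]), -200)
  expect_equal(unname(s["S_minus"]), 0)
  expect_equal(unname(compute_sensitivity(5, 5, 5)), c(0, 0))

  cfg <- cea_config("50:50")
  # connectivity perturbations are absorbed by the to-Other column
  up <- perturb_config(cfg, "p_som_som", 0.60)
  expect_equal(up$connection_probs["SOM", "SOM"], 0.60)
  expect_equal(up$connection_probs["SOM", "Other"], 0.25)
  expect_equal(sum(up$connection_probs["SOM", ]), 1)
  # RS-share perturbations rescale LF and Spont proportionally
  rs <- perturb_config(cfg, "pct_rs_som", 0.32)
  p <- rs$freq_proportions$SOM
  expect_equal(sum(p), 1)
  expect_equal(unname(p["LF"] / p["Spont"]), 0.18 / 0.55)
  # SOM-share perturbation moves both hemispheres, complementing PKCd
  sh <- perturb_config(cfg, "pct_som", 0.55)
  expect_equal(sh$pct_som_left, 0.55)
  expect_equal(sh$pct_som_right, 0.55)
  expect_error(perturb_config(cfg, "pct_som", 1.04), "outside")
})

test_that("a two-parameter sensitivity run produces finite sensitivities at all ticks", {
  sens <- sensitivity_analysis(
    cea_config("50:50", max_in = 1, max_out = 1),
    protocol = generate_protocol("constant", 60),
    params = c("p_som_som", "pct_som"),
    n = 2, ticks = c(10L, 55L), base_seed = 5)
  expect_equal(nrow(sens), 4)
  expect_true(all(is.finite(sens$S_plus)))
  expect_true(all(is.finite(sens$S_minus)))
  expect_equal(sens$S_plus, (sens$P_plus - sens$P) / 0.05)
})

test_that("the silencing grid has the expected layout and exact silenced zeros", {
  sil <- silencing_experiment_table(models = "50:50", n = 2, base_seed = 7,
                                    ticks = c(uninjured = 5L, injured = 55L),
                                    protocol_length = 60L)
  expect_equal(nrow(sil$cells), 2 * 3 * 2)  # conditions x injury x replicates
  som_uninj <- subset(sil$cells, condition == "SOM_silenced" &
                        injury == "uninjured")
  expect_true(all(som_uninj$pain == 0))
})
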