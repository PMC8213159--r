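test_that("cumulative stimulation counts ticks at or above 120 pA", {
  expect_equal(update_cumulative_stimulation(0, 120), 1)
  expect_equal(update_cumulative_stimulation(5, 119), 5)
  expect_equal(update_cumulative_stimulation(5, 220), 6)
  expect_error(update_cumulative_stimulation(0, 250))
})

test_that("damage accrues only past latency under sufficient current, and clamps", {
  pop <- toy_population(type = c("PKCd", "SOM"), freq = c("RS", "RS"),
                        t_L = 80L, t_S = 100L)
  # condition met: one accrual tick adds 100 / t_S
  up <- update_damage(pop, cum_s = 81, s_i = 120)
  expect_equal(up$d, c(1, 1))
  # latency not yet exceeded
  expect_equal(update_damage(pop, cum_s = 80, s_i = 120)$d, c(0, 0))
  # current below threshold
  pop$d <- c(40, 40)
  expect_equal(update_damage(pop, cum_s = 200, s_i = 110)$d, c(40, 40))
  # clamp at 100
  pop$d <- c(99.5, 99.5); pop$t_S <- c(50L, 50L)
  expect_equal(update_damage(pop, cum_s = 200, s_i = 120)$d, c(100, 100))
})

test_that("damage trajectory matches the closed-form accrual count", {
  pop <- toy_population(type = rep("PKCd", 4), freq = "RS",
                        t_L = c(40L, 55L, 70L, 80L),
                        t_S = c(50L, 77L, 100L, 150L))
  d_hist <- matrix(NA_real_, 260, 4)
  cum_s <- 0
  for (tick in 1:260) {
    cum_s <- update_cumulative_stimulation(cum_s, 120)
    pop <- update_damage(pop, cum_s, 120)
    d_hist[tick, ] <- pop$d
  }
  for (j in 1:4) {
    expect_equal(d_hist[, j],
                 closed_form_damage(1:260, pop$t_L[j], pop$t_S[j]))
    # damage is non-decreasing and exactly 100 after t_L + t_S ticks
    expect_true(all(diff(d_hist[, j]) >= 0))
    expect_lt(d_hist[pop$t_L[j] + pop$t_S[j] - 1, j], 100)
    expect_equal(d_hist[pop$t_L[j] + pop$t_S[j], j], 100)
  }
})

test_that("firing-rate mixture interpolates the X and Y draws by damage", {
  tab <- degenerate_table(x_val = 10, y_val = 30)
  pop <- toy_population(type = rep("PKCd", 3), freq = "RS",
                        d = c(0, 100, 50))
  out <- sample_firing_rates(pop, 120, tab)
  # unsensitized limit, sensitized limit, and the 50% midpoint
  expect_equal(out$fr, c(10, 30, 20))
})

test_that("spontaneous neurons fire constantly; silenced types and low current give zero", {
  tab <- degenerate_table()
  pop <- toy_population(type = c("PKCd", "SOM", "PKCd", "SOM"),
                        freq = c("Spont", "Spont", "RS", "LF"))
  out <- sample_firing_rates(pop, 120, tab)
  expect_equal(out$fr[1:2], c(2.838, 4.887))
  # below 120 pA, LF/RS neurons do not fire but spontaneous ones do
  low <- sample_firing_rates(pop, 100, tab)
  expect_equal(low$fr, c(2.838, 4.887, 0, 0))
  # silencing zeroes every neuron of the type, spontaneous included
  sil <- sample_firing_rates(pop, 120, tab, silenced_types = "SOM")
  expect_equal(sil$fr[c(2, 4)], c(0, 0))
  expect_gt(sil$fr[3], 0)
})

test_that("inhibition threshold is inclusive and sums incoming strengths", {
  pop <- toy_population(type = rep("SOM", 5), freq = "RS",
                        fr = c(15, 7, 7, 5, 1))
  # single link at exactly the threshold inhibits
  net <- toy_network(end1 = 1, end2 = 5)
  out <- apply_inhibition(pop, net, threshold = 15)
  expect_true(out$inhibited[5])
  expect_equal(out$fr[5], 0)
  # 7 + 7 = 14 stays below threshold
  net2 <- toy_network(end1 = c(2, 3), end2 = c(5, 5))
  out2 <- apply_inhibition(pop, net2, threshold = 15)
  expect_false(out2$inhibited[5])
  expect_equal(out2$fr[5], 1)
  # 5 + 5 + 5 = 15 cumulative inhibition
  pop3 <- toy_population(type = rep("SOM", 4), freq = "RS",
                         fr = c(5, 5, 5, 9))
  net3 <- toy_network(end1 = 1:3, end2 = c(4, 4, 4))
  expect_true(apply_inhibition(pop3, net3, 15)$inhibited[4])
})

test_that("default inhibition freezes strengths at pre-inhibition rates", {
  # chain a -> b -> c, all at 15 Hz: without cascade both b and c are
  # inhibited (b's pre-inhibition rate still reaches c)
  pop <- toy_population(type = rep("PKCd", 3), freq = "RS", fr = c(15, 15, 15))
  net <- toy_network(end1 = c(1, 2), end2 = c(2, 3))
  out <- apply_inhibition(pop, net, 15, cascade = FALSE)
  expect_equal(out$inhibited, c(FALSE, TRUE, TRUE))
  # with cascading evaluation, b silenced before c is evaluated spares c
  # whenever b happens to be evaluated first; over the random order c is
  # never inhibited when b is (b's rate is zero by then)
  set.seed(1)
  for (i in 1:10) {
    res <- apply_inhibition(pop, net, 15, cascade = TRUE)
    expect_true(res$inhibited[2])
  }
})

test_that("pain matches the brute-force evaluation on toy populations", {
  pop <- toy_population(
    type = c("PKCd", "SOM"), freq = c("RS", "RS"),
    d = c(50, 0), fr = c(10, 4))
  expect_equal(unname(compute_pain(pop)["total"]), 0.5 * 10 - 4)
  # zero damage and silenced SOM: exactly zero
  pop0 <- toy_population(type = c("PKCd", "PKCd", "SOM"),
                         freq = c("RS", "LF", "RS"),
                         d = 0, fr = c(8, 3, 0))
  expect_equal(unname(compute_pain(pop0)["total"]), -0)
  # randomized toy populations against an independent loop
  set.seed(21)
  for (i in 1:25) {
    n <- sample(3:10, 1)
    pop_r <- toy_population(
      type = sample(c("PKCd", "SOM", "Other"), n, replace = TRUE),
      freq = sample(c("LF", "RS", "Spont"), n, replace = TRUE),
      loc = sample(c("Left", "Right"), n, replace = TRUE),
      d = round(runif(n, 0, 100), 1), fr = round(runif(n, 0, 30), 2))
    pop_r$freq[pop_r$type == "Other"] <- NA
    p <- compute_pain(pop_r)
    expect_equal(unname(p["total"]), brute_force_pain(pop_r))
    expect_equal(unname(p["total"]), unname(p["left"] + p["right"]))
  }
})

test_that("pain is linear: increasing SOM rates lowers it, damaged PKCd raises it", {
  base <- toy_population(type = c("PKCd", "SOM"), freq = c("RS", "RS"),
                         d = c(80, 0), fr = c(10, 5))
  p0 <- compute_pain(base)["total"]
  up_som <- base; up_som$fr[2] <- 9
  expect_lt(compute_pain(up_som)["total"], p0)
  up_pkc <- base; up_pkc$fr[1] <- 14
  expect_gt(compute_pain(up_pkc)["total"], p0)
})

test_that("spontaneous SOM conversion tops up RS to the target fraction", {
  pop <- initialize_population(cea_config("50:50"), seed = 2)
  # nothing happens before any SOM reaches full damage
  expect_equal(convert_spontaneous_som(pop)$n_converted, 0)
  # all SOM fully damaged: per-hemisphere RS fraction reaches exactly 48%
  pop$d[pop$type == "SOM"] <- 100
  res <- convert_spontaneous_som(pop)
  for (h in c("Left", "Right")) {
    som <- res$pop[res$pop$type == "SOM" & res$pop$loc == h, ]
    expect_equal(sum(som$freq == "RS") / nrow(som), 0.48)
  }
  # idempotent once the target is met
  expect_equal(convert_spontaneous_som(res$pop)$n_converted, 0)
})

test_that("one scheduled step and the full run agree on structure", {
  cfg <- cea_config("50:50", max_in = 1, max_out = 1)
  tab <- degenerate_table(10, 30)
  pop <- initialize_population(cfg, seed = 3)
  net <- build_network(pop, 1, 1, cfg$connection_probs, seed = 4)
  st <- step_simulation(pop, net, tab, cfg, cum_s = 0, s_i = 120)
  expect_equal(st$cum_s, 1)
  expect_equal(st$record$mean_damage, 0)
  # undamaged: pain reduces to minus the surviving SOM LF/RS rates
  surviving_som <- with(st$pop, type == "SOM" & freq %in% c("LF", "RS"))
  expect_equal(st$record$pain_total, -sum(st$pop$fr[surviving_som]))
})

test_that("simulations are reproducible and respect protocol edge cases", {
  cfg <- cea_config("50:50")
  prot <- generate_protocol("constant", 60)
  a <- run_simulation(cfg, prot, seed = 5)
  b <- run_simulation(cfg, prot, seed = 5)
  expect_identical(a$records, b$records)
  expect_false(identical(a$records$pain_total,
                         run_simulation(cfg, prot, seed = 6)$records$pain_total))
  # empty protocol: zero-tick run
  empty <- run_simulation(cfg, integer(0), seed = 1)
  expect_equal(nrow(empty$records), 0)
  # sub-threshold protocol: no damage, no cumulative stimulation
  low <- run_simulation(cfg, rep(110L, 50), seed = 1)
  expect_true(all(low$records$mean_damage == 0))
  expect_true(all(low$records$cum_S == 0))
  expect_error(run_simulation(cfg, rep(500L, 5), seed = 1), "\\[0, 220\\]")
})

test_that("with the network disabled nothing is ever inhibited", {
  cfg <- cea_config("50:50", max_in = 0, max_out = 0)
  sim <- run_simulation(cfg, generate_protocol("constant", 40), seed = 9)
  expect_equal(sim$n_links, 0)
  expect_true(all(sim$records$n_inhibited == 0))
})

test_that("damage saturates for every neuron within latency plus sensitization bounds", {
  cfg <- cea_config("50:50")
  sim <- run_simulation(cfg, generate_protocol("constant", 235), seed = 12)
  typed <- sim$population$type != "Other"
  # max t_L (80) + max t_S (150) = 230 ticks suffice for full sensitization
  expect_true(all(sim$population$d[typed] == 100))
  expect_true(all(diff(sim$records$mean_damage) >= 0))
})

test_that("full runs keep SOM the majority among inhibited neurons", {
  cfg <- cea_config("50:50")
  sim <- run_simulation(cfg, generate_protocol("constant", 250), seed = 31)
  r <- sim$records
  expect_gt(sum(r$n_inhibited_SOM) / sum(r$n_inhibited), 0.5)
  expect_true(all(r$n_inhibited_SOM <= r$n_inhibited))
})
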