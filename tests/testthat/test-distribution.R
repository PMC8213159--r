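test_that("bundled synthetic table is complete and encodes the injury sign structure", {
  tab <- synthetic_distribution_table()
  expect_s3_class(tab, "cea_disttable")
  expect_equal(nrow(tab$data), 48)
  df <- tab$data
  for (fq in c("LF", "RS")) {
    for (cur in distribution_levels()) {
      mu_of <- function(ty, st)
        df$mu[df$type == ty & df$freq == fq & df$state == st &
              df$current_pA == cur]
      # PKCd fires faster after injury, SOM slower
      expect_gte(mu_of("PKCd", "Y"), mu_of("PKCd", "X"))
      expect_lte(mu_of("SOM", "Y"), mu_of("SOM", "X"))
    }
  }
  # rates increase with injected current within every cell
  by_cell <- split(df, list(df$type, df$freq, df$state))
  for (cell in by_cell) {
    cell <- cell[order(cell$current_pA), ]
    expect_true(all(diff(cell$mu) > 0))
  }
})

test_that("table round-trips through file and validation reports missing cells by key", {
  tab <- synthetic_distribution_table()
  path <- withr::local_tempfile(fileext = ".csv")
  write_distribution_table(tab, path)
  back <- load_distribution_table(path)
  expect_equal(back$data, tab$data, ignore_attr = TRUE)

  df <- tab$data
  drop <- !(df$type == "SOM" & df$freq == "LF" & df$state == "Y" &
              df$current_pA == 220)
  expect_error(as_distribution_table(df[drop, ]), "SOM/LF/Y/220")

  bad <- df; bad$sigma[5] <- -1
  expect_error(as_distribution_table(bad), "sigma")
  bad <- df; bad$max[3] <- bad$min[3] - 1
  expect_error(as_distribution_table(bad), "max")
  bad <- rbind(df, df[1, ])
  expect_error(as_distribution_table(bad), "duplicated")
})

test_that("lookup bins currents to the nearest 20 pA level, ties upward", {
  tab <- synthetic_distribution_table()
  # below 120 pA: degenerate zero distribution (no firing)
  z <- lookup_distribution(tab, "PKCd", "RS", "X", 110)
  expect_equal(z, list(mu = 0, sigma = 0, min = 0, max = 0))
  # direct hit
  direct <- lookup_distribution(tab, "SOM", "LF", "Y", 120)
  row <- subset(tab$data, type == "SOM" & freq == "LF" & state == "Y" &
                  current_pA == 120)
  expect_equal(direct$mu, row$mu)
  # tie at 130 rounds up to 140
  up <- lookup_distribution(tab, "PKCd", "RS", "Y", 130)
  row140 <- subset(tab$data, type == "PKCd" & freq == "RS" & state == "Y" &
                     current_pA == 140)
  expect_equal(up$mu, row140$mu)
  # 129 rounds down to 120
  down <- lookup_distribution(tab, "PKCd", "RS", "Y", 129)
  row120 <- subset(tab$data, type == "PKCd" & freq == "RS" & state == "Y" &
                     current_pA == 120)
  expect_equal(down$mu, row120$mu)
  expect_error(lookup_distribution(tab, "PKCd", "RS", "X", 230), "\\[0, 220\\]")
})

test_that("truncated-normal draws always fall inside the support", {
  set.seed(99)
  for (i in 1:20) {
    mu <- runif(1, -5, 20); sigma <- runif(1, 0, 5)
    lo <- mu - runif(1, 0, 3); hi <- mu + runif(1, 0, 3)
    x <- rtruncnorm(500, mu, sigma, lo, hi)
    expect_true(all(x >= lo & x <= hi))
  }
  # degenerate cells collapse to the clamped mean
  expect_equal(rtruncnorm(5, 10, 0, 0, 30), rep(10, 5))
  expect_equal(rtruncnorm(5, 50, 2, 0, 30), rep(30, 5))
})

test_that("high-current extrapolation matches closed-form least squares", {
  # independent closed-form fit
  ls_predict <- function(x, y, x0) {
    b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    a <- mean(y) - b * mean(x)
    a + b * x0
  }
  expect_equal(extrapolate_firing_rate(cbind(c(140, 160, 180), c(2, 4, 6)), 220), 10)
  expect_equal(extrapolate_firing_rate(cbind(c(140, 160), c(5, 5)), 220), 5)
  set.seed(4)
  for (i in 1:10) {
    x <- sort(sample(seq(120, 200, 20), 4))
    y <- abs(rnorm(4, 10, 4)) + 0.1
    expect_equal(extrapolate_firing_rate(cbind(x, y), 220),
                 max(ls_predict(x, y, 220), 0))
  }
  # zero-rate points (depolarization block) are excluded from the fit
  expect_equal(
    extrapolate_firing_rate(cbind(c(120, 140, 160, 180), c(0, 2, 4, 6)), 220),
    10)
  expect_error(extrapolate_firing_rate(cbind(140, 2), 220), "at least 2")
  expect_error(extrapolate_firing_rate(cbind(c(140, 160), c(2, 0)), 220),
               "at least 2")
})
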