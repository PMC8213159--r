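#' Run a batch of replicate simulations
#'
#' Repeats a simulation `n` times with seeds `base_seed .. base_seed +
#' n - 1` and summarizes the per-tick pain output across replicates
#' (mean, min, max, SD), mirroring the study convention of 100
#' replicates per scenario.
#'
#' @param config A [cea_config()] object.
#' @param protocol Integer vector of stimulation currents (pA).
#' @param table A `cea_disttable`.
#' @param n Number of replicates (`>= 1`).
#' @param base_seed Integer seed of the first replicate.
#' @param observe_at Integer ticks at which per-replicate pain values
#'   are additionally extracted.
#' @return An object of class `cea_replicates`: list with `summary`
#'   (per-tick data frame: `tick`, `mean`, `min`, `max`, `sd`), `pain`
#'   (ticks x replicates matrix), `observed` (data frame of pain at
#'   `observe_at` per replicate), `n`, `seeds`, and `config`.
#' @export
run_replicates <- function(config, protocol,
                           table = synthetic_distribution_table(),
                           n = 100L, base_seed = 1L,
                           observe_at = integer(0)) {
  if (n < 1) stop("`n` must be >= 1")
  seeds <- base_seed + seq_len(n) - 1L
  pain <- matrix(NA_real_, nrow = length(protocol), ncol = n)
  conv <- integer(n)
  for (j in seq_len(n)) {
    sim <- run_simulation(config, protocol, table, seed = seeds[j])
    pain[, j] <- sim$records$pain_total
    conv[j] <- sim$n_converted_total
  }
  summary <- data.frame(
    tick = seq_len(nrow(pain)),
    mean = rowMeans(pain),
    min = apply(pain, 1, min),
    max = apply(pain, 1, max),
    sd = apply(pain, 1, stats::sd)
  )
  observed <- NULL
  if (length(observe_at)) {
    observed <- do.call(rbind, lapply(observe_at, function(t)
      data.frame(tick = t, replicate = seq_len(n), pain = pain[t, ])))
  }
  structure(list(summary = summary, pain = pain, observed = observed,
                 n_converted = conv, n = n, seeds = seeds, config = config),
            class = "cea_replicates")
}

#' @export
print.cea_replicates <- function(x, ...) {
  cat("Replicate batch:", x$n, "runs,", nrow(x$summary), "ticks\n")
  if (nrow(x$summary))
    cat(sprintf("  mean pain: first %.1f, last %.1f\n",
                x$summary$mean[1], x$summary$mean[nrow(x$summary)]))
  invisible(x)
}

# The seven parameters of the local sensitivity analysis, all on the
# probability scale: the four connectivity probabilities, the RS share
# within each type, and the overall SOM share per hemisphere.
#' @rdname sensitivity_analysis
#' @export
sensitivity_parameters <- function() {
  c("p_pkc_pkc", "p_pkc_som", "p_som_som", "p_som_pkc",
    "pct_rs_pkc", "pct_rs_som", "pct_som")
}

#' Perturb one sensitivity parameter of a configuration
#'
#' Applies the rebalancing rules used by the sensitivity analysis:
#' perturbing a connectivity probability is absorbed by the same row's
#' to-Other probability; perturbing the overall SOM share is
#' complemented by the PKCd share; perturbing the RS share within a type
#' rescales that type's LF and Spont shares proportionally.
#'
#' @param config A [cea_config()] object.
#' @param param One of [sensitivity_parameters()].
#' @param value New value of the parameter, in `[0, 1]` (and leaving all
#'   rebalanced quantities in `[0, 1]`).
#' @return The perturbed `cea_config`.
#' @export
perturb_config <- function(config, param, value) {
  stopifnot(inherits(config, "cea_config"),
            param %in% sensitivity_parameters(),
            length(value) == 1L)
  if (value < 0 || value > 1)
    stop("perturbed value of ", param, " outside [0, 1]: ", value)
  cp <- config$connection_probs
  fp <- config$freq_proportions
  if (param %in% c("p_pkc_pkc", "p_pkc_som", "p_som_som", "p_som_pkc")) {
    row <- if (grepl("^p_pkc", param)) "PKCd" else "SOM"
    col <- if (grepl("pkc$", param)) "PKCd" else "SOM"
    cp[row, col] <- value
    cp[row, "Other"] <- 1 - sum(cp[row, c("PKCd", "SOM")])
    if (cp[row, "Other"] < -1e-9)
      stop("perturbation drives the ", row, "-to-Other probability below 0")
    cp[row, "Other"] <- max(cp[row, "Other"], 0)
    config$connection_probs <- cp
  } else if (param %in% c("pct_rs_pkc", "pct_rs_som")) {
    ty <- if (param == "pct_rs_pkc") "PKCd" else "SOM"
    p <- fp[[ty]]
    rest <- p[c("LF", "Spont")]
    p["RS"] <- value
    p[c("LF", "Spont")] <- rest / sum(rest) * (1 - value)
    fp[[ty]] <- p
    config$freq_proportions <- fp
  } else {  # pct_som: SOM share per hemisphere, PKCd takes the complement
    config$pct_som_left <- value
    config$pct_som_right <- value
  }
  config
}

# read the current value of a sensitivity parameter from a configuration
sensitivity_baseline <- function(config, param) {
  switch(param,
    p_pkc_pkc = config$connection_probs["PKCd", "PKCd"],
    p_pkc_som = config$connection_probs["PKCd", "SOM"],
    p_som_som = config$connection_probs["SOM", "SOM"],
    p_som_pkc = config$connection_probs["SOM", "PKCd"],
    pct_rs_pkc = config$freq_proportions$PKCd[["RS"]],
    pct_rs_som = config$freq_proportions$SOM[["RS"]],
    pct_som = config$pct_som_left)
}

#' Local sensitivity of pain to one parameter
#'
#' Given mean pain at the baseline parameter value and at values
#' perturbed by `+delta` / `-delta`, the one-at-a-time sensitivities are
#' `S_plus = (P_plus - P) / delta` and `S_minus = (P_minus - P) / delta`.
#'
#' @param p,p_plus,p_minus Mean pain at the baseline, upper, and lower
#'   parameter values.
#' @param delta Perturbation size (default 0.05).
#' @return Named vector `c(S_plus = ..., S_minus = ...)`.
#' @examples
#' compute_sensitivity(100, 90, 100)  # S_plus = -200, S_minus = 0
#' @export
compute_sensitivity <- function(p, p_plus, p_minus, delta = 0.05) {
  c(S_plus = (p_plus - p) / delta, S_minus = (p_minus - p) / delta)
}

#' Local sensitivity analysis of the pain output
#'
#' One-at-a-time sensitivity analysis over the seven probability-scale
#' parameters: the four connectivity probabilities, the RS share among
#' PKCd and among SOM neurons, and the overall SOM share per hemisphere.
#' For each parameter, replicate batches are run at the baseline value
#' `R`, at `R + delta`, and at `R - delta` (rebalanced as described in
#' [perturb_config()]), and sensitivities `S_plus`, `S_minus` of mean
#' pain are evaluated at the pre-, during-, and post-injury observation
#' ticks.
#'
#' @param config Baseline configuration (study convention: the 50:50
#'   model with a 3:3 network).
#' @param protocol Stimulation protocol (study convention: constant
#'   120 pA for 250 ticks).
#' @param table A `cea_disttable`.
#' @param params Character vector of parameters to analyze.
#' @param delta Perturbation size (default 0.05).
#' @param n Replicates per parameter value (study convention: 100).
#' @param ticks Observation ticks (default `c(10, 105, 240)`).
#' @param base_seed Integer seed for the first replicate of each batch.
#' @return A data frame of class `cea_sensitivity` with one row per
#'   parameter x tick: `param`, `tick`, `R`, `P_minus`, `P`, `P_plus`,
#'   `S_plus`, `S_minus`.
#' @export
sensitivity_analysis <- function(config = cea_config("50:50"),
                                 protocol = generate_protocol("constant", 250),
                                 table = synthetic_distribution_table(),
                                 params = sensitivity_parameters(),
                                 delta = 0.05, n = 100L,
                                 ticks = c(10L, 105L, 240L),
                                 base_seed = 1L) {
  stopifnot(all(params %in% sensitivity_parameters()),
            max(ticks) <= length(protocol))
  mean_pain_at <- function(cfg, seed0) {
    reps <- run_replicates(cfg, protocol, table, n = n, base_seed = seed0)
    reps$summary$mean[ticks]
  }
  out <- list()
  for (pa in params) {
    r <- sensitivity_baseline(config, pa)
    p0 <- mean_pain_at(config, base_seed)
    pp <- mean_pain_at(perturb_config(config, pa, r + delta), base_seed + n)
    pm <- mean_pain_at(perturb_config(config, pa, r - delta), base_seed + 2L * n)
    out[[pa]] <- data.frame(
      param = pa, tick = ticks, R = r,
      P_minus = pm, P = p0, P_plus = pp,
      S_plus = (pp - p0) / delta, S_minus = (pm - p0) / delta,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("cea_sensitivity", "data.frame")
  res
}

#' Cohen's d with pooled standard deviation
#'
#' Standardized mean difference `(m1 - m2) / s_pooled` with the pooled
#' SD computed from both groups' variances. When exactly one group has
#' zero SD (as for the structurally exact zero pain of SOM-silenced
#' uninjured runs), the other group's SD is used instead.
#'
#' @param mean1,sd1,n1 Mean, SD, and size of group 1.
#' @param mean2,sd2,n2 Mean, SD, and size of group 2.
#' @return Cohen's d.
#' @export
cohens_d <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 + n2 > 2, n1 >= 1, n2 >= 1, sd1 >= 0, sd2 >= 0)
  if (sd1 == 0 && sd2 == 0)
    stop("both group SDs are zero; effect size undefined")
  if (sd1 == 0) sd1 <- sd2
  if (sd2 == 0) sd2 <- sd1
  pooled <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  (mean1 - mean2) / pooled
}

#' Hedges' g standardized effect size
#'
#' Small-sample-corrected standardized mean difference,
#' `g = d * (1 - 3 / (4 (n1 + n2 - 2) - 1))` with `d` from
#' [cohens_d()]. The 95% confidence interval uses the standard
#' large-sample variance `(n1 + n2) / (n1 n2) + g^2 / (2 (n1 + n2 - 2))`.
#'
#' @inheritParams cohens_d
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `cea_effect_size`: list with `hedges_g`,
#'   `cohens_d`, `ci_low`, `ci_high`, `conf_level`, and the group
#'   summaries.
#' @examples
#' hedges_g(1, 1, 5, 0, 1, 5)$hedges_g  # 28/31
#' @export
hedges_g <- function(mean1, sd1, n1, mean2, sd2, n2, conf_level = 0.95) {
  d <- cohens_d(mean1, sd1, n1, mean2, sd2, n2)
  correction <- 1 - 3 / (4 * (n1 + n2 - 2) - 1)
  g <- d * correction
  se <- sqrt((n1 + n2) / (n1 * n2) + g^2 / (2 * (n1 + n2 - 2)))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(hedges_g = g, cohens_d = d,
                 ci_low = g - z * se, ci_high = g + z * se,
                 conf_level = conf_level,
                 group1 = c(mean = mean1, sd = sd1, n = n1),
                 group2 = c(mean = mean2, sd = sd2, n = n2)),
            class = "cea_effect_size")
}

#' @export
print.cea_effect_size <- function(x, ...) {
  cat(sprintf("Hedges' g = %.4f [%.4f, %.4f] (%.0f%% CI)\n",
              x$hedges_g, x$ci_low, x$ci_high, 100 * x$conf_level))
  invisible(x)
}

#' Cell-type silencing experiment grid
#'
#' Reproduces the silencing (chemogenetic inhibition analogue)
#' experiment layout: for each population model and each of the
#' conditions intact, PKCd-silenced, and SOM-silenced, `n` replicate
#' simulations are run under constant 120 pA stimulation with a 3:3
#' network, and pain is recorded before injury (tick 10) and after
#' injury (tick 240).
#'
#' @param models Character vector of population models.
#' @param table A `cea_disttable`.
#' @param n Replicates per cell (study convention: 5).
#' @param base_seed Integer seed.
#' @param ticks Named integer vector with observation ticks `uninjured`
#'   and `injured`.
#' @param protocol_length Protocol length in ticks.
#' @param max_in,max_out Network limits.
#' @return An object of class `cea_silencing`: list with `cells` (tidy
#'   data frame: `model`, `condition`, `injury`, `replicate`, `pain`)
#'   and `summary` (mean and SD per model x condition x injury).
#' @export
silencing_experiment_table <- function(models = c("30:70", "50:50", "60:40"),
                                       table = synthetic_distribution_table(),
                                       n = 5L, base_seed = 1L,
                                       ticks = c(uninjured = 10L, injured = 240L),
                                       protocol_length = 250L,
                                       max_in = 3L, max_out = 3L) {
  protocol <- generate_protocol("constant", protocol_length, 120L)
  conditions <- list(intact = character(0), PKCd_silenced = "PKCd",
                     SOM_silenced = "SOM")
  cells <- list()
  for (m in models) {
    for (cn in names(conditions)) {
      cfg <- cea_config(m, max_in = max_in, max_out = max_out,
                        silenced_types = conditions[[cn]])
      reps <- run_replicates(cfg, protocol, table, n = n,
                             base_seed = base_seed, observe_at = ticks)
      obs <- reps$observed
      obs$injury <- names(ticks)[match(obs$tick, ticks)]
      cells[[paste(m, cn)]] <- data.frame(
        model = m, condition = cn, injury = obs$injury,
        replicate = obs$replicate, pain = obs$pain,
        stringsAsFactors = FALSE)
    }
  }
  cells <- do.call(rbind, cells)
  rownames(cells) <- NULL
  summary <- stats::aggregate(pain ~ model + condition + injury, cells,
                              function(x) c(mean = mean(x), sd = stats::sd(x)))
  summary <- cbind(summary[1:3], as.data.frame(summary$pain))
  structure(list(cells = cells, summary = summary, n = n),
            class = "cea_silencing")
}

#' @export
print.cea_silencing <- function(x, ...) {
  cat("Silencing experiment (", x$n, " replicates per cell)\n", sep = "")
  print(x$summary, digits = 6)
  invisible(x)
}
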