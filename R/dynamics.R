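# Internal integer codings used by the simulation kernels:
#   type: 1 = PKCd, 2 = SOM, 3 = Other
#   freq: 1 = LF, 2 = RS, 3 = Spont, NA for Other
TYPE_LEVELS <- c("PKCd", "SOM", "Other")
FREQ_LEVELS <- c("LF", "RS", "Spont")

# Flatten the 4-d distribution arrays into cell x level matrices with the
# truncation CDF bounds evaluated once, so per-tick sampling needs a single
# qnorm per draw. Cell index = type + 2 * (freq - 1).
precompute_table <- function(table) {
  nl <- length(distribution_levels())
  grab <- function(a, state) matrix(a[, , state, ], nrow = 4L, ncol = nl)
  out <- list()
  for (st in c("X", "Y")) {
    mu <- grab(table$mu, st); sg <- grab(table$sigma, st)
    lo <- grab(table$min, st); hi <- grab(table$max, st)
    plo <- matrix(0.5, 4L, nl); phi <- matrix(0.5, 4L, nl)
    ok <- sg > 0 & hi > lo
    plo[ok] <- stats::pnorm((lo[ok] - mu[ok]) / sg[ok])
    phi[ok] <- stats::pnorm((hi[ok] - mu[ok]) / sg[ok])
    sg[!ok] <- 0
    sfx <- tolower(st)
    out[[paste0("mu_", sfx)]] <- mu
    out[[paste0("sigma_", sfx)]] <- sg
    out[[paste0("lo_", sfx)]] <- lo
    out[[paste0("hi_", sfx)]] <- hi
    out[[paste0("plo_", sfx)]] <- plo
    out[[paste0("span_", sfx)]] <- phi - plo
  }
  out
}

pop_codes <- function(pop) {
  list(type = match(pop$type, TYPE_LEVELS),
       freq = match(pop$freq, FREQ_LEVELS),
       left = pop$loc == "Left")
}

#' Update the cumulative stimulation counter
#'
#' The global counter `Cum_S` tracks the number of time steps with
#' stimulation at or above 120 pA; damage accrual begins once it
#' exceeds a neuron's latency period.
#'
#' @param cum_s Current counter value.
#' @param s_i Stimulation current (pA) this tick, in `[0, 220]`.
#' @return Updated counter.
#' @examples
#' update_cumulative_stimulation(0, 120)  # 1
#' update_cumulative_stimulation(5, 119)  # 5
#' @export
update_cumulative_stimulation <- function(cum_s, s_i) {
  stopifnot(length(s_i) == 1L, s_i >= 0, s_i <= 220)
  cum_s + as.integer(s_i >= 120)
}

# damage kernel: d grows by 100 / t_S per accrual tick, clamped to 100.
# Values within 1e-9 of 100 are snapped to exactly 100 so that after t_S
# accrual ticks a neuron is exactly fully sensitized.
k_damage <- function(d, t_L, t_S, typed, cum_s, s_i) {
  if (s_i >= 120) {
    acc <- typed & cum_s > t_L
    d[acc] <- d[acc] + 100 / t_S[acc]
    d[typed & d > 100 - 1e-9] <- 100
  }
  d
}

#' Update damage for all PKCd and SOM neurons
#'
#' During ticks with stimulation at or above 120 pA, every typed neuron
#' whose latency period has elapsed (`cum_s > t_L`) accrues `100 / t_S`
#' damage, clamped at 100. A neuron with `d = 100` is fully sensitized.
#'
#' @param pop A `cea_population`.
#' @param cum_s Cumulative stimulation counter (after this tick's
#'   update).
#' @param s_i Stimulation current (pA) this tick.
#' @return The population with updated `d`.
#' @export
update_damage <- function(pop, cum_s, s_i) {
  stopifnot(inherits(pop, "cea_population"))
  typed <- pop$type != "Other"
  pop$d <- k_damage(pop$d, pop$t_L, pop$t_S, typed, cum_s, s_i)
  pop
}

# conversion kernel: spontaneous SOM neurons at full damage convert to RS,
# one at a time, until the RS share of SOM neurons reaches the target.
k_convert <- function(freq, type, left, d, target, scope) {
  groups <- if (scope == "hemisphere") list(left, !left) else list(left | !left)
  converted <- integer(0)
  for (g in groups) {
    som <- g & type == 2L
    n_som <- sum(som)
    if (n_som == 0L) next
    need <- ceiling(round(target * n_som, 9)) - sum(som & freq == 2L)
    if (need <= 0L) next
    elig <- which(som & freq == 3L & d >= 100)
    k <- min(need, length(elig))
    if (k > 0L) converted <- c(converted, elig[sample.int(length(elig), k)])
  }
  freq[converted] <- 2L
  list(freq = freq, n_converted = length(converted))
}

#' Convert sensitized spontaneous SOM neurons to regular spiking
#'
#' Slice recordings show the share of regular-spiking SOM neurons rising
#' from 27% before injury to 48% after, with a matching drop in
#' spontaneously active SOM neurons. The model reproduces this by
#' converting spontaneous SOM neurons that have reached full damage
#' (`d = 100`) to RS, one at a time and in random order, until RS SOM
#' neurons make up the target fraction of all SOM neurons.
#'
#' @param pop A `cea_population`.
#' @param target Target RS fraction among SOM neurons (default 0.48).
#' @param scope `"hemisphere"` evaluates the target per hemisphere,
#'   `"global"` across both.
#' @return List with elements `pop` (updated population) and
#'   `n_converted`.
#' @export
convert_spontaneous_som <- function(pop, target = 0.48,
                                    scope = c("hemisphere", "global")) {
  stopifnot(inherits(pop, "cea_population"))
  scope <- match.arg(scope)
  cd <- pop_codes(pop)
  res <- k_convert(cd$freq, cd$type, cd$left, pop$d, target, scope)
  pop$freq <- FREQ_LEVELS[res$freq]
  list(pop = pop, n_converted = res$n_converted)
}

# firing-rate kernel. LF/RS neurons mix a fresh unsensitized (X) and
# sensitized (Y) truncated-normal draw by damage fraction:
#   Fr = (100 - d)/100 * X + d/100 * Y
# Spontaneous neurons fire at constant type-specific rates. Below 120 pA
# LF/RS neurons do not fire. Silenced types fire at 0 Hz.
k_sample_rates <- function(type, freq, d, lev, table, silenced,
                           spont_rates) {
  fr <- numeric(length(type))
  sp <- which(freq == 3L)
  fr[sp] <- spont_rates[type[sp]]
  act <- which(freq %in% c(1L, 2L))
  if (lev > 0L && length(act)) {
    ix <- cbind(type[act], freq[act], 1L, lev)
    iy <- cbind(type[act], freq[act], 2L, lev)
    x <- rtruncnorm(length(act), table$mu[ix], table$sigma[ix],
                    table$min[ix], table$max[ix])
    y <- rtruncnorm(length(act), table$mu[iy], table$sigma[iy],
                    table$min[iy], table$max[iy])
    w <- d[act] / 100
    fr[act] <- (1 - w) * x + w * y
  }
  if (length(silenced)) fr[type %in% silenced] <- 0
  fr
}

#' Sample firing rates for all neurons
#'
#' Updates every PKCd and SOM neuron's firing rate for the current tick.
#' LF and RS neurons draw an unsensitized (X) and a sensitized (Y) rate
#' from the truncated-normal cells for their type, frequency, and the
#' binned stimulation level, and mix them by damage fraction; at
#' currents below 120 pA they do not fire. Spontaneous neurons fire at
#' their constant type-specific rate. Neurons of a silenced type fire at
#' 0 Hz.
#'
#' @param pop A `cea_population`.
#' @param s_i Stimulation current (pA) this tick.
#' @param table A `cea_disttable`.
#' @param silenced_types Character subset of `c("PKCd", "SOM")`.
#' @param spont_rates Numeric length-2 vector, constant rates for
#'   spontaneous PKCd and SOM neurons.
#' @return The population with updated `fr` (pre-inhibition).
#' @export
sample_firing_rates <- function(pop, s_i, table,
                                silenced_types = character(0),
                                spont_rates = c(2.838, 4.887)) {
  stopifnot(inherits(pop, "cea_population"), inherits(table, "cea_disttable"))
  cd <- pop_codes(pop)
  fr <- k_sample_rates(cd$type, cd$freq, pop$d, current_level_index(s_i),
                       table, match(silenced_types, TYPE_LEVELS), spont_rates)
  fr[cd$type == 3L] <- NA_real_
  pop$fr <- fr
  pop
}

# inhibition kernel. Signal strength of each link equals its
# transmitter's firing rate. A typed neuron whose summed incoming
# strength reaches the threshold is inhibited: its rate is set to 0.
# Non-cascading (default): strengths are frozen at pre-inhibition rates.
# Cascading: neurons are evaluated one at a time in random order and an
# inhibited neuron's outgoing signals are removed for later evaluations.
k_inhibit <- function(fr, end1, end2, typed, threshold, cascade) {
  n <- length(fr)
  inhibited <- logical(n)
  if (length(end1) == 0L) return(list(fr = fr, inhibited = inhibited))
  if (!cascade) {
    rs <- rowsum(fr[end1], end2)
    incoming <- numeric(n)
    incoming[as.integer(rownames(rs))] <- rs[, 1L]
    inhibited <- typed & incoming >= threshold
    fr[inhibited] <- 0
  } else {
    in_links <- vector("list", n)
    sp <- split(end1, end2)
    in_links[as.integer(names(sp))] <- sp
    for (j in sample(which(typed))) {
      tx <- in_links[[j]]
      if (!is.null(tx) && sum(fr[tx]) >= threshold) {
        inhibited[j] <- TRUE
        fr[j] <- 0
      }
    }
  }
  list(fr = fr, inhibited = inhibited)
}

#' Apply network inhibition
#'
#' Transmits inhibitory signals through the network: each link carries
#' its transmitter's current firing rate, and every PKCd or SOM neuron
#' whose summed incoming signal strength is greater than or equal to the
#' threshold is inhibited (firing rate set to 0) for this tick. The
#' threshold comparison is inclusive, so a single transmitter firing at
#' exactly the threshold inhibits its target.
#'
#' @param pop A `cea_population` with firing rates already sampled.
#' @param net A `cea_network`.
#' @param threshold Inhibition threshold in Hz (default 15).
#' @param cascade Logical; see [cea_config()].
#' @return The population with updated `fr` and `inhibited`.
#' @export
apply_inhibition <- function(pop, net, threshold = 15, cascade = FALSE) {
  stopifnot(inherits(pop, "cea_population"), inherits(net, "cea_network"))
  typed <- pop$type != "Other"
  res <- k_inhibit(pop$fr, net$end1, net$end2, typed, threshold, cascade)
  pop$fr <- res$fr
  pop$inhibited <- ifelse(typed, res$inhibited, NA)
  pop
}

# pain kernel: damage-weighted PKCd LF/RS firing minus SOM LF/RS firing,
# per hemisphere. Spontaneous and Other neurons contribute nothing.
k_pain <- function(type, freq, left, d, fr) {
  act <- freq %in% c(1L, 2L)
  pk <- act & type == 1L
  so <- act & type == 2L
  p_left <- sum(d[pk & left] / 100 * fr[pk & left]) - sum(fr[so & left])
  p_right <- sum(d[pk & !left] / 100 * fr[pk & !left]) - sum(fr[so & !left])
  c(total = p_left + p_right, left = p_left, right = p_right)
}

#' Compute the emergent pain measure
#'
#' Pain is the damage-weighted sum of firing rates over all LF and RS
#' PKCd neurons (pro-nociceptive) minus the sum of firing rates over all
#' LF and RS SOM neurons (anti-nociceptive), across both hemispheres.
#' Undamaged PKCd neurons contribute nothing; SOM neurons contribute at
#' all damage levels. Spontaneous and Other neurons never contribute.
#' Inhibition must already have been applied (inhibited neurons fire at
#' 0 Hz).
#'
#' @param pop A `cea_population`.
#' @return Named numeric vector with elements `total`, `left`, `right`.
#' @export
compute_pain <- function(pop) {
  stopifnot(inherits(pop, "cea_population"))
  cd <- pop_codes(pop)
  k_pain(cd$type, cd$freq, cd$left, pop$d, pop$fr)
}

#' Advance one scheduled time step
#'
#' Executes the per-tick schedule once on an explicit population and
#' network: update the cumulative stimulation counter, accrue damage,
#' convert sensitized spontaneous SOM neurons, sample firing rates,
#' apply inhibition, and compute pain. [run_simulation()] performs the
#' same schedule over a whole protocol; this entry point exposes a
#' single step for inspection and testing.
#'
#' @param pop A `cea_population`.
#' @param net A `cea_network`.
#' @param table A `cea_disttable`.
#' @param config A [cea_config()] object.
#' @param cum_s Cumulative stimulation counter before this tick.
#' @param s_i Stimulation current (pA) this tick.
#' @return List with `pop` (updated population), `cum_s`, `n_converted`,
#'   and `record` (a one-row data frame of system observations).
#' @export
step_simulation <- function(pop, net, table, config, cum_s, s_i) {
  stopifnot(inherits(pop, "cea_population"), inherits(config, "cea_config"))
  cum_s <- update_cumulative_stimulation(cum_s, s_i)
  pop <- update_damage(pop, cum_s, s_i)
  cv <- convert_spontaneous_som(pop, config$post_injury_rs_som_target,
                                config$conversion_scope)
  pop <- cv$pop
  pop <- sample_firing_rates(pop, s_i, table, config$silenced_types,
                             c(config$spont_rate_pkc, config$spont_rate_som))
  pop <- apply_inhibition(pop, net, config$inhibition_threshold,
                          config$cascade)
  p <- compute_pain(pop)
  typed <- pop$type != "Other"
  record <- data.frame(
    S = s_i, cum_S = cum_s,
    pain_total = p[["total"]], pain_left = p[["left"]],
    pain_right = p[["right"]],
    mean_damage = mean(pop$d[typed]),
    n_inhibited = sum(pop$inhibited[typed]),
    n_inhibited_SOM = sum(pop$inhibited[typed] & pop$type[typed] == "SOM"),
    n_converted = cv$n_converted)
  list(pop = pop, cum_s = cum_s, n_converted = cv$n_converted,
       record = record)
}

#' Run a full simulation
#'
#' Initializes the population and network from `config`, then executes
#' the per-tick schedule over the stimulation protocol: update the
#' cumulative stimulation counter, accrue damage, convert sensitized
#' spontaneous SOM neurons to RS, sample firing rates, transmit
#' inhibitory signals, and record the pain output and system
#' observations.
#'
#' A single root seed drives three named substreams (population
#' initialization, network construction, per-tick dynamics), so runs are
#' bit-for-bit reproducible.
#'
#' @param config A [cea_config()] object.
#' @param protocol Integer vector of stimulation currents (pA, one per
#'   tick, each in `[0, 220]`), e.g. from [generate_protocol()] or
#'   [read_stimulation_file()].
#' @param table A `cea_disttable`; defaults to the bundled
#'   [synthetic_distribution_table()].
#' @param seed Integer root seed; defaults to `config$seed`.
#' @param record_rates_at Integer vector of ticks at which to store the
#'   per-neuron pre- and post-inhibition firing rates.
#' @return An object of class `cea_simulation`: a list with `records`
#'   (one row per tick: `tick`, `S`, `cum_S`, `pain_total`, `pain_left`,
#'   `pain_right`, `mean_damage`, `n_inhibited`, `n_inhibited_SOM`,
#'   `n_converted`), `n_links`, `n_converted_total`, `population` (final
#'   state), `rates` (list keyed by tick, when requested), `config`, and
#'   `seed`.
#' @examples
#' sim <- run_simulation(cea_config("50:50"), generate_protocol("constant", 50),
#'                       seed = 1)
#' head(sim$records)
#' @export
run_simulation <- function(config, protocol,
                           table = synthetic_distribution_table(),
                           seed = config$seed,
                           record_rates_at = integer(0)) {
  stopifnot(inherits(config, "cea_config"), inherits(table, "cea_disttable"))
  if (is.null(seed)) stop("a seed is required (argument `seed` or `config$seed`)")
  protocol <- validate_protocol(protocol)
  seeds <- derive_substream_seeds(seed)

  pop <- initialize_population(config, seeds[["init"]])
  net <- build_network(pop, config$max_in, config$max_out,
                       config$connection_probs, seeds[["network"]])
  set.seed(seeds[["dynamics"]])

  cd <- pop_codes(pop)
  type <- cd$type; freq <- cd$freq; left <- cd$left
  typed <- type != 3L
  typed_idx <- which(typed)
  d <- pop$d; t_L <- pop$t_L; t_S <- pop$t_S
  silenced <- match(config$silenced_types, TYPE_LEVELS)
  spont_rates <- c(config$spont_rate_pkc, config$spont_rate_som)
  end1 <- net$end1; end2 <- net$end2
  n_ticks <- length(protocol)
  levs <- if (n_ticks) current_level_index(protocol) else integer(0)

  # precomputed truncation CDF bounds per table cell: one qnorm per draw
  tp <- precompute_table(table)
  # links sorted by receiver: incoming sums per tick via one cumsum
  lk <- NULL
  if (nrow(net) && !config$cascade) {
    ord <- order(end2)
    e1s <- end1[ord]; e2s <- end2[ord]
    ends <- c(which(diff(e2s) != 0L), length(e2s))
    lk <- list(e1s = e1s, recv = e2s[ends], ends = ends,
               starts = c(1L, ends[-length(ends)] + 1L))
  }
  # per-neuron masks that change only when a conversion occurs
  masks <- NULL
  refresh_masks <- function() {
    act <- which(freq == 1L | freq == 2L)
    list(act = act, cell = type[act] + 2L * (freq[act] - 1L),
         sp = which(freq == 3L),
         pk = which(typed & type == 1L & freq != 3L),
         so = which(typed & type == 2L & freq != 3L))
  }
  masks <- refresh_masks()

  rec <- matrix(NA_real_, nrow = n_ticks, ncol = 9L)
  rates <- list()
  cum_s <- 0L
  n_conv_total <- 0L
  fr <- numeric(length(type))
  inhibited <- logical(length(type))

  for (i in seq_len(n_ticks)) {
    s_i <- protocol[i]
    cum_s <- cum_s + (s_i >= 120)
    d <- k_damage(d, t_L, t_S, typed, cum_s, s_i)
    cv <- k_convert(freq, type, left, d, config$post_injury_rs_som_target,
                    config$conversion_scope)
    if (cv$n_converted > 0L) {
      freq <- cv$freq
      n_conv_total <- n_conv_total + cv$n_converted
      masks <- refresh_masks()
    }
    # firing rates
    fr[] <- 0
    fr[masks$sp] <- spont_rates[type[masks$sp]]
    lev <- levs[i]
    if (lev > 0L && length(masks$act)) {
      act <- masks$act; cell <- masks$cell
      x <- tp$mu_x[cell, lev] + tp$sigma_x[cell, lev] *
        stats::qnorm(tp$plo_x[cell, lev] +
                     stats::runif(length(act)) * tp$span_x[cell, lev])
      y <- tp$mu_y[cell, lev] + tp$sigma_y[cell, lev] *
        stats::qnorm(tp$plo_y[cell, lev] +
                     stats::runif(length(act)) * tp$span_y[cell, lev])
      x <- pmin(pmax(x, tp$lo_x[cell, lev]), tp$hi_x[cell, lev])
      y <- pmin(pmax(y, tp$lo_y[cell, lev]), tp$hi_y[cell, lev])
      w <- d[act] / 100
      fr[act] <- (1 - w) * x + w * y
    }
    if (length(silenced)) fr[type %in% silenced] <- 0
    fr_pre <- fr
    # inhibition
    if (!is.null(lk)) {
      str <- fr[lk$e1s]
      cs <- cumsum(str)
      incoming <- cs[lk$ends] - cs[lk$starts] + str[lk$starts]
      hit <- lk$recv[incoming >= config$inhibition_threshold]
      hit <- hit[type[hit] != 3L]
      inhibited[] <- FALSE
      inhibited[hit] <- TRUE
      fr[hit] <- 0
    } else if (nrow(net) && config$cascade) {
      ih <- k_inhibit(fr, end1, end2, typed, config$inhibition_threshold,
                      TRUE)
      fr <- ih$fr; inhibited <- ih$inhibited
    } else {
      inhibited[] <- FALSE
    }
    # pain
    pk <- masks$pk; so <- masks$so
    pl <- left[pk]; sl <- left[so]
    pk_contrib <- d[pk] / 100 * fr[pk]
    p_left <- sum(pk_contrib[pl]) - sum(fr[so][sl])
    p_right <- sum(pk_contrib[!pl]) - sum(fr[so][!sl])
    rec[i, ] <- c(s_i, cum_s, p_left + p_right, p_left, p_right,
                  mean(d[typed_idx]), sum(inhibited),
                  sum(inhibited[typed_idx] & type[typed_idx] == 2L),
                  cv$n_converted)
    if (i %in% record_rates_at) {
      rates[[as.character(i)]] <- data.frame(
        id = pop$id[typed], loc = pop$loc[typed],
        type = TYPE_LEVELS[type[typed]], freq = FREQ_LEVELS[freq[typed]],
        fr_pre = fr_pre[typed], fr_post = fr[typed],
        stringsAsFactors = FALSE)
    }
  }

  records <- data.frame(tick = seq_len(n_ticks))
  records <- cbind(records, as.data.frame(rec))
  names(records) <- c("tick", "S", "cum_S", "pain_total", "pain_left",
                      "pain_right", "mean_damage", "n_inhibited",
                      "n_inhibited_SOM", "n_converted")

  pop$d <- d
  pop$freq <- FREQ_LEVELS[freq]
  pop$fr <- ifelse(typed, fr, NA_real_)
  pop$inhibited <- ifelse(typed, inhibited, NA)
  pop$num_in <- attr(net, "num_in")
  pop$num_out <- attr(net, "num_out")

  structure(list(records = records, n_links = nrow(net),
                 n_converted_total = n_conv_total, population = pop,
                 network = net, rates = rates, config = config,
                 seed = seed),
            class = "cea_simulation")
}

#' @export
print.cea_simulation <- function(x, ...) {
  r <- x$records
  cat("CeA simulation:", nrow(r), "ticks,", x$n_links, "links, seed",
      x$seed, "\n")
  if (nrow(r)) {
    cat(sprintf("  pain: first %.1f, last %.1f; final mean damage %.1f%%\n",
                r$pain_total[1], r$pain_total[nrow(r)],
                r$mean_damage[nrow(r)]))
    cat(sprintf("  spontaneous-to-RS SOM conversions: %d\n",
                x$n_converted_total))
  }
  invisible(x)
}

#' Write per-tick simulation records to CSV
#'
#' @param sim A `cea_simulation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_simulation_csv <- function(sim, path) {
  stopifnot(inherits(sim, "cea_simulation"))
  utils::write.csv(sim$records, path, row.names = FALSE)
  invisible(path)
}
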