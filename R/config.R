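#' Model configuration
#'
#' Build the configuration object holding all population, network, and
#' dynamics parameters of the CeA model. Defaults correspond to the
#' published study conditions: 1640 agents (1600 PKCd/SOM neurons split
#' equally across hemispheres plus 40 passive "Other" neurons), firing
#' frequency proportions of 25/48/27 percent (LF/RS/Spont) for PKCd and
#' 18/27/55 percent for SOM, damage latency drawn uniformly from 40-80
#' ticks, sensitization period from 50-150 ticks, a 15 Hz inhibition
#' threshold, and a 3:3 network.
#'
#' @param model One of `"50:50"`, `"60:40"`, `"30:70"`, selecting the
#'   hemisphere-specific PKCd:SOM proportions explored in the study:
#'   equal proportions, 56:44 in both hemispheres (renormalized
#'   immunohistochemistry counts), or 30:70 on the left with 37:63 on the
#'   right (reporter-line cell counts).
#' @param max_in,max_out Maximum incoming / outgoing connections per
#'   PKCd or SOM neuron. `0` disables the network.
#' @param inhibition_threshold Summed incoming signal strength (Hz) at or
#'   above which a neuron is inhibited for the tick.
#' @param silenced_types Character vector, subset of `c("PKCd", "SOM")`.
#'   Silenced neurons fire at 0 Hz (chemogenetic inhibition analogue):
#'   they neither inhibit others nor contribute to pain.
#' @param pct_som_left,pct_som_right Fraction of typed neurons per
#'   hemisphere that are SOM; overrides `model` when supplied.
#' @param freq_proportions Named list with elements `PKCd` and `SOM`,
#'   each a named numeric vector over `LF`, `RS`, `Spont` summing to 1.
#' @param connection_probs Connection probability table, see
#'   [connection_probability_table()].
#' @param post_injury_rs_som_target Target fraction of SOM neurons that
#'   are regular spiking after injury; drives the spontaneous-to-RS
#'   conversion rule.
#' @param conversion_scope `"hemisphere"` (default) evaluates the RS SOM
#'   conversion target per hemisphere, `"global"` across both.
#' @param cascade Logical; if `TRUE`, inhibition is evaluated neuron by
#'   neuron in random order and an inhibited neuron's outgoing signals
#'   are removed for neurons evaluated later in the same tick. Default
#'   `FALSE`: all signal strengths are frozen at the pre-inhibition
#'   firing rates.
#' @param t_L_range,t_S_range Integer ranges (inclusive) for the damage
#'   latency period and sensitization period.
#' @param spont_rate_pkc,spont_rate_som Constant firing rates (Hz) of
#'   spontaneously active neurons.
#' @param n_typed,n_other Number of PKCd/SOM neurons and of passive
#'   "Other" neurons (split equally across hemispheres).
#' @param seed Optional integer seed stored with the configuration and
#'   used by [run_simulation()] when no explicit seed is given.
#'
#' @return An object of class `cea_config` (a named list).
#' @examples
#' cfg <- cea_config("30:70")
#' cfg$pct_som_left
#' @export
cea_config <- function(model = c("50:50", "60:40", "30:70"),
                       max_in = 3L, max_out = 3L,
                       inhibition_threshold = 15,
                       silenced_types = character(0),
                       pct_som_left = NULL, pct_som_right = NULL,
                       freq_proportions = default_freq_proportions(),
                       connection_probs = connection_probability_table(),
                       post_injury_rs_som_target = 0.48,
                       conversion_scope = c("hemisphere", "global"),
                       cascade = FALSE,
                       t_L_range = c(40L, 80L), t_S_range = c(50L, 150L),
                       spont_rate_pkc = 2.838, spont_rate_som = 4.887,
                       n_typed = 1600L, n_other = 40L,
                       seed = NULL) {
  model <- match.arg(model)
  conversion_scope <- match.arg(conversion_scope)
  som <- switch(model,
    "50:50" = c(0.50, 0.50),
    "60:40" = c(0.44, 0.44),  # renormalized 48%/38% counts
    "30:70" = c(0.70, 0.63))
  if (is.null(pct_som_left)) pct_som_left <- som[1]
  if (is.null(pct_som_right)) pct_som_right <- som[2]
  stopifnot(
    pct_som_left >= 0, pct_som_left <= 1,
    pct_som_right >= 0, pct_som_right <= 1,
    max_in >= 0, max_out >= 0,
    n_typed > 0, n_other >= 0,
    inhibition_threshold >= 0
  )
  if (n_typed %% 2L != 0L)
    stop("`n_typed` must be even (typed neurons are split equally across hemispheres)")
  if (n_other %% 2L != 0L)
    stop("`n_other` must be even (Other neurons are split equally across hemispheres)")
  for (ty in c("PKCd", "SOM")) {
    p <- freq_proportions[[ty]]
    if (is.null(p) || !all(c("LF", "RS", "Spont") %in% names(p)))
      stop("`freq_proportions$", ty, "` must be named over LF, RS, Spont")
    if (abs(sum(p) - 1) > 1e-6)
      stop("`freq_proportions$", ty, "` must sum to 1")
    if (any(p < 0)) stop("`freq_proportions$", ty, "` must be non-negative")
  }
  validate_connection_probs(connection_probs)
  if (!all(silenced_types %in% c("PKCd", "SOM")))
    stop("`silenced_types` must be a subset of c(\"PKCd\", \"SOM\")")
  structure(list(
    model = model,
    n_agents_total = n_typed + n_other,
    n_typed = as.integer(n_typed),
    n_other = as.integer(n_other),
    pct_som_left = pct_som_left,
    pct_som_right = pct_som_right,
    freq_proportions = freq_proportions,
    t_L_range = as.integer(t_L_range),
    t_S_range = as.integer(t_S_range),
    spont_rate_pkc = spont_rate_pkc,
    spont_rate_som = spont_rate_som,
    inhibition_threshold = inhibition_threshold,
    max_in = as.integer(max_in),
    max_out = as.integer(max_out),
    connection_probs = connection_probs,
    silenced_types = silenced_types,
    post_injury_rs_som_target = post_injury_rs_som_target,
    conversion_scope = conversion_scope,
    cascade = cascade,
    seed = seed
  ), class = "cea_config")
}

#' @export
print.cea_config <- function(x, ...) {
  cat("CeA model configuration (", x$model, " base)\n", sep = "")
  cat(sprintf("  agents: %d typed + %d Other\n", x$n_typed, x$n_other))
  cat(sprintf("  SOM fraction: left %.2f, right %.2f\n",
              x$pct_som_left, x$pct_som_right))
  cat(sprintf("  network: %d:%d, inhibition threshold %g Hz\n",
              x$max_in, x$max_out, x$inhibition_threshold))
  if (length(x$silenced_types))
    cat("  silenced:", paste(x$silenced_types, collapse = ", "), "\n")
  invisible(x)
}

#' Default firing-frequency proportions
#'
#' Proportions of late-firing (LF), regular-spiking (RS), and
#' spontaneously active neurons within each cell type at initialization,
#' as observed in slice physiology of control mice.
#'
#' @return Named list with numeric vectors `PKCd` and `SOM`.
#' @export
default_freq_proportions <- function() {
  list(
    PKCd = c(LF = 0.25, RS = 0.48, Spont = 0.27),
    SOM  = c(LF = 0.18, RS = 0.27, Spont = 0.55)
  )
}

#' Renormalize two reported cell-type proportions
#'
#' Immunohistochemistry studies report the fractions of counted CeA
#' neurons positive for each marker, leaving out double-labeled and
#' unlabeled cells. To use such data as the two-type split of the model,
#' the pair is renormalized to sum to one and rounded to whole percent.
#' With the published 48% PKCd / 38% SOM counts this yields the 56:44
#' split behind the "60:40" model.
#'
#' @param pct_a,pct_b Reported fractions (either proportions in `[0, 1]`
#'   or percentages; both on the same scale).
#' @return Numeric vector of length 2 summing to 1, rounded to whole
#'   percent.
#' @examples
#' renormalize_reported_proportions(0.48, 0.38)  # 0.56 0.44
#' @export
renormalize_reported_proportions <- function(pct_a, pct_b) {
  stopifnot(is.numeric(pct_a), is.numeric(pct_b),
            length(pct_a) == 1L, length(pct_b) == 1L,
            pct_a >= 0, pct_b >= 0)
  tot <- pct_a + pct_b
  if (tot <= 0) stop("at least one of the two proportions must be positive")
  round(c(pct_a, pct_b) / tot, 2)
}

#' Read a model configuration from a YAML file
#'
#' Keys mirror the arguments of [cea_config()]; `freq_proportions` is a
#' nested mapping `PKCd:/SOM:` over `LF`, `RS`, `Spont`, and
#' `connection_probs` a nested mapping from transmitter type to receiver
#' type probabilities. Unknown keys raise an error.
#'
#' @param path Path to a YAML file.
#' @return A `cea_config` object.
#' @export
read_model_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(cea_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  if (!is.null(raw$freq_proportions))
    raw$freq_proportions <- lapply(raw$freq_proportions, unlist)
  if (!is.null(raw$connection_probs)) {
    cp <- raw$connection_probs
    m <- rbind(PKCd = unlist(cp$PKCd)[c("PKCd", "SOM", "Other")],
               SOM  = unlist(cp$SOM)[c("PKCd", "SOM", "Other")])
    colnames(m) <- c("PKCd", "SOM", "Other")
    raw$connection_probs <- m
  }
  do.call(cea_config, raw)
}

# Derive named, independent substream seeds from one root seed so that the
# initialization, network construction, and per-tick dynamics draws can be
# reproduced separately. Seeds stay below 2^31.
derive_substream_seeds <- function(seed, streams = c("init", "network", "dynamics")) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  out <- sample.int(.Machine$integer.max - 1L, length(streams))
  names(out) <- streams
  out
}
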