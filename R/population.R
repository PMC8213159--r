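#' Initialize the agent population
#'
#' Creates the full set of agents: per hemisphere, `n_typed / 2` PKCd or
#' SOM neurons plus `n_other / 2` passive "Other" neurons. Each typed
#' neuron receives a firing-frequency class (LF, RS, or Spont) according
#' to the type-specific proportions, a damage latency period `t_L` drawn
#' uniformly from `t_L_range`, a sensitization period `t_S` drawn
#' uniformly from `t_S_range`, zero damage, zero connection counters,
#' and uninhibited status. Other neurons act as passive signal sinks and
#' carry none of these variables.
#'
#' Category counts are obtained by rounding each proportion times the
#' category total to the nearest integer; any remainder is assigned to
#' the largest category so totals are exact.
#'
#' @param config A [cea_config()] object.
#' @param seed Optional integer seed; when `NULL`, the current RNG state
#'   is used.
#' @return A data frame of class `cea_population` with one row per agent
#'   and columns `id`, `loc` (`"Left"`/`"Right"`), `type`
#'   (`"PKCd"`/`"SOM"`/`"Other"`), `freq` (`"LF"`/`"RS"`/`"Spont"`, `NA`
#'   for Other), `t_L`, `t_S`, `d`, `num_in`, `num_out`, `inhibited`,
#'   `fr`.
#' @examples
#' pop <- initialize_population(cea_config("50:50"), seed = 1)
#' table(pop$loc, pop$type)
#' @export
initialize_population <- function(config, seed = NULL) {
  stopifnot(inherits(config, "cea_config"))
  if (!is.null(seed)) set.seed(as.integer(seed))

  half_typed <- config$n_typed %/% 2L
  half_other <- config$n_other %/% 2L

  hemi <- function(loc, pct_som) {
    n_som <- rounded_counts(c(PKCd = 1 - pct_som, SOM = pct_som), half_typed)
    type <- rep(c("PKCd", "SOM"), n_som)
    freq <- character(half_typed)
    for (ty in c("PKCd", "SOM")) {
      idx <- which(type == ty)
      cnt <- rounded_counts(config$freq_proportions[[ty]], length(idx))
      freq[idx] <- rep(names(cnt), cnt)
    }
    data.frame(
      loc = loc, type = type, freq = freq,
      t_L = sample(config$t_L_range[1]:config$t_L_range[2], half_typed, replace = TRUE),
      t_S = sample(config$t_S_range[1]:config$t_S_range[2], half_typed, replace = TRUE),
      d = 0, num_in = 0L, num_out = 0L, inhibited = FALSE, fr = 0,
      stringsAsFactors = FALSE
    )
  }
  typed <- rbind(hemi("Left", config$pct_som_left),
                 hemi("Right", config$pct_som_right))
  other <- data.frame(
    loc = rep(c("Left", "Right"), each = half_other),
    type = "Other", freq = NA_character_,
    t_L = NA_integer_, t_S = NA_integer_, d = NA_real_,
    num_in = 0L, num_out = 0L, inhibited = NA, fr = NA_real_,
    stringsAsFactors = FALSE
  )
  pop <- rbind(typed, other)
  pop <- cbind(id = seq_len(nrow(pop)), pop)
  class(pop) <- c("cea_population", "data.frame")
  pop
}

# Round proportions to integer category counts; the remainder (positive or
# negative) is absorbed by the largest category so counts always sum to n.
rounded_counts <- function(props, n) {
  stopifnot(abs(sum(props) - 1) < 1e-6, n >= 0)
  cnt <- round(props * n)
  rem <- n - sum(cnt)
  if (rem != 0) {
    k <- which.max(props)
    cnt[k] <- cnt[k] + rem
  }
  if (any(cnt < 0)) stop("rounding produced a negative category count")
  storage.mode(cnt) <- "integer"
  cnt
}

#' Summarize a population by hemisphere, type, and firing class
#'
#' @param pop A `cea_population`.
#' @return A data frame of counts.
#' @export
population_counts <- function(pop) {
  stopifnot(inherits(pop, "cea_population"))
  as.data.frame(table(loc = pop$loc, type = pop$type,
                      freq = addNA(factor(pop$freq)), useNA = "no"),
                responseName = "n")
}
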