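# Shared fixtures, all built in code.

# Distribution table whose cells are point masses: X always equals x_val,
# Y always equals y_val. Makes the firing-rate mixture deterministic.
degenerate_table <- function(x_val = 10, y_val = 30) {
  grid <- expand.grid(type = c("PKCd", "SOM"), freq = c("LF", "RS"),
                      state = c("X", "Y"), current_pA = distribution_levels(),
                      stringsAsFactors = FALSE)
  grid$mu <- ifelse(grid$state == "X", x_val, y_val)
  grid$sigma <- 0
  grid$min <- grid$mu
  grid$max <- grid$mu
  as_distribution_table(grid)
}

# Hand-built miniature population. `...` are equal-length vectors for the
# columns that matter; remaining columns get neutral defaults.
toy_population <- function(type, freq = NA_character_, loc = "Left",
                           d = 0, fr = 0, t_L = 40L, t_S = 100L) {
  n <- length(type)
  pop <- data.frame(
    id = seq_len(n), loc = rep_len(loc, n), type = type,
    freq = rep_len(freq, n), t_L = rep_len(as.integer(t_L), n),
    t_S = rep_len(as.integer(t_S), n), d = rep_len(d, n),
    num_in = 0L, num_out = 0L, inhibited = FALSE, fr = rep_len(fr, n),
    stringsAsFactors = FALSE)
  class(pop) <- c("cea_population", "data.frame")
  pop
}

toy_network <- function(end1, end2) {
  net <- data.frame(end1 = as.integer(end1), end2 = as.integer(end2))
  class(net) <- c("cea_network", "data.frame")
  net
}

# Independent brute-force evaluation of the pain measure: explicit loop
# over agents, no vectorized shortcuts shared with the implementation.
brute_force_pain <- function(pop) {
  total <- 0
  for (i in seq_len(nrow(pop))) {
    if (is.na(pop$freq[i]) || pop$freq[i] == "Spont") next
    if (pop$type[i] == "PKCd") total <- total + pop$d[i] / 100 * pop$fr[i]
    if (pop$type[i] == "SOM") total <- total - pop$fr[i]
  }
  total
}

# Closed-form damage trajectory under constant >= 120 pA stimulation:
# zero through the latency period, then linear accrual over t_S ticks.
closed_form_damage <- function(tick, t_L, t_S) {
  pmin(100, pmax(0, tick - t_L) * (100 / t_S))
}
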