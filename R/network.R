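#' Connection probability table
#'
#' Probabilities that a directed inhibitory connection transmitted by a
#' PKCd or SOM neuron targets each receiving type. Defaults are the
#' frequencies of classified connected neuron pairs reported in paired
#' recording / immunohistochemistry data: of all classified connections,
#' 20% were PKCd-to-PKCd, 10% PKCd-to-SOM, 55% SOM-to-SOM, and 15%
#' SOM-to-PKCd; the remainder targets neurons expressing neither marker
#' ("Other").
#'
#' @param pkc_to_pkc,pkc_to_som,som_to_pkc,som_to_som Connection
#'   probabilities; each transmitter row is completed by the
#'   corresponding to-Other probability so rows sum to 1.
#' @return A 2 x 3 matrix with rows `PKCd`, `SOM` and columns `PKCd`,
#'   `SOM`, `Other`.
#' @export
connection_probability_table <- function(pkc_to_pkc = 0.20, pkc_to_som = 0.10,
                                         som_to_pkc = 0.15, som_to_som = 0.55) {
  m <- rbind(
    PKCd = c(PKCd = pkc_to_pkc, SOM = pkc_to_som,
             Other = 1 - pkc_to_pkc - pkc_to_som),
    SOM = c(PKCd = som_to_pkc, SOM = som_to_som,
            Other = 1 - som_to_pkc - som_to_som)
  )
  validate_connection_probs(m)
  m
}

validate_connection_probs <- function(m) {
  if (!is.matrix(m) || !identical(dim(m), c(2L, 3L)) ||
      !identical(rownames(m), c("PKCd", "SOM")) ||
      !identical(colnames(m), c("PKCd", "SOM", "Other")))
    stop("connection probabilities must be a 2 x 3 matrix with rows ",
         "PKCd/SOM and columns PKCd/SOM/Other")
  if (any(m < -1e-9)) stop("connection probabilities must be non-negative")
  if (any(abs(rowSums(m) - 1) > 1e-6))
    stop("each row of the connection probability table must sum to 1")
  invisible(m)
}

#' Sample the receiving type of a connection
#'
#' @param probs Connection probability table, see
#'   [connection_probability_table()].
#' @param transmitter_type `"PKCd"` or `"SOM"`.
#' @return One of `"PKCd"`, `"SOM"`, `"Other"`.
#' @export
sample_receiver_type <- function(probs, transmitter_type) {
  validate_connection_probs(probs)
  stopifnot(transmitter_type %in% c("PKCd", "SOM"))
  sample(colnames(probs), 1L, prob = probs[transmitter_type, ])
}

#' Build the inhibitory connection network
#'
#' Stochastically creates the directed, intra-hemisphere network through
#' which neurons transmit inhibitory signals. Within each hemisphere the
#' algorithm repeatedly picks, uniformly at random, a PKCd or SOM neuron
#' with fewer than `max_out` outgoing links as transmitter, samples the
#' receiving type from the connection probability table, and picks a
#' random same-hemisphere receiver of that type with fewer than `max_in`
#' incoming links ("Other" receivers have no in-limit). Links never
#' cross hemispheres and self-loops are disallowed; parallel links
#' between the same ordered pair may occur. Construction ends when every
#' PKCd/SOM neuron has reached `max_out` outgoing links (or, in the rare
#' case that a transmitter's draws fail repeatedly because all potential
#' receivers are saturated, when that transmitter has been abandoned).
#'
#' @param pop A `cea_population`.
#' @param max_in,max_out Per-neuron connection limits (`>= 0`).
#' @param probs Connection probability table.
#' @param seed Optional integer seed.
#' @param max_failed_draws Number of failed receiver draws after which a
#'   transmitter is abandoned.
#' @return A data frame of class `cea_network` with columns `end1`
#'   (transmitting agent id) and `end2` (receiving agent id), and
#'   attributes `num_in` / `num_out` giving per-agent link counts.
#' @examples
#' pop <- initialize_population(cea_config("50:50"), seed = 1)
#' net <- build_network(pop, max_in = 1, max_out = 1, seed = 2)
#' nrow(net)  # 1600
#' @export
build_network <- function(pop, max_in, max_out,
                          probs = connection_probability_table(),
                          seed = NULL, max_failed_draws = 100L) {
  stopifnot(inherits(pop, "cea_population"))
  if (max_in < 0 || max_out < 0) stop("max_in and max_out must be >= 0")
  validate_connection_probs(probs)
  if (!is.null(seed)) set.seed(as.integer(seed))

  n <- nrow(pop)
  num_in <- integer(n); num_out <- integer(n)
  e1 <- integer(0); e2 <- integer(0)

  for (hemi in c("Left", "Right")) {
    in_hemi <- pop$loc == hemi
    ids <- list(PKCd = pop$id[in_hemi & pop$type == "PKCd"],
                SOM = pop$id[in_hemi & pop$type == "SOM"],
                Other = pop$id[in_hemi & pop$type == "Other"])
    res <- build_hemisphere(ids, max_in, max_out, probs, max_failed_draws)
    e1 <- c(e1, res$end1); e2 <- c(e2, res$end2)
    num_in[res$ids] <- res$num_in
    num_out[res$ids] <- res$num_out
  }
  net <- data.frame(end1 = e1, end2 = e2)
  class(net) <- c("cea_network", "data.frame")
  attr(net, "num_in") <- num_in
  attr(net, "num_out") <- num_out
  net
}

# One hemisphere of the network algorithm. Transmitter and receiver pools
# are kept as flat vectors with swap-with-last removal so each link costs
# O(1) regardless of population size.
build_hemisphere <- function(ids, max_in, max_out, probs, max_failed_draws) {
  all_ids <- c(ids$PKCd, ids$SOM, ids$Other)
  n_typed <- length(ids$PKCd) + length(ids$SOM)
  loc_type <- rep.int(1:3, c(length(ids$PKCd), length(ids$SOM),
                             length(ids$Other)))
  num_in <- integer(length(all_ids)); num_out <- integer(length(all_ids))
  # cumulative receiver-type probabilities per transmitter row
  cum_probs <- t(apply(probs, 1, cumsum))

  out_pool <- if (max_out > 0L) seq_len(n_typed) else integer(0)
  in_pool <- if (max_in > 0L) {
    list(which(loc_type == 1L), which(loc_type == 2L))
  } else list(integer(0), integer(0))
  other_pos <- which(loc_type == 3L)

  cap <- n_typed * max_out
  e1 <- integer(cap); e2 <- integer(cap); k <- 0L

  pool_drop <- function(pool, value) {  # swap-with-last removal
    i <- match(value, pool)
    pool[i] <- pool[length(pool)]
    pool[-length(pool)]
  }

  while (length(out_pool)) {
    tr <- out_pool[sample.int(length(out_pool), 1L)]
    rc <- NA_integer_
    for (attempt in seq_len(max_failed_draws)) {
      rt <- findInterval(stats::runif(1), cum_probs[loc_type[tr], ],
                         left.open = TRUE) + 1L
      if (rt == 3L) {  # Other: passive sink, no in-limit
        if (length(other_pos)) {
          rc <- other_pos[sample.int(length(other_pos), 1L)]
          break
        }
      } else {
        cand <- in_pool[[rt]]
        if (length(cand) > 1L || (length(cand) == 1L && cand[1L] != tr)) {
          repeat {  # rejection on self-loop
            rc <- cand[sample.int(length(cand), 1L)]
            if (rc != tr) break
          }
          break
        }
      }
      rc <- NA_integer_
    }
    if (is.na(rc)) {  # all draws failed: abandon this transmitter
      out_pool <- pool_drop(out_pool, tr)
      next
    }
    k <- k + 1L; e1[k] <- tr; e2[k] <- rc
    num_out[tr] <- num_out[tr] + 1L
    num_in[rc] <- num_in[rc] + 1L
    if (num_out[tr] >= max_out) out_pool <- pool_drop(out_pool, tr)
    if (loc_type[rc] != 3L && num_in[rc] >= max_in)
      in_pool[[loc_type[rc]]] <- pool_drop(in_pool[[loc_type[rc]]], rc)
  }
  list(end1 = all_ids[e1[seq_len(k)]], end2 = all_ids[e2[seq_len(k)]],
       ids = all_ids, num_in = num_in, num_out = num_out)
}

#' @export
print.cea_network <- function(x, ...) {
  cat("CeA inhibitory network:", nrow(x), "directed links\n")
  invisible(x)
}

#' Write / read a network edge list
#'
#' Plain-text dump (one `end1 end2 hemisphere` triple per line, tab
#' separated, with header) for inspection and replay.
#'
#' @param net A `cea_network`.
#' @param pop The `cea_population` the network was built on (provides
#'   hemisphere labels).
#' @param path Output (input) file path.
#' @return `write_edge_list()` returns `path` invisibly;
#'   `read_edge_list()` returns a data frame with columns `end1`,
#'   `end2`, `hemisphere`.
#' @export
write_edge_list <- function(net, pop, path) {
  stopifnot(inherits(net, "cea_network"), inherits(pop, "cea_population"))
  df <- data.frame(end1 = net$end1, end2 = net$end2,
                   hemisphere = pop$loc[match(net$end1, pop$id)])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
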