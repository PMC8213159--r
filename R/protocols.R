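validate_protocol <- function(protocol) {
  if (length(protocol) == 0L) return(integer(0))
  if (!is.numeric(protocol) || any(!is.finite(protocol)) ||
      any(protocol != round(protocol)))
    stop("stimulation values must be integers")
  if (any(protocol < 0 | protocol > 220))
    stop("stimulation values must lie in [0, 220] pA")
  as.integer(protocol)
}

#' Read a stimulation protocol file
#'
#' The protocol is a plain-text file with one integer current value in
#' picoamperes per line, each in `[0, 220]`; its length defines the
#' simulation duration. Non-integer tokens and out-of-range values are
#' rejected with the offending line number.
#'
#' @param path Path to the protocol file.
#' @return Integer vector of currents (possibly empty).
#' @export
read_stimulation_file <- function(path) {
  if (!file.exists(path)) stop("stimulation file not found: ", path)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(integer(0))
  ok_int <- grepl("^[+-]?[0-9]+$", lines)
  if (any(!ok_int))
    stop("non-integer stimulation value at line ", which(!ok_int)[1],
         ": \"", lines[which(!ok_int)[1]], "\"")
  vals <- as.integer(lines)
  bad <- vals < 0 | vals > 220
  if (any(bad))
    stop("stimulation value out of range [0, 220] at line ", which(bad)[1],
         ": ", vals[which(bad)[1]])
  vals
}

#' Write a stimulation protocol file
#'
#' @param protocol Integer vector of currents (pA).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stimulation_file <- function(protocol, path) {
  protocol <- validate_protocol(protocol)
  writeLines(as.character(protocol), path)
  invisible(path)
}

#' Generate a stimulation protocol
#'
#' Builds the stimulation scenarios used in the simulation experiments:
#' a constant current, or a stepwise ramp that starts at 120 pA, climbs
#' the 20 pA grid to 220 pA, and returns to 120 pA. Ramp plateaus split
#' the duration as evenly as possible across the seven levels
#' (120, 140, 160, 180, 200, 220, 120), any remainder going to the
#' leading plateaus.
#'
#' @param kind `"constant"` or `"ramp"`.
#' @param length Number of ticks.
#' @param level Current (pA) for `kind = "constant"`; must be an
#'   integer in `[0, 220]`. Levels below 120 pA are allowed but produce
#'   no damage (a warning is issued).
#' @return Integer vector of currents, one per tick.
#' @examples
#' table(generate_protocol("ramp", 250))
#' @export
generate_protocol <- function(kind = c("constant", "ramp"), length = 250L,
                              level = 120L) {
  kind <- match.arg(kind)
  stopifnot(length >= 0)
  if (kind == "constant") {
    prot <- validate_protocol(rep(level, length))
    if (length > 0 && level < 120)
      warning("constant level below 120 pA: neurons accrue no damage")
    return(prot)
  }
  levels <- c(seq(120L, 220L, by = 20L), 120L)
  base <- length %/% length(levels)
  extra <- length %% length(levels)
  reps <- rep(base, length(levels)) + c(rep(1L, extra),
                                        rep(0L, length(levels) - extra))
  validate_protocol(rep(levels, reps))
}
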