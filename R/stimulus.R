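#' Bath GABA application protocol
#'
#' A spatially uniform ("bath") GABA stimulus: zero before onset, held at
#' \code{dose} for \code{duration}, then cleared exponentially at the
#' clearance rate (default \code{ln(2)/3} per second, i.e. a 3-s half-life).
#'
#' @param dose bath GABA concentration during the stimulus (uM); the standard
#'   experiment uses 0, 1, 5 or 10 uM but any non-negative dose is accepted
#' @param t_on stimulus onset (s)
#' @param duration stimulus duration (s)
#' @param clearance clearance rate after offset (s^-1)
#' @return an object of class \code{gaba_protocol}
#' @export
#' @examples
#' pr <- gaba_protocol(10)
#' gaba_concentration(pr, c(0.5, 1.2, 1.5 + 3))  # 0, plateau, one half-life
gaba_protocol <- function(dose = 0, t_on = 1.0, duration = 0.5,
                          clearance = log(2) / 3) {
  stopifnot(dose >= 0, t_on >= 0, duration > 0, clearance > 0)
  structure(list(dose = dose, t_on = t_on, duration = duration,
                 clearance = clearance),
            class = "gaba_protocol")
}

#' Bath GABA concentration at given times
#'
#' Evaluates the hold-then-decay protocol: the concentration is \code{dose} on
#' \code{[t_on, t_on + duration]} and decays exponentially afterwards, so it
#' is continuous at offset, non-negative, and non-increasing after offset.
#' The bath is global: every synapse and astrocyte sees the same
#' concentration.
#'
#' @param protocol a \code{\link{gaba_protocol}} object
#' @param t time or vector of times (s), non-negative
#' @return concentrations (uM), vectorized over \code{t}
#' @export
gaba_concentration <- function(protocol, t) {
  stopifnot(all(t >= 0))
  t_off <- protocol$t_on + protocol$duration
  out <- numeric(length(t))
  on <- t >= protocol$t_on & t <= t_off
  after <- t > t_off
  out[on] <- protocol$dose
  out[after] <- protocol$dose * exp(-protocol$clearance * (t[after] - t_off))
  out
}
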