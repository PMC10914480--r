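# Temperature replica-exchange machinery: ladder construction and the
# Metropolis exchange criterion.

BOLTZMANN_KCAL <- 0.0019872041  # kcal/mol/K

#' Build a geometric temperature ladder
#'
#' Temperatures follow \eqn{T_i = T_{min} r^i} with
#' \eqn{r = (T_{max}/T_{min})^{1/(n-1)}}, endpoints exact. A geometric ladder
#' gives (approximately) uniform exchange probability between neighbours for
#' systems with temperature-independent heat capacity; the target exchange
#' probability is carried as a reported diagnostic, not a fitted constraint.
#'
#' @param n_replicas Number of rungs (>= 2).
#' @param t_min,t_max Endpoint temperatures in K (defaults 275 and 500).
#' @param target_exchange Target neighbour exchange probability carried for
#'   diagnostics (default 0.4).
#' @return Object of class `temperature_ladder`: list with `temperatures` (K)
#'   and `target_exchange`.
#' @export
#' @examples
#' build_temperature_ladder(3)$temperatures  # middle rung = sqrt(275*500)
build_temperature_ladder <- function(n_replicas, t_min = 275, t_max = 500,
                                     target_exchange = 0.4) {
  if (n_replicas < 2) stop("need at least 2 replicas", call. = FALSE)
  stopifnot(t_min > 0, t_min < t_max)
  r <- (t_max / t_min)^(1 / (n_replicas - 1))
  temps <- t_min * r^(seq_len(n_replicas) - 1)
  temps[n_replicas] <- t_max  # exact endpoint
  structure(list(temperatures = temps, target_exchange = target_exchange),
            class = "temperature_ladder")
}

#' Metropolis replica-exchange acceptance
#'
#' Accepts a configuration swap between replicas at temperatures `temp_i` and
#' `temp_j` with probability
#' \eqn{\min(1, \exp[(\beta_i - \beta_j)(E_i - E_j)])},
#' \eqn{\beta = 1/(k_B T)} with energies in kcal/mol.
#'
#' @param energy_i,energy_j Potential energies (kcal/mol).
#' @param temp_i,temp_j Temperatures (K), both > 0.
#' @return Logical: whether the exchange is accepted. Uses R's RNG stream.
#' @export
attempt_exchange <- function(energy_i, temp_i, energy_j, temp_j) {
  stopifnot(temp_i > 0, temp_j > 0)
  bi <- 1 / (BOLTZMANN_KCAL * temp_i)
  bj <- 1 / (BOLTZMANN_KCAL * temp_j)
  delta <- (bi - bj) * (energy_i - energy_j)
  if (delta >= 0) return(TRUE)
  stats::runif(1) < exp(delta)
}
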