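#' @title Competing-reaction kinetics: coupling vs protodeboronation
#'
#' @description
#' A boronic acid A that is meant to couple with partner B competes with
#' its own degradation:
#'
#' * `A + B -> C` — intended coupling, second order, rate constant
#'   `k_couple`;
#' * `A -> D` — protodeboronation, first order, `k_proto` (this is the
#'   `k_obs` the rate model predicts at a given pH);
#' * `A + A -> A + D` — self-catalytic protodeboronation, second order,
#'   `k_selfcat` (net consumption of one A).
#'
#' Integrating this scheme translates a predicted protodeboronation rate
#' into its consequence for coupling yield.
#'
#' @name competition
NULL

#' Define a competing-reaction scheme
#'
#' @param k_couple Second-order rate constant for `A + B -> C`
#'   (1/(conc s)).
#' @param k_proto First-order protodeboronation rate constant (1/s).
#' @param k_selfcat Second-order self-catalytic rate constant
#'   (1/(conc s)).
#' @param a0,b0 Initial concentrations of A and B.
#' @param t_end Simulation end time in seconds (> 0).
#' @return A list with class `"competition_scheme"`.
#' @export
competition_scheme <- function(k_couple, k_proto, k_selfcat, a0, b0, t_end) {
  vals <- c(k_couple = k_couple, k_proto = k_proto, k_selfcat = k_selfcat,
            a0 = a0, b0 = b0)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("rate constants and initial concentrations must be finite and >= 0",
         call. = FALSE)
  }
  if (!is.finite(t_end) || t_end <= 0) {
    stop("t_end must be positive", call. = FALSE)
  }
  structure(list(k_couple = k_couple, k_proto = k_proto,
                 k_selfcat = k_selfcat, a0 = a0, b0 = b0, t_end = t_end),
            class = "competition_scheme")
}

#' Integrate the competing-reaction scheme
#'
#' Solves
#' `dA/dt = -k_couple A B - k_proto A - k_selfcat A^2`,
#' `dB/dt = -k_couple A B`, `dC/dt = k_couple A B`,
#' `dD/dt = k_proto A + k_selfcat A^2`
#' with a stiff-capable adaptive integrator (`deSolve::lsoda`, relative
#' tolerance 1e-8). Mass balances `A + C + D = a0` and `B + C = b0` hold
#' to integrator tolerance.
#'
#' @param scheme A `competition_scheme`.
#' @param n_steps Number of output intervals (trajectory has
#'   `n_steps + 1` rows).
#' @return A data frame with class `"trajectory"`: columns `time`, `A`,
#'   `B`, `C`, `D`; attributes `a0`, `b0`, `t_end`.
#' @export
simulate_competition <- function(scheme, n_steps = 200L) {
  stopifnot(inherits(scheme, "competition_scheme"), n_steps >= 1L)
  deriv <- function(t, y, p) {
    couple <- p$k_couple * y["A"] * y["B"]
    proto <- p$k_proto * y["A"]
    selfcat <- p$k_selfcat * y["A"]^2
    list(c(A = -couple - proto - selfcat,
           B = -couple,
           C = couple,
           D = proto + selfcat))
  }
  times <- seq(0, scheme$t_end, length.out = n_steps + 1L)
  sol <- deSolve::ode(y = c(A = scheme$a0, B = scheme$b0, C = 0, D = 0),
                      times = times, func = deriv, parms = scheme,
                      method = "lsoda", rtol = 1e-8, atol = 1e-12)
  out <- as.data.frame(sol)
  # lsoda can undershoot zero by amounts within tolerance; clip for the
  # non-negativity invariant without disturbing the mass balance materially
  for (col in c("A", "B", "C", "D")) out[[col]] <- pmax(out[[col]], 0)
  structure(out, class = c("trajectory", "data.frame"),
            a0 = scheme$a0, b0 = scheme$b0, t_end = scheme$t_end)
}

#' Coupling yield at the end of a trajectory
#'
#' Fraction of the limiting reagent converted to the coupled product:
#' `C(t_end) / min(a0, b0)`.
#'
#' @param trajectory A `trajectory` from [simulate_competition()].
#' @return Yield in `[0, 1]` (to integrator tolerance).
#' @export
yield_at <- function(trajectory) {
  stopifnot(inherits(trajectory, "trajectory"), nrow(trajectory) > 0L)
  limiting <- min(attr(trajectory, "a0"), attr(trajectory, "b0"))
  if (limiting <= 0) {
    stop("yield undefined: no limiting reagent present (a0 or b0 is 0)",
         call. = FALSE)
  }
  trajectory$C[nrow(trajectory)] / limiting
}

#' Write a trajectory to CSV
#' @param trajectory A `trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  utils::write.csv(as.data.frame(trajectory)[, c("time", "A", "B", "C", "D")],
                   path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
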