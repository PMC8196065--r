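#' Kinetic parameters for the tile assembly model
#'
#' Builds the rate-parameter set of the deterministic ODE model of
#' RNA-triggered DNA tile assembly. Units are nM and minutes throughout;
#' RNase H is kept in U/uL (its catalytic rate constant `k_deg` absorbs
#' the unit conversion, because enzyme activity is specified in units, not
#' molarity). The defaults are order-of-magnitude choices that reproduce
#' the qualitative regimes of the system (gene-titration speedup,
#' RNase-H-tunable assembly/disassembly pulse); they are *not* fitted to
#' any experimental dataset.
#'
#' @param k_tx Transcription rate constant (1/min per nM gene template):
#'   RNA trigger is produced at `k_tx * G * a` nM/min.
#' @param G Synthetic gene template concentration (nM).
#' @param delta First-order decay rate of RNA polymerase activity (1/min).
#' @param k_act Tile activation rate constant (1/nM/min): free trigger RNA
#'   hybridizes to an inactive tile, completing its sticky end.
#' @param n_nuc Critical nucleus size (tiles, integer >= 2). Cooperative
#'   nucleation of order `n_nuc` produces the concentration-dependent lag
#'   characteristic of nucleated polymerization.
#' @param k_nuc Nucleation rate constant (1/nM^(n_nuc-1)/min).
#' @param k_on Elongation rate constant (1/nM/min).
#' @param k_off Depolymerization rate constant (1/min per filament end);
#'   released tiles return to the active pool. The ratio `k_off / k_on` is
#'   the critical concentration below which filaments shrink rather than
#'   grow, which is what lets RNase H delay (and not merely attenuate)
#'   assembly.
#' @param k_deg RNase H deactivation rate constant (1/(U/uL)/min). RNase H
#'   hydrolyzes the RNA moiety of the DNA:RNA hybrid sticky end on *free*
#'   active tiles only; polymerized tiles are protected.
#' @param kappa RNase H interception strength for the activation
#'   intermediate (1/(U/uL)). The nascent tile:RNA hybrid formed while the
#'   trigger completes the sticky end is itself an RNase H substrate, so
#'   only a fraction `1/(1 + kappa*H)` of activation attempts succeed; the
#'   rest destroy the trigger and return the tile to the inactive pool.
#'   This is what delays the onset of assembly at high RNase H instead of
#'   merely attenuating it.
#' @param H RNase H concentration (U/uL).
#' @param w_frac Fraction of deactivation events that leave the tile
#'   sequestered in an inert waste complex (incomplete degradation
#'   products); the remainder return to the re-activatable inactive pool.
#' @param T_total Total tile concentration (nM).
#' @param peg_factor Optional multiplicative preset on `k_nuc` and `k_on`
#'   emulating PEG macromolecular crowding (1 = no crowding).
#' @return A `rate_params` list.
#' @seealso [simulate_assembly()], [assembly_derivatives()]
#' @export
rate_params <- function(k_tx = 0.05, G = 100, delta = 0.01,
                        k_act = 1e-3, n_nuc = 3L, k_nuc = 2e-7,
                        k_on = 2e-2, k_off = 0.2,
                        k_deg = 0.3, kappa = 10, H = 0, w_frac = 0.2,
                        T_total = 500, peg_factor = 1) {
  p <- list(k_tx = k_tx, G = G, delta = delta, k_act = k_act,
            n_nuc = as.integer(n_nuc), k_nuc = k_nuc * peg_factor,
            k_on = k_on * peg_factor, k_off = k_off,
            k_deg = k_deg, kappa = kappa, H = H, w_frac = w_frac,
            T_total = T_total)
  vals <- unlist(p)
  if (any(vals < 0)) stop("rate parameters must be non-negative")
  if (p$n_nuc < 2L) stop("n_nuc must be an integer >= 2")
  if (p$w_frac > 1) stop("w_frac must lie in [0, 1]")
  structure(p, class = "rate_params")
}

#' Initial state of the tile assembly model
#'
#' @param params A [rate_params()] object (supplies `T_total`).
#' @param active_fraction Fraction of the tile pool that starts in the
#'   active (polymerization-competent) state. 0 emulates inactive tiles
#'   awaiting transcription of the RNA trigger; 1 emulates pre-activated
#'   tiles (the two-tile isothermal preset, where activation plays no
#'   role).
#' @param R0 Initial free trigger RNA (nM), e.g. for pre-added trigger.
#' @param N0 Initial nucleus/filament number density (nM), normally 0.
#' @return Named numeric state vector with components `Ti` (inactive
#'   tile), `Ta` (active free tile), `P` (polymerized tile mass), `N`
#'   (filament number density), `R` (free trigger RNA), `W`
#'   (waste-sequestered tile), `a` (relative RNAP activity), all in nM
#'   except the dimensionless `a`.
#' @export
initial_state <- function(params, active_fraction = 0, R0 = 0, N0 = 0) {
  stopifnot(inherits(params, "rate_params"),
            active_fraction >= 0, active_fraction <= 1, R0 >= 0, N0 >= 0)
  c(Ti = params$T_total * (1 - active_fraction),
    Ta = params$T_total * active_fraction,
    P = 0, N = N0, R = R0, W = 0, a = 1)
}

#' Time derivatives of the tile assembly model
#'
#' The model couples four processes:
#' \itemize{
#'   \item Transcription: trigger RNA is produced at `k_tx * G * a`, with
#'     RNAP activity `a` decaying as `da/dt = -delta * a`.
#'   \item Activation: free RNA hybridizes to inactive tiles at the
#'     attempt rate `k_act * Ti * R`, consuming one RNA per attempt. A
#'     fraction `1/(1 + kappa*H)` of attempts completes the sticky end;
#'     the rest are intercepted by RNase H (the nascent hybrid is a
#'     substrate), destroying the trigger and leaving the tile inactive.
#'   \item Nucleation-elongation: active tiles nucleate cooperatively
#'     (`k_nuc * Ta^n_nuc`, creating nuclei of `n_nuc` tiles) and add to
#'     existing filaments at `k_on * Ta * N`; filament ends release tiles
#'     at `k_off * N * P/(P + 0.1)` back into the active pool (the
#'     saturating factor only shuts the flux off as the polymer pool
#'     empties).
#'   \item Degradation: RNase H deactivates *free* active tiles at
#'     `k_deg * H * Ta`; a fraction `w_frac` is lost to waste complexes,
#'     the rest returns to the inactive pool. Polymerized tiles and free
#'     RNA are untouched.
#' }
#' The tile pool `Ti + Ta + P + W` is conserved exactly; RNA is not (it is
#' consumed by activation).
#'
#' @param t Time (min); the system is autonomous, `t` is unused.
#' @param state Named state vector as from [initial_state()].
#' @param params A [rate_params()] object.
#' @return A list of derivatives in [deSolve::ode()] convention.
#' @export
assembly_derivatives <- function(t, state, params) {
  if (any(state < -1e-6)) {
    stop("negative state component: ",
         paste(names(state)[state < -1e-6], collapse = ", "))
  }
  s <- pmax(state, 0)
  Ti <- s[["Ti"]]; Ta <- s[["Ta"]]; P <- s[["P"]]; N <- s[["N"]]
  R <- s[["R"]]; W <- s[["W"]]; a <- s[["a"]]
  p <- params
  att <- p$k_act * Ti * R            # attempted activations (consume R)
  act <- att / (1 + p$kappa * p$H)   # attempts surviving interception
  # nucleation is driven by the supersaturation above the critical
  # concentration c* = k_off/k_on: subcritical nuclei dissolve, so no new
  # filaments form while Ta < c*. This is what gives RNase H (which pins
  # Ta down) the power to delay, and not merely attenuate, assembly.
  cstar <- if (p$k_on > 0) p$k_off / p$k_on else 0
  nuc <- p$k_nuc * max(Ta - cstar, 0)^p$n_nuc
  elo <- p$k_on * Ta * N             # elongation flux (nM/min)
  # depolymerization; the saturating factor shuts the flux off smoothly as
  # the polymer pool empties, so P cannot be driven negative
  dep <- p$k_off * N * P / (P + 0.1)
  deg <- p$k_deg * p$H * Ta          # deactivation flux (nM/min)
  list(c(
    Ti = -act + (1 - p$w_frac) * deg,
    Ta = act - deg - p$n_nuc * nuc - elo + dep,
    P  = p$n_nuc * nuc + elo - dep,
    N  = nuc,
    R  = p$k_tx * p$G * a - att,
    W  = p$w_frac * deg,
    a  = -p$delta * a
  ))
}

#' Simulate the tile assembly model
#'
#' Integrates the ODE system with a stiff-capable adaptive solver
#' ([deSolve::ode()], `lsoda`). Small negative excursions (below
#' `-10 * atol`) are clipped to zero with a warning; the assembled
#' fraction `f = P / T_total` is attached to the trajectory.
#'
#' @param params A [rate_params()] object.
#' @param init Initial state from [initial_state()]; defaults to all-inactive
#'   tiles.
#' @param t_end End time (min, > 0).
#' @param n_points Number of output grid points (including t = 0).
#' @param rtol,atol Relative and absolute integration tolerances.
#' @return An object of class `assembly_sim`: a data.frame with columns
#'   `time`, `Ti`, `Ta`, `P`, `N`, `R`, `W`, `a`, `f`, and the parameters
#'   as attribute `"params"`.
#' @examples
#' p <- rate_params(G = 100, H = 0)
#' sim <- simulate_assembly(p, t_end = 600)
#' max(sim$f)
#' @export
simulate_assembly <- function(params, init = initial_state(params),
                              t_end, n_points = 401,
                              rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "rate_params"), t_end > 0, n_points >= 2)
  times <- seq(0, t_end, length.out = n_points)
  out <- deSolve::ode(y = init, times = times, func = assembly_derivatives,
                      parms = params, method = "lsoda",
                      rtol = rtol, atol = atol)
  istate <- attr(out, "istate")[1L]
  if (is.null(istate) || istate < 0 || nrow(out) < n_points) {
    stop("ODE integration failed (istate = ", istate, ") with parameters: ",
         paste(names(params), unlist(params), sep = "=", collapse = ", "))
  }
  df <- as.data.frame(out)
  names(df)[1L] <- "time"
  species <- c("Ti", "Ta", "P", "N", "R", "W", "a")
  neg <- vapply(df[species], function(x) any(x < -10 * atol), logical(1))
  if (any(neg)) {
    warning("clipping negative excursions in: ",
            paste(species[neg], collapse = ", "))
  }
  df[species] <- lapply(df[species], pmax, 0)
  df$f <- df$P / params$T_total
  structure(df, params = params, class = c("assembly_sim", "data.frame"))
}

#' Pulse metrics of an assembled-fraction trajectory
#'
#' Quantifies the transient assembly/disassembly pulse produced when
#' transcription (under decaying RNAP activity) competes with RNase H
#' degradation: peak height and time of the assembled fraction, the time
#' spent above a threshold, and the time at which the rise first crosses
#' half the peak. Crossings are located by linear interpolation on the
#' output grid. If the trajectory never falls below the threshold after
#' rising, `duration_above` runs to the end of the window and
#' `right_censored` is set.
#'
#' @param result An `assembly_sim` from [simulate_assembly()], or any
#'   data.frame with `time` and `f` columns.
#' @param threshold Assembled-fraction threshold for `duration_above`
#'   (default 0.1).
#' @return A list of class `pulse_metrics`: `peak_height`, `t_peak`,
#'   `duration_above`, `t_half_rise`, `right_censored`.
#' @export
pulse_metrics <- function(result, threshold = 0.1) {
  stopifnot(is.data.frame(result), all(c("time", "f") %in% names(result)),
            threshold >= 0)
  t <- result$time; f <- result$f
  i_pk <- which.max(f)
  peak <- f[i_pk]
  crossings <- function(level) {
    # all interpolated times where f crosses `level`
    below <- f < level
    idx <- which(below[-length(below)] != below[-1L])
    vapply(idx, function(i) {
      t[i] + (level - f[i]) * (t[i + 1L] - t[i]) / (f[i + 1L] - f[i])
    }, numeric(1))
  }
  if (peak <= threshold) {
    dur <- 0; censored <- FALSE
  } else {
    up <- crossings(threshold)
    t_up <- if (f[1L] >= threshold) t[1L] else min(up)
    after <- up[up > t[i_pk]]
    if (length(after) == 0L) {
      dur <- t[length(t)] - t_up; censored <- TRUE
    } else {
      dur <- min(after) - t_up; censored <- FALSE
    }
  }
  half <- crossings(peak / 2)
  t_half <- if (length(half) == 0L) NA_real_ else min(half)
  structure(list(peak_height = peak, t_peak = t[i_pk],
                 duration_above = dur, t_half_rise = t_half,
                 right_censored = censored, threshold = threshold),
            class = "pulse_metrics")
}

#' @export
print.pulse_metrics <- function(x, ...) {
  cat(sprintf(paste0("pulse: peak f = %.3f at t = %.1f min; ",
                     "%.1f min above f = %.2f%s; half-rise at %.1f min\n"),
              x$peak_height, x$t_peak, x$duration_above, x$threshold,
              if (x$right_censored) " (right-censored)" else "",
              x$t_half_rise))
  invisible(x)
}

#' Sweep one model parameter across a set of values
#'
#' Re-simulates the model for each value of a named parameter, keeping the
#' initial condition fixed (it is rebuilt from each parameter set when it
#' depends on `T_total`). Used to emulate titration series such as the
#' gene-template or RNase H titrations.
#'
#' @param base A [rate_params()] object.
#' @param name Name of the parameter to vary (e.g. `"G"`, `"H"`,
#'   `"T_total"`).
#' @param values Non-empty numeric vector of parameter values.
#' @param t_end,n_points,threshold Passed to [simulate_assembly()] and
#'   [pulse_metrics()].
#' @param active_fraction,R0,N0 Passed to [initial_state()].
#' @return A list with one element per value: `list(value, sim, metrics)`.
#'   Use [sweep_summary()] for a tidy table.
#' @export
sweep_parameter <- function(base, name, values, t_end, n_points = 401,
                            threshold = 0.1, active_fraction = 0,
                            R0 = 0, N0 = 0) {
  stopifnot(inherits(base, "rate_params"))
  if (!name %in% names(base)) {
    stop("unknown parameter '", name, "'; valid names: ",
         paste(names(base), collapse = ", "))
  }
  if (length(values) == 0L) stop("values must be non-empty")
  lapply(values, function(v) {
    p <- base
    p[[name]] <- if (name == "n_nuc") as.integer(v) else v
    sim <- simulate_assembly(
      p, initial_state(p, active_fraction = active_fraction, R0 = R0, N0 = N0),
      t_end = t_end, n_points = n_points)
    list(value = v, sim = sim, metrics = pulse_metrics(sim, threshold))
  })
}

#' Tidy summary table of a parameter sweep
#'
#' @param sweep Result of [sweep_parameter()].
#' @param name Label for the swept parameter column.
#' @return data.frame with one row per swept value: the parameter value,
#'   final assembled fraction, and pulse metrics.
#' @export
sweep_summary <- function(sweep, name = "value") {
  rows <- lapply(sweep, function(s) {
    data.frame(value = s$value,
               final_f = s$sim$f[nrow(s$sim)],
               peak_height = s$metrics$peak_height,
               t_peak = s$metrics$t_peak,
               duration_above = s$metrics$duration_above,
               t_half_rise = s$metrics$t_half_rise,
               right_censored = s$metrics$right_censored)
  })
  out <- do.call(rbind, rows)
  names(out)[1L] <- name
  out
}
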