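#' Fast sodium channel parameters
#'
#' The fast sodium current of the neonatal rat ventricular myocyte model is
#' \deqn{I_{Na} = G_{Na}\, m^3 h j \,(V - E_{Na})}
#' with activation gate \eqn{m}, fast inactivation \eqn{h} and slow
#' inactivation \eqn{j}. Steady states are sigmoids
#' \deqn{m_\infty = \{1 + \exp[(p_1 + V)/p_2]\}^{-1}, \qquad
#'       j_\infty = h_\infty = \{1 + \exp[(q_1 + V)/q_2]\}^{-1}}
#' and the activation time constant has the Luo-Rudy-type form
#' \deqn{\tau_m = \left\{ \frac{p_3 (V+p_4)}{1 - e^{p_5 (V+p_4)}}
#'       + p_6 e^{-V/p_7} \right\}^{-1}.}
#' The inactivation time constants are kept fixed (they are not constrained
#' by steady-state protocols) as are conductance and reversal potential.
#'
#' @param p1,p2,p3,p4,p5,p6,p7 Activation kinetics parameters; `p1` (mV) and
#'   `p2` (mV, negative) set the activation midpoint and slope.
#' @param q1,q2 Inactivation midpoint (mV) and slope (mV, positive).
#' @param g_na Maximal conductance (normalised, fixed at 1: every protocol
#'   summary is normalised so the conductance cancels).
#' @param e_na Reversal potential in mV (fixed).
#' @param tau_h,tau_j Fixed inactivation time constants in ms, either
#'   constants or functions of voltage.
#' @return An object of class `epk_channel_params`.
#' @export
channel_params <- function(p1 = 45, p2 = -6.5, p3 = 0.235, p4 = 47.1,
                           p5 = -0.1, p6 = 0.0588, p7 = 11.0,
                           q1 = 76.1, q2 = 6.07,
                           g_na = 1, e_na = 65, tau_h = 5, tau_j = 50) {
  ps <- list(p1 = p1, p2 = p2, p3 = p3, p4 = p4, p5 = p5, p6 = p6, p7 = p7,
             q1 = q1, q2 = q2, g_na = g_na, e_na = e_na,
             tau_h = tau_h, tau_j = tau_j)
  for (nm in setdiff(names(ps), c("tau_h", "tau_j"))) {
    check_scalar(ps[[nm]], nm)
  }
  structure(ps, class = "epk_channel_params")
}

#' Original published parameter values and inference priors
#'
#' Returns the table of the nine inferable gate-kinetics parameters: the
#' original model values and the uniform prior bounds (roughly an order of
#' magnitude wider than each original value) used for Bayesian calibration.
#'
#' @return Data frame with columns `name`, `orig`, `prior_lo`, `prior_hi`.
#' @export
channel_prior_table <- function() {
  data.frame(
    name = c("p1", "p2", "p3", "p4", "p5", "p6", "p7", "q1", "q2"),
    orig = c(45, -6.5, 0.235, 47.1, -0.1, 0.0588, 11.0, 76.1, 6.07),
    prior_lo = c(0, -50, 0, 0, -50, 0, 0, 0, 0),
    prior_hi = c(100, 0, 1, 100, 0, 1, 1000, 100, 50),
    stringsAsFactors = FALSE
  )
}

# numerically safe logistic of (a + v)/b
gate_sigmoid <- function(v, a, b) {
  x <- (a + v) / b
  ifelse(x > 500, 0, ifelse(x < -500, 1, 1 / (1 + exp(x))))
}

#' Steady-state activation \eqn{m_\infty(V)}
#' @param v Membrane potential, mV (vectorised).
#' @param params An `epk_channel_params`.
#' @return Occupancy in (0, 1).
#' @export
m_inf <- function(v, params) gate_sigmoid(v, params$p1, params$p2)

#' Steady-state inactivation \eqn{h_\infty(V) = j_\infty(V)}
#' @inheritParams m_inf
#' @return Occupancy in (0, 1).
#' @export
h_inf <- function(v, params) gate_sigmoid(v, params$q1, params$q2)

#' Activation time constant \eqn{\tau_m(V)} in ms
#'
#' The rate term \eqn{p_3(V+p_4)/[1-e^{p_5(V+p_4)}]} has a removable
#' singularity at \eqn{V = -p_4}, where it tends to \eqn{-p_3/p_5}; it is
#' evaluated through `expm1` for numerical stability.
#'
#' @inheritParams m_inf
#' @return Positive time constant, ms.
#' @export
tau_m <- function(v, params) {
  u <- params$p5 * (v + params$p4)
  alpha <- ifelse(abs(u) < 1e-12,
                  -params$p3 / params$p5,
                  -params$p3 * (v + params$p4) / expm1(u))
  beta <- params$p6 * exp(-v / params$p7)
  1 / (alpha + beta)
}

tau_h_of <- function(v, params) {
  if (is.function(params$tau_h)) params$tau_h(v) else params$tau_h
}
tau_j_of <- function(v, params) {
  if (is.function(params$tau_j)) params$tau_j(v) else params$tau_j
}

#' Sodium current for a gate state
#'
#' @param state List or `epk_gate_state` with elements `m`, `h`, `j`, `v`.
#' @param params An `epk_channel_params`.
#' @return \eqn{I_{Na} = G_{Na} m^3 h j (V - E_{Na})} (normalised units).
#' @export
i_na <- function(state, params) {
  params$g_na * state$m^3 * state$h * state$j * (state$v - params$e_na)
}

#' Gate state at the steady state of a holding potential
#' @param v_hold Holding potential, mV.
#' @param params An `epk_channel_params`.
#' @return An `epk_gate_state` list with `m`, `h`, `j`, `v`, `t`.
#' @export
gate_steady_state <- function(v_hold, params) {
  structure(list(m = m_inf(v_hold, params), h = h_inf(v_hold, params),
                 j = h_inf(v_hold, params), v = v_hold, t = 0),
            class = "epk_gate_state")
}

#' Advance the gates at a fixed clamp voltage
#'
#' Exact exponential relaxation \eqn{g(t+dt) = g_\infty + (g - g_\infty)
#' e^{-dt/\tau_g}} for each gate, a convex combination that keeps occupancies
#' in \eqn{[0,1]} for any `dt`.
#'
#' @param state An `epk_gate_state`.
#' @param v_clamp Clamp voltage, mV.
#' @param dt Time increment, ms (>= 0).
#' @param params An `epk_channel_params`.
#' @return Updated `epk_gate_state` at voltage `v_clamp`.
#' @export
gate_step <- function(state, v_clamp, dt, params) {
  stopifnot(dt >= 0)
  minf <- m_inf(v_clamp, params)
  hinf <- h_inf(v_clamp, params)
  structure(list(
    m = minf + (state$m - minf) * exp(-dt / tau_m(v_clamp, params)),
    h = hinf + (state$h - hinf) * exp(-dt / tau_h_of(v_clamp, params)),
    j = hinf + (state$j - hinf) * exp(-dt / tau_j_of(v_clamp, params)),
    v = v_clamp, t = state$t + dt), class = "epk_gate_state")
}

# peak (largest-magnitude, signed) current during a fixed-voltage step,
# sampled at `res` ms from the closed-form gate trajectories
step_peak_current <- function(state, v, dur, params, res = 0.01,
                              tau_m_scale = 1) {
  tt <- seq(0, dur, by = res)
  tm <- tau_m(v, params) * tau_m_scale
  minf <- m_inf(v, params)
  hinf <- h_inf(v, params)
  m <- minf + (state$m - minf) * exp(-tt / tm)
  h <- hinf + (state$h - hinf) * exp(-tt / tau_h_of(v, params))
  j <- hinf + (state$j - hinf) * exp(-tt / tau_j_of(v, params))
  cur <- params$g_na * m^3 * h * j * (v - params$e_na)
  cur[which.max(abs(cur))]
}

#' Default patch-clamp protocol configuration
#'
#' @param v_hold Holding potential, mV.
#' @param act_v Test voltages of the activation protocols, mV.
#' @param act_dur Activation step duration, ms.
#' @param inact_v Prepulse voltages of the inactivation protocol, mV.
#' @param inact_prepulse,inact_test_v,inact_test_dur Prepulse duration (ms),
#'   test voltage (mV) and test duration (ms) of the inactivation protocol.
#' @param train_n,train_v,train_dur,train_gap Pulse-train protocol: number of
#'   pulses, pulse voltage (mV), pulse duration and inter-pulse gap (ms).
#' @param rec_intervals Recovery inter-pulse intervals, ms.
#' @param res Sampling resolution for peak detection, ms.
#' @param tau_m_scale Multiplier on the activation time constant (1 for the
#'   physical model; near 0 approaches instantaneous activation).
#' @return A list of protocol settings.
#' @export
protocol_config <- function(v_hold = -80, act_v = seq(-60, 30, by = 5),
                            act_dur = 20, inact_v = seq(-120, -20, by = 5),
                            inact_prepulse = 500, inact_test_v = -20,
                            inact_test_dur = 20, train_n = 20L,
                            train_v = -20, train_dur = 20, train_gap = 50,
                            rec_intervals = exp(seq(log(1), log(500),
                                                    length.out = 12)),
                            res = 0.01, tau_m_scale = 1) {
  list(v_hold = v_hold, act_v = act_v, act_dur = act_dur, inact_v = inact_v,
       inact_prepulse = inact_prepulse, inact_test_v = inact_test_v,
       inact_test_dur = inact_test_dur, train_n = as.integer(train_n),
       train_v = train_v, train_dur = train_dur, train_gap = train_gap,
       rec_intervals = rec_intervals, res = res, tau_m_scale = tau_m_scale)
}

#' Simulate one patch-clamp protocol and return its normalised summary curve
#'
#' Protocols:
#' \describe{
#'   \item{activation_iv}{peak current per test voltage from the holding
#'     potential, normalised by the largest magnitude.}
#'   \item{activation_gv}{peak conductance \eqn{I_{peak}/(V - E_{Na})} per
#'     test voltage, normalised.}
#'   \item{inactivation}{channel availability: normalised peak test-pulse
#'     current after a long conditioning prepulse at each voltage.}
#'   \item{pulse_train}{normalised peak current of each pulse in a regular
#'     train (use-dependent reduction).}
#'   \item{recovery}{fraction of the first-pulse peak recovered after an
#'     inter-pulse interval at the holding potential.}
#' }
#' Every curve is normalised so that \eqn{\max |y| = 1}.
#'
#' @param protocol_id One of `"activation_iv"`, `"activation_gv"`,
#'   `"inactivation"`, `"pulse_train"`, `"recovery"`.
#' @param params An `epk_channel_params`.
#' @param config A [protocol_config()] list.
#' @return Data frame with columns `protocol`, `x`, `y`.
#' @export
run_protocol <- function(protocol_id, params, config = protocol_config()) {
  cfg <- config
  hold <- gate_steady_state(cfg$v_hold, params)
  out <- switch(
    protocol_id,
    activation_iv = {
      peaks <- vapply(cfg$act_v, function(v) {
        step_peak_current(hold, v, cfg$act_dur, params, cfg$res,
                          cfg$tau_m_scale)
      }, 0)
      list(x = cfg$act_v, y = peaks)
    },
    activation_gv = {
      peaks <- vapply(cfg$act_v, function(v) {
        step_peak_current(hold, v, cfg$act_dur, params, cfg$res,
                          cfg$tau_m_scale) / (v - params$e_na)
      }, 0)
      list(x = cfg$act_v, y = peaks)
    },
    inactivation = {
      peaks <- vapply(cfg$inact_v, function(vp) {
        st <- gate_step(hold, vp, cfg$inact_prepulse, params)
        step_peak_current(st, cfg$inact_test_v, cfg$inact_test_dur, params,
                          cfg$res, cfg$tau_m_scale)
      }, 0)
      list(x = cfg$inact_v, y = peaks)
    },
    pulse_train = {
      st <- hold
      peaks <- numeric(cfg$train_n)
      for (i in seq_len(cfg$train_n)) {
        peaks[i] <- step_peak_current(st, cfg$train_v, cfg$train_dur, params,
                                      cfg$res, cfg$tau_m_scale)
        st <- gate_step(st, cfg$train_v, cfg$train_dur, params)
        st <- gate_step(st, cfg$v_hold, cfg$train_gap, params)
      }
      list(x = seq_len(cfg$train_n), y = peaks)
    },
    recovery = {
      p1 <- step_peak_current(hold, cfg$train_v, cfg$train_dur, params,
                              cfg$res, cfg$tau_m_scale)
      after <- gate_step(hold, cfg$train_v, cfg$train_dur, params)
      fr <- vapply(cfg$rec_intervals, function(gap) {
        st <- gate_step(after, cfg$v_hold, gap, params)
        step_peak_current(st, cfg$train_v, cfg$train_dur, params, cfg$res,
                          cfg$tau_m_scale) / p1
      }, 0)
      list(x = cfg$rec_intervals, y = fr)
    },
    stop(sprintf("unknown protocol '%s'", protocol_id), call. = FALSE)
  )
  data.frame(protocol = protocol_id, x = out$x, y = out$y / max(abs(out$y)),
             stringsAsFactors = FALSE)
}

#' Analytic steady-state activation and availability curves
#'
#' Returns \eqn{m_\infty} and \eqn{h_\infty} evaluated on a voltage grid --
#' the deterministic summaries used as observations in fast calibration runs.
#'
#' @param params An `epk_channel_params`.
#' @param v_grid Strictly increasing voltages, mV.
#' @return Named list of two curve data frames (`activation`,
#'   `inactivation`), each with columns `protocol`, `x`, `y`.
#' @export
steady_state_curves <- function(params, v_grid = seq(-100, 10, by = 2.5)) {
  if (any(diff(v_grid) <= 0)) stop("v_grid must be strictly increasing",
                                   call. = FALSE)
  list(activation = data.frame(protocol = "ss_activation", x = v_grid,
                               y = m_inf(v_grid, params),
                               stringsAsFactors = FALSE),
       inactivation = data.frame(protocol = "ss_inactivation", x = v_grid,
                                 y = h_inf(v_grid, params),
                                 stringsAsFactors = FALSE))
}

#' @export
print.epk_channel_params <- function(x, ...) {
  cat("<epk_channel_params>\n")
  cat(sprintf("  activation: midpoint %.1f mV, slope %.2f mV, tau_m(0) %.3g ms\n",
              -x$p1, x$p2, tau_m(0, x)))
  cat(sprintf("  inactivation: midpoint %.1f mV, slope %.2f mV (tau_h %s, tau_j %s ms)\n",
              -x$q1, x$q2,
              if (is.function(x$tau_h)) "fn" else format(x$tau_h),
              if (is.function(x$tau_j)) "fn" else format(x$tau_j)))
  invisible(x)
}
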