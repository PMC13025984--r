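# Synthetic test beds.  The thermostat is the canonical regulation example:
# a slow thermal plant driven by varying outdoor weather, a bang-bang
# controller with hysteresis, and a quantised error readout.  All fixtures
# are generated from seeds; nothing is downloaded or stored.

#' Thermostat study parameters
#'
#' Discrete-time room model
#' `T[t+1] = T[t] + retention * (T_out[t] - T[t]) + u[t] * heater_power`,
#' with `u` from bang-bang-with-hysteresis control (ON mode), identically 0
#' (OFF mode) or a world-independent random emitter (control condition).
#' Outdoor temperature is a slow sinusoid plus AR(1) weather noise.  The
#' readout is the error `T - setpoint` quantised at fixed sensor
#' resolution.
#'
#' Defaults describe a well-insulated room on a fine time grid: thermal
#' retention 0.001 per step (time constant of ~1000 steps), a heater able
#' to lift the room about 6 degrees above outdoor equilibrium, outdoor mean
#' 3 degrees below the setpoint with unit-scale seasonal and AR(1)
#' variation, and a +-0.3 degree hysteresis band.  The controller holds the
#' band just above the sensor reporting threshold (`comfort_offset` 0.5, a
#' half sensor cell), so a functioning thermostat reports an almost
#' constant error symbol while the free-running room wanders across sensor
#' cells.
#'
#' @param retention fractional heat loss toward outdoor per step, in (0,1).
#' @param heater_power temperature gain per step at full heat.
#' @param setpoint target temperature defining the error readout.
#' @param comfort_offset controller target above the setpoint.
#' @param deadband hysteresis half-width (> 0).
#' @param outdoor_mean,outdoor_amplitude,outdoor_period sinusoidal outdoor
#'   component.
#' @param outdoor_ar,outdoor_sd AR(1) coefficient and innovation sd of the
#'   weather noise.
#' @param horizon episode length N.
#' @param initial_temperature room temperature at t = 1 (default: the
#'   controller target).
#' @param quantization readout [quantization_spec()] (8 cells over
#'   `[-4, 4]` degrees).
#' @return a `thermostat_params` list.
#' @export
thermostat_params <- function(retention = 0.001, heater_power = 0.006,
                              setpoint = 21, comfort_offset = 0.5,
                              deadband = 0.3, outdoor_mean = 18,
                              outdoor_amplitude = 1.0, outdoor_period = 400,
                              outdoor_ar = 0.9, outdoor_sd = 0.3,
                              horizon = 2000L,
                              initial_temperature = setpoint + comfort_offset,
                              quantization = quantization_spec(8L, -4, 4)) {
  chk <- function(ok, field, msg) if (!ok) stop("invalid ", field, ": ", msg)
  chk(retention > 0 && retention < 1, "retention", "must lie in (0, 1)")
  chk(deadband > 0, "deadband", "must be positive")
  chk(horizon >= 1, "horizon", "must be at least 1")
  chk(heater_power > 0, "heater_power", "must be positive")
  chk(outdoor_period > 0, "outdoor_period", "must be positive")
  structure(list(retention = retention, heater_power = heater_power,
                 setpoint = setpoint, comfort_offset = comfort_offset,
                 deadband = deadband, outdoor_mean = outdoor_mean,
                 outdoor_amplitude = outdoor_amplitude,
                 outdoor_period = outdoor_period, outdoor_ar = outdoor_ar,
                 outdoor_sd = outdoor_sd, horizon = as.integer(horizon),
                 initial_temperature = initial_temperature,
                 quantization = quantization),
            class = "thermostat_params")
}

#' Simulate one thermostat episode
#'
#' The weather trajectory depends only on `seed`, so ON, OFF and
#' random-control runs with the same seed face the same disturbances -- the
#' paired design used by the gap diagnostic.
#'
#' @param params a [thermostat_params()].
#' @param mode `"on"` (bang-bang control), `"off"` (heater off: the null
#'   baseline) or `"random"` (world-independent fair-coin emitter).
#' @param seed episode seed.
#' @return list with `temperature`, `outdoor`, the quantised `readout`,
#'   `heater` (the actuation sequence), `mode`.
#' @export
thermostat_episode <- function(params = thermostat_params(),
                               mode = c("on", "off", "random"), seed = 1L) {
  mode <- match.arg(mode)
  p <- params
  n <- p$horizon
  set.seed(seed)
  innov <- stats::rnorm(n, 0, p$outdoor_sd)
  e <- stats::filter(innov, p$outdoor_ar, method = "recursive")
  outdoor <- p$outdoor_mean +
    p$outdoor_amplitude * sin(2 * pi * seq_len(n) / p$outdoor_period) +
    as.numeric(e)
  if (mode == "random") {
    set.seed(seed + 777777L)               # controller stream, weather-independent
    u_rand <- stats::rbinom(n, 1L, 0.5)
  }
  target <- p$setpoint + p$comfort_offset
  temp <- numeric(n)
  heater <- integer(n)
  temp[1L] <- p$initial_temperature
  u <- 0L
  for (t in seq_len(n)) {
    if (t > 1L)
      temp[t] <- temp[t - 1L] +
        p$retention * (outdoor[t - 1L] - temp[t - 1L]) +
        heater[t - 1L] * p$heater_power
    u <- switch(mode,
                on = if (temp[t] < target - p$deadband) 1L
                     else if (temp[t] > target + p$deadband) 0L
                     else u,
                off = 0L,
                random = u_rand[t])
    heater[t] <- u
  }
  list(temperature = temp, outdoor = outdoor,
       readout = quantize(temp - p$setpoint, p$quantization),
       heater = heater, mode = mode)
}

#' Paired thermostat gap study
#'
#' Runs `n_episodes` paired episodes (shared weather per episode), scores
#' the contrast `delta = L(off readout) - L(mode readout)` with one
#' estimator, and attaches the sign-flip permutation p-value.
#'
#' @param n_episodes number of paired episodes.
#' @param params a [thermostat_params()].
#' @param mode the regulated condition contrasted against OFF: `"on"` or
#'   `"random"`.
#' @param estimator shared codelength estimator (default LZ76 over the
#'   sensor alphabet).
#' @param seed study seed; episode e uses `seed + e`.
#' @param n_permutations permutation count for the p-value.
#' @return a `gap_result` with `episode_deltas` and `p_value`.
#' @export
thermostat_gap_study <- function(n_episodes = 20L,
                                 params = thermostat_params(),
                                 mode = c("on", "random"),
                                 estimator = est_lz76(params$quantization$levels),
                                 seed = 1L, n_permutations = 999L) {
  mode <- match.arg(mode)
  deltas <- vapply(seq_len(n_episodes), function(e) {
    on <- thermostat_episode(params, mode, seed = seed + e)
    off <- thermostat_episode(params, "off", seed = seed + e)
    delta_gap(on$readout, off$readout, estimator)$delta_bits
  }, numeric(1L))
  pt <- paired_permutation_test(deltas, n_permutations, seed = seed)
  structure(list(a_bits = NA_real_, b_bits = NA_real_,
                 delta_bits = mean(deltas), episode_deltas = deltas,
                 estimator_id = estimator$id, params = estimator,
                 n_episodes = n_episodes, p_value = pt$p_value,
                 n_permutations = pt$n_permutations, seed = seed),
            class = "gap_result")
}

#' Header slack of the LZ76 estimator
#'
#' The self-delimiting header cost shared by every LZ76 codelength at a
#' given length and alphabet; the natural "zero" scale for gap estimates
#' (a gap within the header slack is indistinguishable from no gap).
#'
#' @param n sequence length.
#' @param alphabet alphabet size.
#' @return bits.
#' @export
lz76_header_slack <- function(n, alphabet) lz_header_bits(n, alphabet)

#' Reference symbol strings
#'
#' Reproducible fixture sequences for estimator validation: i.i.d.
#' Bernoulli, periodic repetitions of a motif, and constants.
#'
#' @param kind `"bernoulli"`, `"periodic"` or `"constant"`.
#' @param n length.
#' @param p success probability (`bernoulli`).
#' @param motif symbol vector or digit string (`periodic`).
#' @param symbol constant symbol (`constant`).
#' @param seed RNG seed (`bernoulli`).
#' @return integer symbol vector.
#' @export
make_string <- function(kind = c("bernoulli", "periodic", "constant"),
                        n, p = 0.5, motif = c(0L, 1L), symbol = 0L,
                        seed = NULL) {
  kind <- tryCatch(match.arg(kind), error = function(e)
    stop("unknown string kind; use bernoulli, periodic or constant"))
  n <- as.integer(n)
  switch(kind,
         bernoulli = {
           if (!is.null(seed)) set.seed(seed)
           stats::rbinom(n, 1L, p)
         },
         periodic = rep(as_symbols(motif), length.out = n),
         constant = rep(as.integer(symbol), n))
}

#' Quantised thermostat world and bang-bang controller as transducers
#'
#' A finite-state rendition of the thermostat loop for the coupled-episode
#' machinery: the world state is a temperature level in `0..levels-1` that
#' drifts one level down per step (heat loss) and one level up under heat
#' (net), emitting its level; the controller is a two-state (heating/idle)
#' hysteresis switch over the level alphabet.  Coupled with
#' [run_episode()], the pair settles into a limit cycle of period at least
#' 2 ramping between the two thresholds.
#'
#' @param levels number of temperature levels.
#' @param initial_level world start level.
#' @return a `transducer`.
#' @export
thermostat_world_spec <- function(levels = 16L, initial_level = 4L) {
  levels <- as.integer(levels)
  lvl <- function(x) pmin(pmax(x, 0L), levels - 1L)
  trans <- cbind(lvl(0:(levels - 1L) - 1L),   # u = 0: cool one level
                 lvl(0:(levels - 1L) + 1L))   # u = 1: heat one level
  transducer(levels, 2L, levels, transition = trans, emission = trans,
             initial_state = initial_level, initial_emission = initial_level)
}

#' @rdname thermostat_world_spec
#' @param low,high hysteresis thresholds (heat below `low`, coast above
#'   `high`).
#' @export
bang_bang_spec <- function(levels = 16L, low = 6L, high = 10L) {
  levels <- as.integer(levels)
  stopifnot(low < high, high < levels)
  lv <- 0:(levels - 1L)
  # state 0 = heating, state 1 = idle; input = observed level
  trans <- rbind(ifelse(lv < high, 0L, 1L),
                 ifelse(lv <= low, 0L, 1L))
  emis <- rbind(ifelse(lv < high, 1L, 0L),
                ifelse(lv <= low, 1L, 0L))
  transducer(2L, levels, 2L, transition = trans, emission = emis,
             initial_state = 0L, initial_emission = 1L)
}

#' Eventual period of a sequence's tail
#'
#' Smallest p such that the last `window` symbols are p-periodic; a cheap
#' cycle detector for eventually periodic readouts.
#'
#' @param s symbol sequence.
#' @param max_period largest period tried.
#' @param window tail length examined (default: half the sequence).
#' @return the period, or `NA` if none at most `max_period` fits.
#' @export
tail_period <- function(s, max_period = 64L, window = length(s) %/% 2L) {
  s <- as_symbols(s)
  tail_s <- s[(length(s) - window + 1L):length(s)]
  for (p in seq_len(min(max_period, window - 1L))) {
    if (all(tail_s[seq_len(window - p)] == tail_s[seq_len(window - p) + p]))
      return(p)
  }
  NA_integer_
}
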