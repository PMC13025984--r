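# Exact verification of the posterior-tilt results inside an enumerated
# universe of world-regulator pairs.  Every pair of binary-interface
# transducers whose joint canonical code fits the length bound is run both
# coupled (ON) and against the null regulator (OFF); the prefix prior over
# joint codes then yields exact posteriors, from which the posterior
# identity, the contrastive tilt bound, the geometric tails and the
# Bayes-factor identity are all measured with exact mass arithmetic.
#
# Joint codebook (prefix-free): a pair program is
#
#     1^j 0  |  flag  |  code(W) [ code(R) ]
#
# where "1^j 0" is the same no-op prologue as in the string universe, and
# flag = 1 means the regulator is a copy of the world (only W's code
# follows) while flag = 0 is followed by both canonical codes.  The copy
# flag is the crudest shared-structure facility of the code: identical
# pairs are describable in about half the bits, giving them positive
# in-universe mutual information |W| - 2, while unrelated pairs carry the
# flag-plus-prologue overhead M-hat = -2.

#' Build an exact world-regulator pair universe
#'
#' Enumerates all pairs of binary-interface transducers with up to
#' `max_states` states whose minimal joint code length is at most `L_pair`,
#' runs each pair for `horizon` steps (ON) and against [null_regulator()]
#' (OFF), and aggregates exact prior masses per ON readout.
#'
#' @param L_pair joint code length bound in bits.
#' @param horizon episode length N.
#' @param max_states state bound of the codebook (1 or 2; the default 1 is
#'   the smallest closed universe in which posterior mass is dominated by
#'   minimal explanations, the regime the theory addresses).
#' @return a `pair_universe` with the pair table, the ON-readout
#'   `universe_table`, and metadata.
#' @export
build_pair_universe <- function(L_pair = 30L, horizon = 8L, max_states = 1L) {
  stopifnot(horizon >= 1L, max_states >= 1L, max_states <= 2L)
  specs <- enumerate_binary_specs(max_states)
  ns <- length(specs)
  lens <- vapply(specs, program_length, integer(1L))
  null_r <- null_regulator(2L)
  off_cache <- vapply(specs, function(w)
    paste(run_episode(w, null_r, horizon)$w_out, collapse = ""), character(1L))
  # admit a pair when its minimal joint code (copy flag available only on
  # the diagonal) fits the bound; enumerate admitted index pairs up front
  base_long_mat <- outer(lens, lens, "+") + 1L
  keep <- (base_long_mat + 1L) <= L_pair
  diag(keep) <- diag(keep) | (lens + 2L) <= L_pair
  idx <- which(keep, arr.ind = TRUE)
  i <- idx[, 1L]; j <- idx[, 2L]
  base_long <- base_long_mat[idx]
  base_short <- ifelse(i == j, 1L + lens[i], NA_integer_)
  joint_bits <- as.integer(pmin(base_long, base_short, na.rm = TRUE) + 1L)
  mass <- pad_series_units(base_long, L_pair) +
    ifelse(is.na(base_short), 0, pad_series_units(base_short, L_pair))
  x <- character(length(i))
  for (p in seq_along(i))
    x[p] <- paste(run_episode(specs[[i[p]]], specs[[j[p]]], horizon)$w_out,
                  collapse = "")
  pairs <- data.frame(
    w = i, r = j, code_w_bits = lens[i], code_r_bits = lens[j],
    base_long = base_long, base_short = base_short,
    joint_bits = joint_bits, mass_units = mass,
    m_hat_bits = lens[i] + lens[j] - joint_bits,
    x = x, y = off_cache[i], stringsAsFactors = FALSE)
  agg_m <- tapply(pairs$mass_units, pairs$x, sum)
  agg_k <- tapply(pairs$joint_bits, pairs$x, min)
  agg_n <- tapply(pairs$mass_units, pairs$x, length)
  outs <- names(agg_m)
  ent <- data.frame(output = outs, m_units = as.numeric(agg_m),
                    K_bits = as.integer(agg_k),
                    n_programs = as.numeric(agg_n),
                    stringsAsFactors = FALSE)
  ent <- ent[order(ent$K_bits, -ent$m_units, ent$output), ]
  rownames(ent) <- NULL
  readouts <- structure(
    list(entries = ent, witness = rep(NA_character_, nrow(ent)),
         meta = list(L = as.integer(L_pair), alphabet = 2L,
                     step_cap = as.integer(horizon),
                     max_output_len = as.integer(horizon),
                     codebook = "algoreg-pair-1",
                     total_units = sum(ent$m_units))),
    class = "universe_table")
  structure(list(specs = specs, spec_bits = lens, pairs = pairs,
                 readouts = readouts,
                 L_pair = as.integer(L_pair), horizon = as.integer(horizon),
                 max_states = as.integer(max_states)),
            class = "pair_universe")
}

# All transducers with binary input and output alphabets and S <= max_states.
enumerate_binary_specs <- function(max_states) {
  specs <- list()
  for (S in seq_len(max_states)) {
    cells <- 2L * S
    fills <- expand.grid(c(rep(list(0:(S - 1L)), cells),
                           rep(list(0:1L), cells),
                           list(0:(S - 1L)), list(0:1L)))
    for (i in seq_len(nrow(fills))) {
      row <- as.integer(fills[i, ])
      specs[[length(specs) + 1L]] <- transducer(
        S, 2L, 2L,
        transition = matrix(row[seq_len(cells)], nrow = S, byrow = TRUE),
        emission = matrix(row[cells + seq_len(cells)], nrow = S,
                          byrow = TRUE),
        initial_state = row[2L * cells + 1L],
        initial_emission = row[2L * cells + 2L])
    }
  }
  specs
}

#' @export
print.pair_universe <- function(x, ...) {
  cat(sprintf(paste0("<pair universe: %d pairs over %d machines, L_pair = ",
                     "%d, N = %d, %d distinct ON readouts>\n"),
              nrow(x$pairs), length(x$specs), x$L_pair, x$horizon,
              nrow(x$readouts$entries)))
  invisible(x)
}

#' Posterior over explanations of an observed readout
#'
#' All pairs whose ON readout equals `x`, with their exact universal-prior
#' posterior masses `2^-|p| / m(x)` (computed from integer mass units, so
#' the masses sum to exactly 1), joint code lengths, in-universe mutual
#' information, per-pair contrast gaps `delta = K(y_pair) - K(x)` and the
#' Theorem-2 reference bound `bound_rhs = 2^(m_hat - delta)`.
#'
#' @param universe a `pair_universe`.
#' @param x observed readout (digit string or symbol vector).
#' @return data frame of posterior records (zero rows when no pair produces
#'   `x`).
#' @export
posterior_given_x <- function(universe, x) {
  x <- readout_key(x)
  cons <- universe$pairs[universe$pairs$x == x, , drop = FALSE]
  if (nrow(cons) == 0L) return(cons)
  mx <- sum(cons$mass_units)
  cons$posterior <- cons$mass_units / mx
  kx <- k_exact(universe$readouts, x)
  cons$delta_bits <- k_exact(universe$readouts, cons$y) - kx
  cons$bound_rhs <- 2^(cons$m_hat_bits - cons$delta_bits)
  rownames(cons) <- NULL
  cons
}

readout_key <- function(x) {
  if (is.character(x) && length(x) == 1L) x else paste(as_symbols(x),
                                                       collapse = "")
}

#' Verify the contrastive tilt bound on one readout
#'
#' For every pair explaining `x`, the tilt bound states
#' `posterior <= C * 2^(M_hat) * 2^(-delta)`.  This computes the smallest
#' constant `C*` making the bound hold for all consistent pairs, together
#' with the per-pair records.  Across a suite of readouts `C*` should be of
#' one order of magnitude: the bound's constant is a property of the
#' machine, not of the string.
#'
#' @param universe a `pair_universe`.
#' @param x_on observed ON readout.
#' @return list with `C_star` and the posterior `records`.
#' @export
verify_theorem2 <- function(universe, x_on) {
  rec <- posterior_given_x(universe, x_on)
  if (nrow(rec) == 0L) stop("readout not produced within the universe")
  list(C_star = max(rec$posterior / rec$bound_rhs), records = rec)
}

#' Default readout suite of a pair universe
#'
#' The `n` most compressible distinct ON readouts (smallest in-universe K,
#' ties broken by larger mass then lexicographically).  The tilt results
#' are most informative exactly when the observed readout is simple, so the
#' default verification suite consists of the simplest readouts the
#' universe produces.
#'
#' @param universe a `pair_universe`.
#' @param n suite size.
#' @return character vector of readouts.
#' @export
readout_suite <- function(universe, n = 12L) {
  utils::head(universe$readouts$entries$output, n)
}

#' Pooled posterior envelope against (delta - m_hat)
#'
#' Pools all posterior records of the suite readouts and, for every
#' observed value of `v = delta - m_hat`, records the maximal posterior.
#' Under the tilt bound the envelope halves per bit of `v`; the fitted
#' log-linear slope is returned.
#'
#' @param universe a `pair_universe`.
#' @param readouts suite of readouts (default [readout_suite()]).
#' @return list with the `envelope` data frame (`v`, `max_posterior`) and
#'   the fitted `slope` in bits per bit.
#' @export
posterior_envelope <- function(universe, readouts = readout_suite(universe)) {
  vs <- numeric(0); ps <- numeric(0)
  for (x in readouts) {
    rec <- posterior_given_x(universe, x)
    vs <- c(vs, rec$delta_bits - rec$m_hat_bits)
    ps <- c(ps, rec$posterior)
  }
  env <- tapply(ps, vs, max)
  df <- data.frame(v = as.numeric(names(env)), max_posterior = as.numeric(env))
  fit <- stats::lm(log2(max_posterior) ~ v, data = df)
  list(envelope = df, slope = unname(stats::coef(fit)[2L]))
}

#' Posterior tail curves of a readout
#'
#' Two exact tail functions of the posterior given `x`, for k = 0..`k_max`:
#' the excess-length tail `Pr(|p| >= K(x) + k | x)` over joint programs
#' (prologue-padded lengths included), and the mutual-information tail
#' `Pr(M_hat <= delta - k | x)` over pairs.  Fitted log-linear decay slopes
#' use the convention that exact zeros after positive values are floored at
#' half the universe's mass resolution, and a tail that is identically zero
#' decays faster than any geometric rate (slope `-Inf`, the bound holds
#' vacuously).
#'
#' @param universe a `pair_universe`.
#' @param x_on observed ON readout.
#' @param k_max largest excess considered.
#' @return list with `excess` and `mutual` data frames (`k`, `tail`) and
#'   fitted `excess_slope`, `mutual_slope` (bits per unit k).
#' @export
tail_curves <- function(universe, x_on, k_max = 5L) {
  x <- readout_key(x_on)
  rec <- posterior_given_x(universe, x)
  if (nrow(rec) == 0L) stop("readout not produced within the universe")
  mx <- sum(rec$mass_units)
  kx <- k_exact(universe$readouts, x)
  L <- universe$L_pair
  excess <- vapply(0:k_max, function(k) {
    cutoff <- kx + k
    u <- pad_series_units_from(rec$base_long, L, cutoff)
    short <- !is.na(rec$base_short)
    u[short] <- u[short] +
      pad_series_units_from(rec$base_short[short], L, cutoff)
    sum(u) / mx
  }, numeric(1L))
  mutual <- vapply(0:k_max, function(k) {
    sum(rec$posterior[rec$m_hat_bits <= rec$delta_bits - k])
  }, numeric(1L))
  floor_p <- 0.5 / mx
  list(excess = data.frame(k = 0:k_max, tail = excess),
       mutual = data.frame(k = 0:k_max, tail = mutual),
       excess_slope = fit_tail_slope(excess, floor_p),
       mutual_slope = fit_tail_slope(mutual, floor_p))
}

# Least-squares slope of log2 tail(k) vs k; zeros floored at the mass
# resolution; identically-zero tails decay faster than any geometric rate.
fit_tail_slope <- function(tail, floor_p) {
  if (all(tail == 0)) return(-Inf)
  y <- log2(pmax(tail, floor_p))
  k <- seq_along(tail) - 1
  sum((k - mean(k)) * (y - mean(y))) / sum((k - mean(k))^2)
}

#' Universal Bayes factor between two readouts
#'
#' `log2 m(x_on) - log2 m(x_off)` under the universe's exact semimeasure:
#' the ON-vs-OFF evidence.  The Coding-Theorem identity ties it to the
#' complexity gap: the residual
#' `|bayes_factor - (K(x_off) - K(x_on))|` never exceeds the universe's
#' measured maximal coding gap, and the factor is zero and exact when the
#' readouts coincide.
#'
#' @param universe a `pair_universe` or a `universe_table`.
#' @param x_on,x_off readouts produced within the universe.
#' @return list with `bits`, the complexity-gap reference `k_gap_bits`, the
#'   `residual`, and the table's `max_gap`.
#' @export
bayes_factor <- function(universe, x_on, x_off) {
  tab <- if (inherits(universe, "pair_universe")) universe$readouts
         else universe
  x_on <- readout_key(x_on); x_off <- readout_key(x_off)
  m_on <- m_exact(tab, x_on); m_off <- m_exact(tab, x_off)
  if (m_on == 0 || m_off == 0)
    return(structure(list(bits = NA_real_,
                          absent = c(x_on, x_off)[c(m_on, m_off) == 0]),
                     class = "bayes_factor"))
  bits <- if (identical(x_on, x_off)) 0 else log2(m_on) - log2(m_off)
  kg <- as.numeric(k_exact(tab, x_off) - k_exact(tab, x_on))
  structure(list(bits = bits, k_gap_bits = kg, residual = abs(bits - kg),
                 max_gap = coding_gap_report(tab)$max_gap),
            class = "bayes_factor")
}

#' @export
print.bayes_factor <- function(x, ...) {
  if (!is.null(x$absent)) {
    cat("<Bayes factor undefined: readout(s) not produced within universe>\n")
  } else {
    cat(sprintf("<log2 Bayes factor ON/OFF = %+.3f bits (K gap %+d, residual %.3f <= max gap %.3f)>\n",
                x$bits, as.integer(x$k_gap_bits), x$residual, x$max_gap))
  }
  invisible(x)
}
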