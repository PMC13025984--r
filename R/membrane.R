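# Agency detection in cellular automata.  A candidate "membrane" is a
# rectangular boundary separating a putative agent (the window interior)
# from its environment; the interface stream read off the window perimeter
# is scored for compressibility, and candidates are ranked by how much an
# ablation of their interior inflates that codelength.

#' Evolve a Game of Life history
#'
#' Standard B3/S23 rule on a toroidal grid.
#'
#' @param grid 0/1 matrix (rows x cols), the state at t = 0.
#' @param steps number of update steps T.
#' @return a `grid_history`: `states` is a rows x cols x (T + 1) array of
#'   0/1 frames (frame 1 is the initial state).
#' @examples
#' g <- matrix(0L, 8, 8); g[4, 3:5] <- 1L   # blinker
#' h <- evolve_life(g, 2)
#' identical(h$states[, , 1], h$states[, , 3])
#' @export
evolve_life <- function(grid, steps) {
  grid <- matrix(as.integer(grid != 0), nrow(grid), ncol(grid))
  steps <- as.integer(steps)
  states <- array(0L, dim = c(nrow(grid), ncol(grid), steps + 1L))
  states[, , 1L] <- grid
  for (t in seq_len(steps)) {
    grid <- life_step(grid)
    states[, , t + 1L] <- grid
  }
  structure(list(states = states, steps = steps, rule = "B3/S23",
                 boundary = "toroidal"),
            class = "grid_history")
}

# One synchronous B3/S23 update with toroidal wrap.
life_step <- function(g) {
  up <- function(m) m[c(2:nrow(m), 1L), , drop = FALSE]
  dn <- function(m) m[c(nrow(m), 1:(nrow(m) - 1L)), , drop = FALSE]
  lf <- function(m) m[, c(2:ncol(m), 1L), drop = FALSE]
  rt <- function(m) m[, c(ncol(m), 1:(ncol(m) - 1L)), drop = FALSE]
  nb <- up(g) + dn(g) + lf(g) + rt(g) +
    up(lf(g)) + up(rt(g)) + dn(lf(g)) + dn(rt(g))
  matrix(as.integer(nb == 3L | (g == 1L & nb == 2L)), nrow(g), ncol(g))
}

#' @export
print.grid_history <- function(x, ...) {
  d <- dim(x$states)
  cat(sprintf("<grid history: %dx%d, T = %d, rule %s, %s>\n",
              d[1L], d[2L], x$steps, x$rule, x$boundary))
  invisible(x)
}

#' Rectangular membrane candidate
#'
#' Half-open, 0-based row/column intervals: the region covers rows
#' `row0..row1-1` and columns `col0..col1-1`.  The perimeter is the outer
#' ring of region cells; the interior is everything strictly inside it.
#'
#' @param row0,row1,col0,col1 interval endpoints (`row0 < row1`,
#'   `col0 < col1`).
#' @return a `membrane_partition`.
#' @export
partition <- function(row0, row1, col0, col1) {
  stopifnot(row0 >= 0, col0 >= 0, row1 > row0, col1 > col0)
  structure(list(row0 = as.integer(row0), row1 = as.integer(row1),
                 col0 = as.integer(col0), col1 = as.integer(col1)),
            class = "membrane_partition")
}

#' @export
print.membrane_partition <- function(x, ...) {
  cat(sprintf("<membrane: rows [%d,%d) x cols [%d,%d)>\n",
              x$row0, x$row1, x$col0, x$col1))
  invisible(x)
}

# 1-based (row, col) coordinates of the region's perimeter, in a fixed
# clockwise order starting at the top-left corner: top row left-to-right,
# right column downwards, bottom row right-to-left, left column upwards.
perimeter_cells <- function(part) {
  r0 <- part$row0 + 1L; r1 <- part$row1; c0 <- part$col0 + 1L; c1 <- part$col1
  if (r1 - r0 <= 1L || c1 - c0 <= 1L) {
    # degenerate (single row/column): every region cell is perimeter
    return(as.matrix(expand.grid(row = r0:r1, col = c0:c1))[, 1:2])
  }
  rbind(cbind(r0, c0:c1),
        cbind((r0 + 1L):r1, c1),
        cbind(r1, (c1 - 1L):c0),
        cbind((r1 - 1L):(r0 + 1L), c0))
}

interior_cells <- function(part) {
  r0 <- part$row0 + 2L; r1 <- part$row1 - 1L
  c0 <- part$col0 + 2L; c1 <- part$col1 - 1L
  if (r1 < r0 || c1 < c0) return(matrix(integer(0), 0L, 2L))
  as.matrix(expand.grid(row = r0:r1, col = c0:c1))[, 1:2, drop = FALSE]
}

#' Interface stream of a membrane
#'
#' Concatenates, frame by frame, the states of the region's perimeter cells
#' in the documented clockwise order: the membrane's input-output stream.
#' Its length is `frames x perimeter cells`, with `frames = T + 1`.
#'
#' @param history a `grid_history`.
#' @param part a [partition()].
#' @return integer 0/1 symbol sequence.
#' @export
readout_from_partition <- function(history, part) {
  d <- dim(history$states)
  if (part$row1 > d[1L] || part$col1 > d[2L])
    stop(sprintf("region rows [%d,%d) x cols [%d,%d) exceeds the %dx%d grid",
                 part$row0, part$row1, part$col0, part$col1, d[1L], d[2L]))
  per <- perimeter_cells(part)
  frames <- d[3L]
  out <- integer(frames * nrow(per))
  for (t in seq_len(frames)) {
    out[((t - 1L) * nrow(per) + 1L):(t * nrow(per))] <-
      history$states[cbind(per, t)]
  }
  out
}

#' Scan candidate membranes by compressibility gap
#'
#' For each candidate window, computes the gap
#' `delta = mean_d L(null readout_d) - L(actual readout)` under the chosen
#' null, with one fixed estimator across all candidates, and ranks the
#' candidates by gap (descending; ties broken by smaller region area, then
#' row-major position).  Structured, self-maintaining contents inflate the
#' gap: destroying them makes the interface stream harder to compress.
#'
#' Null modes: `"ablate"` (default) re-evolves the whole history after
#' randomly permuting the candidate's interior cells at t = 0 -- a
#' density-preserving ablation, so a window whose interior is empty (or an
#' all-dead grid) has a gap of exactly zero; `"shuffle"` permutes the time
#' frames of the actual readout without re-simulation (a weaker surrogate).
#' Each candidate's null draws use an RNG substream derived from `seed` and
#' the window coordinates, so duplicated candidates receive identical gaps
#' and a fixed seed yields an identical ranking.
#'
#' @param history a `grid_history`.
#' @param candidates list of [partition()] windows.
#' @param estimator a `codelength_estimator`, shared by all candidates.
#' @param null_mode `"ablate"` or `"shuffle"`.
#' @param seed integer seed.
#' @param n_null number of null draws averaged per candidate.
#' @return data frame with one row per candidate (`row0`, `row1`, `col0`,
#'   `col1`, `delta_bits`, `rank`), ordered by rank.
#' @export
scan_membranes <- function(history, candidates, estimator = est_lz76(2L),
                           null_mode = c("ablate", "shuffle"), seed = 1L,
                           n_null = 8L) {
  null_mode <- tryCatch(match.arg(null_mode), error = function(e)
    stop("unknown null_mode; available modes: ablate, shuffle"))
  stopifnot(length(candidates) >= 1L)
  g0 <- history$states[, , 1L]
  delta <- numeric(length(candidates))
  for (ci in seq_along(candidates)) {
    part <- candidates[[ci]]
    actual <- readout_from_partition(history, part)
    l_actual <- codelength(estimator, actual)$bits
    set.seed(candidate_seed(seed, part))
    l_null <- numeric(n_null)
    for (d in seq_len(n_null)) {
      if (null_mode == "ablate") {
        inter <- interior_cells(part)
        if (nrow(inter) == 0L) {
          l_null[d] <- l_actual
          next
        }
        g <- g0
        g[inter] <- g0[inter][sample.int(nrow(inter))]
        null_hist <- evolve_life(g, history$steps)
        l_null[d] <- codelength(estimator,
                                readout_from_partition(null_hist, part))$bits
      } else {
        per_n <- nrow(perimeter_cells(part))
        frames <- length(actual) / per_n
        shuf <- sample.int(frames)
        fr <- matrix(actual, nrow = per_n)
        l_null[d] <- codelength(estimator, as.vector(fr[, shuf]))$bits
      }
    }
    delta[ci] <- mean(l_null) - l_actual
  }
  res <- data.frame(
    candidate = seq_along(candidates),
    row0 = vapply(candidates, `[[`, 0L, "row0"),
    row1 = vapply(candidates, `[[`, 0L, "row1"),
    col0 = vapply(candidates, `[[`, 0L, "col0"),
    col1 = vapply(candidates, `[[`, 0L, "col1"),
    delta_bits = delta)
  area <- (res$row1 - res$row0) * (res$col1 - res$col0)
  ord <- order(-res$delta_bits, area, res$row0, res$col0)
  res <- res[ord, ]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  res
}

# Deterministic per-candidate seed: mixes the scan seed with the window
# coordinates so identical windows share a null stream.
candidate_seed <- function(seed, part) {
  h <- (part$row0 * 2654435761 + part$row1 * 40503 +
          part$col0 * 69069 + part$col1 * 1103515245) %% 2147480009
  as.integer((seed + h) %% 2147480009)
}

#' Blinker-plus-noise test grid
#'
#' A 64x64 toroidal grid containing, in one quadrant, a small stable colony
#' -- a period-2 blinker flanked by four still-life blocks -- and, in the
#' opposite quadrant, an i.i.d. random soup block; evolved for `steps`
#' generations.  The canonical fixture for [scan_membranes()]: the colony
#' maintains a silent membrane (its window perimeter stays dead), but a
#' density-preserving ablation of the window interior scatters its ~20 live
#' cells into a soup that reliably boils over the perimeter, so the colony
#' window shows a large compressibility gap while the noise window -- whose
#' interior is already unstructured -- does not.
#'
#' @param steps generations to evolve.
#' @param noise_density live-cell probability of the soup block.
#' @param seed RNG seed for the soup.
#' @return list with the `history`, the list of `candidates` (the colony
#'   window containing the blinker, the soup window and two empty control
#'   windows), and `blinker_candidate`, the index of the colony window.
#' @export
life_fixture_blinker_noise <- function(steps = 128L, noise_density = 0.35,
                                       seed = 7L) {
  g <- matrix(0L, 64L, 64L)
  g[11L, 10:12] <- 1L                       # blinker
  g[8:9, 8:9] <- 1L                         # still-life blocks around it
  g[8:9, 14:15] <- 1L
  g[14:15, 8:9] <- 1L
  g[14:15, 14:15] <- 1L
  set.seed(seed)
  block <- matrix(as.integer(stats::runif(14L * 14L) < noise_density),
                  14L, 14L)
  g[41:54, 41:54] <- block
  history <- evolve_life(g, steps)
  candidates <- list(
    partition(6L, 17L, 6L, 17L),            # around the blinker colony
    partition(38L, 56L, 38L, 56L),          # around the soup
    partition(6L, 17L, 40L, 51L),           # empty control
    partition(24L, 35L, 12L, 23L))          # empty control
  list(history = history, candidates = candidates, blinker_candidate = 1L)
}
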