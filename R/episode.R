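# Coupled episodes.  The world and regulator exchange symbols over interface
# streams for a fixed horizon; the world's output stream is the readout whose
# compressibility the rest of the package scores.

#' Run a coupled world-regulator episode
#'
#' Simulates the synchronous causal coupling for `horizon` steps under
#' staggered semantics: at t = 1 both machines emit their `initial_emission`;
#' at each later step a machine reads the symbol its partner emitted at the
#' previous step, moves to `transition(state, input)` and emits
#' `emission(state, input)` (state taken before the move).  The trajectory is
#' therefore unique and deterministic for every machine pair -- no fixed-point
#' search is needed -- and each emission at step t depends only on symbols
#' received at steps before t.
#'
#' @param world,regulator `transducer` objects with complementary alphabets
#'   (the world's input alphabet must equal the regulator's output alphabet
#'   and vice versa).
#' @param horizon number of steps N (>= 1).
#' @param readout_projection function mapping the world output stream to the
#'   readout (default identity).
#' @return a `transcript` with fields `horizon`, `w_out`, `r_out`, `readout`.
#' @examples
#' w <- null_regulator(2)       # constant-0 world
#' r <- null_regulator(2)
#' run_episode(w, r, 5)$w_out
#' @export
run_episode <- function(world, regulator, horizon,
                        readout_projection = identity) {
  stopifnot(inherits(world, "transducer"), inherits(regulator, "transducer"),
            horizon >= 1L)
  if (world$input_alphabet_size != regulator$output_alphabet_size ||
      world$output_alphabet_size != regulator$input_alphabet_size)
    stop(sprintf(paste0("alphabet mismatch: world consumes %d / emits %d ",
                        "symbols but regulator emits %d / consumes %d"),
                 world$input_alphabet_size, world$output_alphabet_size,
                 regulator$output_alphabet_size,
                 regulator$input_alphabet_size))
  horizon <- as.integer(horizon)
  w_out <- integer(horizon)
  r_out <- integer(horizon)
  sw <- world$initial_state
  sr <- regulator$initial_state
  w_out[1L] <- world$initial_emission
  r_out[1L] <- regulator$initial_emission
  if (horizon > 1L) {
    for (t in 2:horizon) {
      uw <- r_out[t - 1L]            # world reads regulator's last emission
      ur <- w_out[t - 1L]
      w_out[t] <- world$emission[sw + 1L, uw + 1L]
      r_out[t] <- regulator$emission[sr + 1L, ur + 1L]
      sw <- world$transition[sw + 1L, uw + 1L]
      sr <- regulator$transition[sr + 1L, ur + 1L]
    }
  }
  structure(list(horizon = horizon, w_out = w_out, r_out = r_out,
                 readout = as.integer(readout_projection(w_out))),
            class = "transcript")
}

#' @export
print.transcript <- function(x, ...) {
  show <- function(v) {
    s <- paste(utils::head(v, 40L), collapse = "")
    if (length(v) > 40L) s <- paste0(s, "...")
    s
  }
  cat(sprintf("<transcript: N = %d>\n  w_out: %s\n  r_out: %s\n",
              x$horizon, show(x$w_out), show(x$r_out)))
  invisible(x)
}

#' Write / read a transcript as CSV
#'
#' Columns `t`, `w_out`, `r_out`; a `#`-prefixed JSON header line records the
#' horizon and (when supplied) machine hashes and the seed, so reruns can be
#' checked for byte identity.
#'
#' @param transcript a `transcript`.
#' @param path file path.
#' @param meta optional named list merged into the header.
#' @return the path (write) or a `transcript` (read).
#' @export
write_transcript <- function(transcript, path, meta = list()) {
  hdr <- c(list(horizon = transcript$horizon), meta)
  con <- file(path, open = "wb")  # binary connection pins LF endings
  on.exit(close(con))
  writeLines(paste0("#", jsonlite::toJSON(hdr, auto_unbox = TRUE)), con,
             sep = "\n")
  writeLines("t,w_out,r_out", con, sep = "\n")
  writeLines(sprintf("%d,%d,%d", seq_len(transcript$horizon),
                     transcript$w_out, transcript$r_out), con, sep = "\n")
  invisible(path)
}

#' @rdname write_transcript
#' @export
read_transcript <- function(path) {
  lines <- readLines(path)
  stopifnot(startsWith(lines[1L], "#"))
  df <- utils::read.csv(text = lines[-1L])
  structure(list(horizon = nrow(df), w_out = as.integer(df$w_out),
                 r_out = as.integer(df$r_out),
                 readout = as.integer(df$w_out)),
            class = "transcript")
}

#' Write a transcript as JSON lines
#'
#' First line is a header object (`horizon`, plus any `meta`); each following
#' line is one step `{"t":..,"w_out":..,"r_out":..}`.
#' @inheritParams write_transcript
#' @export
write_transcript_jsonl <- function(transcript, path, meta = list()) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  hdr <- c(list(horizon = transcript$horizon), meta)
  writeLines(as.character(jsonlite::toJSON(hdr, auto_unbox = TRUE)), con,
             sep = "\n")
  for (t in seq_len(transcript$horizon)) {
    writeLines(as.character(jsonlite::toJSON(
      list(t = t, w_out = transcript$w_out[t], r_out = transcript$r_out[t]),
      auto_unbox = TRUE)), con, sep = "\n")
  }
  invisible(path)
}
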