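# Worlds and regulators are deterministic causal finite transducers.  A
# transducer is identified with its canonical self-delimiting binary code,
# whose length serves as the computable stand-in for the (uncomputable)
# minimal program length used by the theory.

MAX_CODE_SIZE <- 64L  # states / alphabet sizes accepted by the canonical code

#' Deterministic causal finite transducer
#'
#' Constructs a finite-state machine with total transition and emission maps
#' over `n_states` x `input_alphabet_size`.  Symbols and states are 0-based
#' integers; symbol 0 is the designated null symbol.  The machine is causal by
#' construction: in a coupled episode its emission at step t depends only on
#' symbols received at steps before t (see [run_episode()]).
#'
#' @param n_states number of states (>= 1).
#' @param input_alphabet_size,output_alphabet_size alphabet sizes (>= 1).
#' @param transition integer matrix `n_states x input_alphabet_size`; entry
#'   `[s + 1, a + 1]` is the next state after reading symbol `a` in state `s`.
#' @param emission integer matrix of the same shape; the symbol emitted when
#'   reading `a` in state `s`.
#' @param initial_state starting state (0-based).
#' @param initial_emission symbol emitted at t = 1, before any input is seen.
#'   This resolves the bootstrapping of the coupled dynamics.
#' @return an object of class `transducer`.
#' @examples
#' null_regulator(2)
#' @export
transducer <- function(n_states, input_alphabet_size, output_alphabet_size,
                       transition, emission, initial_state = 0L,
                       initial_emission = 0L) {
  n_states <- as.integer(n_states)
  ai <- as.integer(input_alphabet_size)
  ao <- as.integer(output_alphabet_size)
  stopifnot(n_states >= 1L, ai >= 1L, ao >= 1L)
  transition <- matrix(as.integer(transition), nrow = n_states, ncol = ai)
  emission <- matrix(as.integer(emission), nrow = n_states, ncol = ai)
  if (anyNA(transition) || anyNA(emission))
    stop("transition and emission must be total (no NA entries)")
  if (any(transition < 0L) || any(transition >= n_states))
    stop("transition targets must lie in 0..", n_states - 1L)
  if (any(emission < 0L) || any(emission >= ao))
    stop("emission symbols must lie in 0..", ao - 1L)
  initial_state <- as.integer(initial_state)
  initial_emission <- as.integer(initial_emission)
  stopifnot(initial_state >= 0L, initial_state < n_states,
            initial_emission >= 0L, initial_emission < ao)
  structure(
    list(n_states = n_states, input_alphabet_size = ai,
         output_alphabet_size = ao, transition = transition,
         emission = emission, initial_state = initial_state,
         initial_emission = initial_emission),
    class = "transducer")
}

#' @export
print.transducer <- function(x, ...) {
  cat(sprintf("<transducer: %d state%s, in-alphabet %d, out-alphabet %d, |code| = %d bits>\n",
              x$n_states, if (x$n_states > 1) "s" else "",
              x$input_alphabet_size, x$output_alphabet_size,
              program_length(x)))
  invisible(x)
}

#' @export
format.transducer <- function(x, ...) bits_to_chr(encode_program(x))

#' The null (all-zero) regulator
#'
#' A one-state machine that emits symbol 0 forever regardless of input.
#' Coupling a world to it realises the unregulated OFF baseline: the world's
#' output stream in that episode is the OFF readout contrasted against the
#' regulated ON readout by [delta_gap()].
#'
#' @param output_alphabet_size size of the (ignored) input alphabet seen by
#'   the world, i.e. this machine's output alphabet.
#' @param input_alphabet_size the world's output alphabet (default equal).
#' @return a `transducer`.
#' @export
null_regulator <- function(output_alphabet_size, input_alphabet_size = output_alphabet_size) {
  stopifnot(output_alphabet_size >= 1L)
  transducer(1L, input_alphabet_size, output_alphabet_size,
             transition = matrix(0L, 1L, input_alphabet_size),
             emission = matrix(0L, 1L, input_alphabet_size),
             initial_state = 0L, initial_emission = 0L)
}

#' Canonical self-delimiting code of a transducer
#'
#' Layout (prefix-free; lengths in bits): Elias-gamma codes of `n_states`,
#' `input_alphabet_size`, `output_alphabet_size`; then fixed-width fields
#' `initial_state` (`ceiling(log2(n_states))` bits), `initial_emission`
#' (`ceiling(log2(output_alphabet_size))` bits), followed by the transition
#' and emission table entries in row-major (state, input) order, each entry a
#' transition target then an emission symbol at the same widths.  Width-0
#' fields (singleton ranges) occupy no bits.  The code word length is the
#' program length `|p|` used throughout the package.
#'
#' @param spec a `transducer`.
#' @return integer 0/1 vector, the code word.
#' @seealso [decode_program()], [program_length()]
#' @export
encode_program <- function(spec) {
  stopifnot(inherits(spec, "transducer"))
  if (spec$n_states > MAX_CODE_SIZE || spec$input_alphabet_size > MAX_CODE_SIZE ||
      spec$output_alphabet_size > MAX_CODE_SIZE)
    stop("canonical code supports at most ", MAX_CODE_SIZE,
         " states and alphabet symbols")
  ws <- field_width(spec$n_states)
  wo <- field_width(spec$output_alphabet_size)
  bits <- c(elias_gamma(spec$n_states),
            elias_gamma(spec$input_alphabet_size),
            elias_gamma(spec$output_alphabet_size),
            encode_field(spec$initial_state, ws),
            encode_field(spec$initial_emission, wo))
  body <- integer(0)
  for (s in seq_len(spec$n_states)) {
    for (a in seq_len(spec$input_alphabet_size)) {
      body <- c(body, encode_field(spec$transition[s, a], ws),
                encode_field(spec$emission[s, a], wo))
    }
  }
  c(bits, body)
}

#' Length in bits of a transducer's canonical code
#' @inheritParams encode_program
#' @return integer bit count.
#' @export
program_length <- function(spec) {
  canonical_code_length(spec$n_states, spec$input_alphabet_size,
                        spec$output_alphabet_size)
}

# Closed form of the code length for a (states, in, out) shape.
canonical_code_length <- function(n_states, ai, ao) {
  ws <- field_width(n_states)
  wo <- field_width(ao)
  as.integer(elias_gamma_length(n_states) + elias_gamma_length(ai) +
               elias_gamma_length(ao) + ws + wo + n_states * ai * (ws + wo))
}

#' Decode a canonical transducer code
#'
#' Reads exactly one code word from the front of `bits` (self-delimiting:
#' trailing bits are never touched).  A truncated or malformed prefix yields
#' `NULL` -- the invalid-program signal used by the universe enumerators --
#' rather than an error.
#'
#' @param bits integer 0/1 vector beginning with a candidate code word.
#' @return `list(spec = <transducer>, consumed = <bits read>)`, or `NULL`.
#' @export
decode_program <- function(bits) {
  pos <- 1L
  hdr <- list()
  for (fld in c("n_states", "ai", "ao")) {
    g <- elias_gamma_decode(bits, pos)
    if (is.null(g) || g$value > MAX_CODE_SIZE) return(NULL)
    hdr[[fld]] <- g$value
    pos <- pos + g$consumed
  }
  ws <- field_width(hdr$n_states)
  wo <- field_width(hdr$ao)
  rd <- function(width, max_value) {
    f <- decode_field(bits, pos, width)
    if (is.null(f) || f$value >= max_value) return(NULL)
    pos <<- pos + f$consumed
    f$value
  }
  init_s <- rd(ws, hdr$n_states); if (is.null(init_s)) return(NULL)
  init_e <- rd(wo, hdr$ao); if (is.null(init_e)) return(NULL)
  trans <- matrix(0L, hdr$n_states, hdr$ai)
  emis <- matrix(0L, hdr$n_states, hdr$ai)
  for (s in seq_len(hdr$n_states)) {
    for (a in seq_len(hdr$ai)) {
      tv <- rd(ws, hdr$n_states); if (is.null(tv)) return(NULL)
      ev <- rd(wo, hdr$ao); if (is.null(ev)) return(NULL)
      trans[s, a] <- tv
      emis[s, a] <- ev
    }
  }
  spec <- transducer(hdr$n_states, hdr$ai, hdr$ao, trans, emis, init_s, init_e)
  list(spec = spec, consumed = pos - 1L)
}

#' Sample a transducer from the prefix prior
#'
#' Draws a machine with probability proportional to `2^-|p|` over all valid
#' canonical codes of length at most `max_code_length`, the in-codebook
#' realisation of sampling programs from the universal prior.
#'
#' @param max_code_length bound on the code length in bits.
#' @param rng_seed integer seed; draws are reproducible.
#' @param n number of machines to draw.
#' @param max_states,max_alphabet bounds on the shapes enumerated.
#' @return a `transducer` (or a list of them when `n > 1`).
#' @export
sample_program <- function(max_code_length, rng_seed = NULL, n = 1L,
                           max_states = 4L, max_alphabet = 4L) {
  shapes <- expand.grid(S = seq_len(max_states), Ai = seq_len(max_alphabet),
                        Ao = seq_len(max_alphabet))
  shapes$len <- mapply(canonical_code_length, shapes$S, shapes$Ai, shapes$Ao)
  shapes <- shapes[shapes$len <= max_code_length, , drop = FALSE]
  if (nrow(shapes) == 0L)
    stop("max_code_length = ", max_code_length,
         " is too small to contain any valid code")
  # mass of a shape = (#field fillings) * 2^-len
  shapes$count <- with(shapes, S * Ao * (S * Ao)^(S * Ai))
  shapes$mass <- shapes$count * 2^(-shapes$len)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  draws <- vector("list", n)
  idx <- sample.int(nrow(shapes), n, replace = TRUE,
                    prob = shapes$mass / sum(shapes$mass))
  for (i in seq_len(n)) {
    sh <- shapes[idx[i], ]
    cells <- sh$S * sh$Ai
    draws[[i]] <- transducer(
      sh$S, sh$Ai, sh$Ao,
      transition = sample.int(sh$S, cells, replace = TRUE) - 1L,
      emission = sample.int(sh$Ao, cells, replace = TRUE) - 1L,
      initial_state = sample.int(sh$S, 1L) - 1L,
      initial_emission = sample.int(sh$Ao, 1L) - 1L)
  }
  if (n == 1L) draws[[1L]] else draws
}

#' Serialise a transducer to / from JSON
#'
#' The JSON schema carries the state count, both alphabet sizes, the
#' flattened row-major transition and emission tables and the initial
#' state/emission, so machine files are portable and human-readable.
#'
#' @param spec a `transducer`.
#' @param path file path; `transducer_to_json()` returns the JSON string when
#'   `path` is `NULL`.
#' @return `transducer_to_json()`: the path or JSON string;
#'   `transducer_from_json()`: a `transducer`.
#' @export
transducer_to_json <- function(spec, path = NULL) {
  obj <- list(n_states = spec$n_states,
              input_alphabet_size = spec$input_alphabet_size,
              output_alphabet_size = spec$output_alphabet_size,
              transition = as.vector(t(spec$transition)),
              emission = as.vector(t(spec$emission)),
              initial_state = spec$initial_state,
              initial_emission = spec$initial_emission)
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE)
  if (is.null(path)) return(as.character(txt))
  writeLines(txt, path)
  invisible(path)
}

#' @rdname transducer_to_json
#' @param json JSON string (alternative to `path`).
#' @export
transducer_from_json <- function(path = NULL, json = NULL) {
  obj <- jsonlite::fromJSON(if (is.null(json)) path else json)
  transducer(obj$n_states, obj$input_alphabet_size, obj$output_alphabet_size,
             transition = matrix(obj$transition, nrow = obj$n_states,
                                 byrow = TRUE),
             emission = matrix(obj$emission, nrow = obj$n_states, byrow = TRUE),
             initial_state = obj$initial_state,
             initial_emission = obj$initial_emission)
}
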