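# Exact enumeration of a micro program universe.  Every self-delimiting
# program up to a length bound is classified halting or not and its output
# recorded, yielding the exact universal semimeasure m(x), exact prefix
# complexity K(x) and measured Coding-Theorem constants *within* the
# universe.  Masses are accumulated as integer counts of 2^-L units, so
# Kraft sums and posterior identities are exact.
#
# Codebook (version "algoreg-1"): a program is
#
#     1^j 0  |  gamma(n)  |  branch  |  payload
#
# where "1^j 0" (j >= 0) is a no-op prologue -- as on a genuine universal
# machine, every behaviour is realised by programs of every sufficiently
# large length, with the total mass per base program preserved exactly --
# gamma(n) is the Elias-gamma output length, and branch is
#   "0"  literal: n fixed-width symbols;
#   "10" repeat:  gamma(m) + m symbols, cycled/truncated to length n;
#   "11" generator: a canonical transducer code (output alphabet must equal
#        the universe alphabet) free-run on the all-zero input stream.
# A program halts iff its code is well formed and n is within both
# `max_output_len` and `step_cap`; everything else is the non-halting
# bucket.

UNIVERSE_CODEBOOK <- "algoreg-1"

#' Micro-interpreter configuration
#'
#' @param alphabet output alphabet size (symbols `0..alphabet-1`).
#' @param step_cap computation budget: programs needing more than this many
#'   emission steps are classified non-halting.
#' @param max_output_len longest output enumerated.
#' @return a `micro_interpreter`.
#' @export
micro_interpreter <- function(alphabet = 2L, step_cap = 256L,
                              max_output_len = 8L) {
  structure(list(alphabet = as.integer(alphabet),
                 step_cap = as.integer(step_cap),
                 max_output_len = as.integer(max_output_len),
                 codebook = UNIVERSE_CODEBOOK),
            class = "micro_interpreter")
}

# Units of 2^-L contributed by one base program of length `b` once the no-op
# prologue is summed over: lengths b+1+j for j >= 0 up to L.  Total units
# 2^(L-b) - 1; the minimal (j = 0) program has length b + 1.
pad_series_units <- function(b, L) {
  ifelse(b + 1 > L, 0, 2^(L - b) - 1)
}

# Units of the same series restricted to padded lengths >= cutoff.
pad_series_units_from <- function(b, L, cutoff) {
  lo <- pmax(b + 1, cutoff)
  ifelse(lo > L, 0, 2^(L - lo + 1) - 1)
}

#' Enumerate the micro program universe
#'
#' Constructively enumerates every valid program of the codebook with code
#' length at most `L` bits and aggregates, per output string, the exact
#' prior mass `m(x)` (in units of `2^-L`), the exact minimal program length
#' `K(x)`, the number of distinct base programs, and a witness minimal
#' program.
#'
#' @param interpreter a [micro_interpreter()].
#' @param L maximal program length in bits.
#' @return a `universe_table`: `entries` data frame with columns `output`,
#'   `m_units`, `K_bits`, `n_programs`, plus metadata (including
#'   `total_units`, the Kraft sum numerator).
#' @export
enumerate_universe <- function(interpreter = micro_interpreter(), L = 22L) {
  A <- interpreter$alphabet
  w <- field_width(A)
  nmax <- min(interpreter$max_output_len, interpreter$step_cap)
  acc <- new.env(parent = emptyenv())      # output -> c(units, K, n)
  wit <- new.env(parent = emptyenv())      # output -> witness bits (chr)
  put <- function(out, base, count = 1, witness = NULL) {
    if (base + 1 > L) return(invisible())
    units <- count * pad_series_units(base, L)
    cur <- acc[[out]]
    if (is.null(cur)) {
      acc[[out]] <- c(units, base + 1, count)
      if (!is.null(witness)) wit[[out]] <- witness
    } else {
      newK <- min(cur[2L], base + 1)
      if (!is.null(witness) && base + 1 < cur[2L]) wit[[out]] <- witness
      acc[[out]] <- c(cur[1L] + units, newK, cur[3L] + count)
    }
  }
  all_strings <- function(n) {
    # all A^n outputs of length n, as a character vector
    grid <- do.call(expand.grid, rep(list(0:(A - 1L)), n))
    apply(grid, 1L, paste, collapse = "")
  }
  for (n in seq_len(nmax)) {
    hdr <- elias_gamma_length(n)
    # literal branch: 1(pad) + hdr + 1 + n*w
    b_lit <- hdr + 1L + n * w
    if (b_lit + 1 <= L) {
      for (x in all_strings(n))
        put(x, b_lit, witness = paste0("0", bits_to_chr(elias_gamma(n)), "0",
                                       x))
    }
    # repeat branch: 1 + hdr + 2 + gamma(m) + m*w
    m <- 1L
    repeat {
      b_rep <- hdr + 2L + elias_gamma_length(m) + m * w
      if (b_rep + 1 > L || (w == 0L && m > nmax)) break
      if (m < n) {
        for (mot in all_strings(m)) {
          x <- paste(rep(strsplit(mot, "")[[1L]], length.out = n),
                     collapse = "")
          put(x, b_rep,
              witness = paste0("0", bits_to_chr(elias_gamma(n)), "10",
                               bits_to_chr(elias_gamma(m)), mot))
        }
      } else {
        # motif at least as long as the output: every output of length n is
        # the prefix of A^(m-n) motifs
        for (x in all_strings(n))
          put(x, b_rep, count = A^(m - n))
      }
      m <- m + 1L
    }
    # generator branch: 1 + hdr + 2 + |spec|; output alphabet must match
    for (S in 1:4) {
      for (Ai in 1:2) {
        slen <- canonical_code_length(S, Ai, A)
        if (hdr + 2L + slen + 1L > L) next
        cells <- S * Ai
        fills <- expand.grid(c(rep(list(0:(S - 1L)), cells),
                               rep(list(0:(A - 1L)), cells),
                               list(0:(S - 1L)), list(0:(A - 1L))))
        for (i in seq_len(nrow(fills))) {
          row <- as.integer(fills[i, ])
          trans0 <- row[seq_len(cells)][seq(1L, cells, by = Ai)]
          em0 <- row[cells + seq_len(cells)][seq(1L, cells, by = Ai)]
          init_s <- row[2L * cells + 1L]
          init_e <- row[2L * cells + 2L]
          out <- integer(n)
          out[1L] <- init_e
          s <- init_s
          if (n > 1L) for (t in 2:n) {
            out[t] <- em0[s + 1L]
            s <- trans0[s + 1L]
          }
          spec <- transducer(S, Ai, A,
                             transition = matrix(row[seq_len(cells)],
                                                 nrow = S, byrow = TRUE),
                             emission = matrix(row[cells + seq_len(cells)],
                                               nrow = S, byrow = TRUE),
                             initial_state = init_s,
                             initial_emission = init_e)
          put(paste(out, collapse = ""), hdr + 2L + slen,
              witness = paste0("0", bits_to_chr(elias_gamma(n)), "11",
                               bits_to_chr(encode_program(spec))))
        }
      }
    }
  }
  outs <- ls(acc)
  ent <- data.frame(output = outs,
                    m_units = vapply(outs, function(o) acc[[o]][1L], 0),
                    K_bits = vapply(outs, function(o) acc[[o]][2L], 0),
                    n_programs = vapply(outs, function(o) acc[[o]][3L], 0),
                    stringsAsFactors = FALSE)
  ent <- ent[order(ent$K_bits, -ent$m_units, ent$output), ]
  rownames(ent) <- NULL
  witness <- vapply(ent$output, function(o) {
    z <- wit[[o]]; if (is.null(z)) NA_character_ else z
  }, character(1L))
  structure(list(entries = ent, witness = witness,
                 meta = list(L = as.integer(L),
                             alphabet = A,
                             step_cap = interpreter$step_cap,
                             max_output_len = interpreter$max_output_len,
                             codebook = interpreter$codebook,
                             total_units = sum(ent$m_units))),
            class = "universe_table")
}

#' @export
print.universe_table <- function(x, ...) {
  cat(sprintf(paste0("<universe table: %d outputs, L = %d bits, ",
                     "Kraft sum = %.6f>\n"),
              nrow(x$entries), x$meta$L,
              x$meta$total_units / 2^x$meta$L))
  invisible(x)
}

#' Kraft sum of a universe table
#' @param table a `universe_table`.
#' @return exact value of `sum 2^-|p|` over halting programs (a double whose
#'   integer numerator was accumulated exactly).
#' @export
kraft_sum <- function(table) table$meta$total_units / 2^table$meta$L

#' Exact in-universe prefix complexity
#'
#' The minimal program length for `x` within the enumerated universe.
#' Outputs never produced within the universe yield `NA` (the distinguished
#' "not produced" result), not an error.
#'
#' @param table a `universe_table`.
#' @param x output string(s).
#' @return integer bits (vectorised), `NA` where absent.
#' @export
k_exact <- function(table, x) {
  idx <- match(x, table$entries$output)
  as.integer(table$entries$K_bits[idx])
}

#' Exact in-universe semimeasure
#' @inheritParams k_exact
#' @return `m(x)` as a double (exact numerator over `2^L`); 0 where absent.
#' @export
m_exact <- function(table, x) {
  idx <- match(x, table$entries$output)
  u <- table$entries$m_units[idx]
  u[is.na(u)] <- 0
  u / 2^table$meta$L
}

#' Witness minimal program for an output
#' @inheritParams k_exact
#' @return the bits (as a 0/1 string) of one minimal program printing `x`.
#' @export
universe_witness <- function(table, x) {
  unname(table$witness[match(x, table$entries$output)])
}

#' Execute one program of the universe codebook
#'
#' Decodes and runs a single program; used to re-check witnesses.  Returns
#' the output string, or `NULL` for invalid/non-halting programs.
#'
#' @param bits program bits (0/1 integer vector or string).
#' @param interpreter a [micro_interpreter()].
#' @return the output string with attribute `consumed` (bits read), or
#'   `NULL`.  A program whose code word is shorter than `bits` leaves the
#'   trailing bits unread (self-delimiting contract).
#' @export
run_universe_program <- function(bits, interpreter = micro_interpreter()) {
  if (is.character(bits)) bits <- chr_to_bits(bits)
  A <- interpreter$alphabet
  w <- field_width(A)
  pos <- 1L
  while (pos <= length(bits) && bits[pos] == 1L) pos <- pos + 1L  # prologue
  if (pos > length(bits)) return(NULL)
  pos <- pos + 1L                                                  # the 0
  g <- elias_gamma_decode(bits, pos)
  if (is.null(g)) return(NULL)
  n <- g$value
  pos <- pos + g$consumed
  if (n > interpreter$max_output_len || n > interpreter$step_cap) return(NULL)
  if (pos > length(bits)) return(NULL)
  branch <- bits[pos]; pos <- pos + 1L
  if (branch == 0L) {                       # literal
    out <- integer(n)
    for (t in seq_len(n)) {
      f <- decode_field(bits, pos, w)
      if (is.null(f) || f$value >= A) return(NULL)
      out[t] <- f$value; pos <- pos + f$consumed
    }
    return(structure(paste(out, collapse = ""), consumed = pos - 1L))
  }
  if (pos > length(bits)) return(NULL)
  branch2 <- bits[pos]; pos <- pos + 1L
  if (branch2 == 0L) {                      # "10" repeat
    g <- elias_gamma_decode(bits, pos)
    if (is.null(g)) return(NULL)
    m <- g$value; pos <- pos + g$consumed
    motif <- integer(m)
    for (t in seq_len(m)) {
      f <- decode_field(bits, pos, w)
      if (is.null(f) || f$value >= A) return(NULL)
      motif[t] <- f$value; pos <- pos + f$consumed
    }
    return(structure(paste(rep(motif, length.out = n), collapse = ""),
                     consumed = pos - 1L))
  }
  if (pos > length(bits)) return(NULL)
  dec <- decode_program(bits[pos:length(bits)])   # "11" generator
  if (is.null(dec) || dec$spec$output_alphabet_size != A) return(NULL)
  spec <- dec$spec
  out <- integer(n)
  out[1L] <- spec$initial_emission
  s <- spec$initial_state
  if (n > 1L) for (t in 2:n) {
    out[t] <- spec$emission[s + 1L, 1L]
    s <- spec$transition[s + 1L, 1L]
  }
  structure(paste(out, collapse = ""), consumed = pos - 1L + dec$consumed)
}

#' Coding-Theorem gap report
#'
#' Per-string gap `g(x) = K(x) + log2 m(x)`, non-negative because the
#' minimal program contributes `2^-K(x)` to `m(x)`.  `2^min_gap` and
#' `2^max_gap` realise the machine-dependent Coding Theorem constants of
#' this universe: `c1 <= m(x) * 2^K(x) <= c2` holds for every produced
#' string with `c1 = 2^min_gap`, `c2 = 2^max_gap`.
#'
#' @param table a `universe_table` (the pair universe's readout table also
#'   works).
#' @return a `coding_gap_report` with the per-string table and `min_gap`,
#'   `max_gap`.
#' @export
coding_gap_report <- function(table) {
  ent <- table$entries
  if (nrow(ent) == 0L) stop("empty universe table")
  gap <- ent$K_bits + (log2(ent$m_units) - table$meta$L)
  structure(list(per_string = data.frame(output = ent$output,
                                         K_bits = ent$K_bits,
                                         log2_m = log2(ent$m_units) -
                                           table$meta$L,
                                         gap = gap,
                                         stringsAsFactors = FALSE),
                 min_gap = min(gap), max_gap = max(gap)),
            class = "coding_gap_report")
}

#' @export
print.coding_gap_report <- function(x, ...) {
  cat(sprintf("<coding gaps over %d strings: min %.3f, max %.3f bits>\n",
              nrow(x$per_string), x$min_gap, x$max_gap))
  invisible(x)
}

#' Serialise a universe table
#'
#' A `#`-prefixed JSON metadata line (L, step cap, alphabet, codebook
#' version, total mass units) followed by CSV entries.
#'
#' @param table a `universe_table`.
#' @param path file path.
#' @export
write_universe <- function(table, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste0("#", jsonlite::toJSON(table$meta, auto_unbox = TRUE)),
             con, sep = "\n")
  writeLines("output,m_units,K_bits,n_programs", con, sep = "\n")
  e <- table$entries
  writeLines(sprintf("%s,%.0f,%d,%.0f", e$output, e$m_units,
                     as.integer(e$K_bits), e$n_programs), con, sep = "\n")
  invisible(path)
}

#' @rdname write_universe
#' @export
read_universe <- function(path) {
  lines <- readLines(path)
  meta <- jsonlite::fromJSON(sub("^#", "", lines[1L]))
  ent <- utils::read.csv(text = lines[-1L],
                         colClasses = c(output = "character",
                                        m_units = "numeric",
                                        K_bits = "integer",
                                        n_programs = "numeric"))
  structure(list(entries = ent, witness = rep(NA_character_, nrow(ent)),
                 meta = meta),
            class = "universe_table")
}
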