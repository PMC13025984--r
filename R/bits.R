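# Bit-level plumbing shared by the canonical transducer code and the program
# universes.  Bitstrings are integer vectors of 0/1; all codes built here are
# prefix-free by construction (Elias-gamma headers + fixed-width bodies).

#' Elias gamma code of a positive integer
#'
#' `elias_gamma()` returns the self-delimiting Elias gamma code of `n` as an
#' integer 0/1 vector; `elias_gamma_length()` returns just its length in bits
#' (`2*floor(log2(n)) + 1`).
#'
#' @param n positive integer (vectorised for `elias_gamma_length`).
#' @return integer vector of bits, or bit lengths.
#' @keywords internal
elias_gamma <- function(n) {
  stopifnot(length(n) == 1L, n >= 1)
  k <- floor(log2(n))
  body <- as.integer(intToBits(n))[seq_len(k + 1)]  # little-endian
  c(rep(0L, k), rev(body))
}

#' @rdname elias_gamma
#' @keywords internal
elias_gamma_length <- function(n) 2L * floor(log2(n)) + 1L

# Decode an Elias gamma code starting at `pos`; NULL when truncated/invalid.
elias_gamma_decode <- function(bits, pos = 1L) {
  n <- length(bits)
  k <- 0L
  while (pos + k <= n && bits[pos + k] == 0L) k <- k + 1L
  if (pos + k > n) return(NULL)           # ran off the end scanning zeros
  if (pos + 2L * k > n) return(NULL)      # body truncated
  body <- bits[(pos + k):(pos + 2L * k)]
  value <- sum(body * 2^(rev(seq_along(body)) - 1L))
  list(value = as.integer(value), consumed = 2L * k + 1L)
}

# Fixed-width big-endian field; width 0 encodes the single value 0.
field_width <- function(size) if (size <= 1L) 0L else as.integer(ceiling(log2(size)))

encode_field <- function(value, width) {
  if (width == 0L) return(integer(0))
  rev(as.integer(intToBits(value))[seq_len(width)])
}

decode_field <- function(bits, pos, width) {
  if (width == 0L) return(list(value = 0L, consumed = 0L))
  if (pos + width - 1L > length(bits)) return(NULL)
  seg <- bits[pos:(pos + width - 1L)]
  list(value = as.integer(sum(seg * 2^(rev(seq_along(seg)) - 1L))),
       consumed = width)
}

#' Render a bit vector as a compact string
#' @param bits integer 0/1 vector.
#' @return single string such as `"010011"`.
#' @keywords internal
bits_to_chr <- function(bits) paste(bits, collapse = "")

chr_to_bits <- function(x) as.integer(strsplit(x, "", fixed = TRUE)[[1]])
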