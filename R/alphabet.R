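#' Symbol alphabet
#'
#' The source alphabet over which the sequence channel is modelled. The core
#' DNA alphabet is `A,C,G,T`; any other character in an input sequence is
#' replaced by a placeholder symbol in the model stream and restored losslessly
#' from an exception side-channel (see [split_streams()]).
#'
#' @param symbols Character vector of unique single characters, in index order.
#' @return An object of class `symbol_alphabet` with fields `symbols` and
#'   `size`.
#' @examples
#' dna_alphabet()
#' @export
symbol_alphabet <- function(symbols = c("A", "C", "G", "T")) {
  symbols <- as.character(symbols)
  if (length(symbols) < 2)
    stop("alphabet must have at least 2 symbols")
  if (anyDuplicated(symbols))
    stop("alphabet symbols must be unique")
  if (any(nchar(symbols) != 1))
    stop("alphabet symbols must be single characters")
  structure(list(symbols = symbols, size = length(symbols)),
            class = "symbol_alphabet")
}

#' @rdname symbol_alphabet
#' @export
dna_alphabet <- function() symbol_alphabet(c("A", "C", "G", "T"))

#' @export
print.symbol_alphabet <- function(x, ...) {
  cat("<symbol_alphabet> |Σ| =", x$size, ":",
      paste(x$symbols, collapse = ","), "\n")
  invisible(x)
}

# complement of a 0-based DNA symbol index (A<->T, C<->G)
complement_index <- function(sym) 3L - sym
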