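#' Parse a molecular formula
#'
#' Parses a condensed molecular formula such as `"C16H34"` into a named
#' integer vector of element counts. Charge is never encoded in the
#' formula string; it is a separate attribute of a species (so the proton
#' is the species with formula `"H"` and charge `+1`). The symbol `"R"`
#' is accepted as a bookkeeping pseudo-element for the H4MPT methyl
#' carrier pair (`R-H` / `R-CH3`) used in the pathway half-reactions.
#'
#' @param text Molecular formula string: a sequence of element symbols,
#'   each optionally followed by a positive integer count.
#' @return Named integer vector mapping element symbol to count, in the
#'   order first encountered. The empty composition (for the formal
#'   electron species) is represented by a zero-length vector and is only
#'   produced by [species()], never by `parse_formula()`.
#' @examples
#' parse_formula("C16H34")
#' parse_formula("H2O")
#' parse_formula("C2H3O2") # acetate; charge -1 is supplied separately
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1 || is.na(text)) {
    stop("formula must be a single character string", call. = FALSE)
  }
  if (!nzchar(trimws(text))) {
    stop("cannot parse empty formula string", call. = FALSE)
  }
  text <- trimws(text)
  tokens <- regmatches(text, gregexpr("[A-Z][a-z]?[0-9]*", text))[[1]]
  if (paste(tokens, collapse = "") != text) {
    bad <- sub(paste0("^", paste(vapply(tokens, function(t) {
      paste0("\\Q", t, "\\E")
    }, character(1)), collapse = "")), "", text)
    stop("unparseable formula token near: '", substr(bad, 1, 8), "' in '",
         text, "'", call. = FALSE)
  }
  comp <- integer(0)
  for (tok in tokens) {
    sym <- regmatches(tok, regexpr("^[A-Z][a-z]?", tok))
    if (!sym %in% .known_elements) {
      stop("unknown element symbol '", sym, "' in formula '", text, "'",
           call. = FALSE)
    }
    cnt_str <- sub("^[A-Z][a-z]?", "", tok)
    cnt <- if (nzchar(cnt_str)) as.integer(cnt_str) else 1L
    if (is.na(cnt) || cnt < 1) {
      stop("element count must be a positive integer in token '", tok, "'",
           call. = FALSE)
    }
    comp[sym] <- (if (sym %in% names(comp)) comp[[sym]] else 0L) + cnt
  }
  comp
}

# small-molecule bookkeeping scope: CHONSP plus common counter-ions and
# the carrier pseudo-element R
.known_elements <- c("C", "H", "O", "N", "S", "P", "Fe", "Na", "K", "Cl",
                     "Mg", "Ca", "R")

#' Write a composition as a Hill-order formula
#'
#' Canonical writer: carbon first, then hydrogen, then remaining elements
#' alphabetically; when no carbon is present, all elements alphabetically.
#' `parse_formula(write_formula(x))` is the identity on canonical
#' compositions.
#'
#' @param composition Named integer vector as returned by [parse_formula()].
#' @return A single formula string; `""` for the empty composition.
#' @examples
#' write_formula(c(H = 34L, C = 16L)) # "C16H34"
#' @export
write_formula <- function(composition) {
  if (length(composition) == 0) return("")
  els <- names(composition)
  if ("C" %in% els) {
    rest <- sort(setdiff(els, c("C", "H")))
    ord <- c("C", intersect("H", els), rest)
  } else {
    ord <- sort(els)
  }
  paste0(vapply(ord, function(e) {
    n <- composition[[e]]
    if (n == 1) e else paste0(e, n)
  }, character(1)), collapse = "")
}
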