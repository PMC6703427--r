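#' Construct a reaction
#'
#' A reaction is a signed stoichiometric map over species ids: negative
#' coefficients are consumed, positive are produced. Coefficients for the
#' same species are summed and zero coefficients dropped, so a reaction
#' that nets to nothing (e.g. methanogenic "disproportionation" of
#' methane itself) becomes the empty reaction; such reactions carry a
#' `degenerate` attribute when produced by [balance_alkane()].
#'
#' @param coefficients Named numeric vector, species id -> signed
#'   coefficient. Coefficients are exact rationals in intent; in practice
#'   every reaction produced by this package has integer coefficients.
#' @param label Free-text label.
#' @param degenerate Logical flag for reactions that net to zero.
#' @return A tibble of class `alk_reaction` with columns `species`, `coef`.
#' @examples
#' reaction(c(c16h34 = -4, h2o = -30, ch4_g = 49, co2_aq = 15),
#'          label = "methanogenic hexadecane disproportionation")
#' @export
reaction <- function(coefficients, label = "", degenerate = FALSE) {
  if (is.null(names(coefficients)) ||
      any(!nzchar(names(coefficients)))) {
    stop("coefficients must be a fully named numeric vector", call. = FALSE)
  }
  agg <- tapply(coefficients, names(coefficients), sum)
  agg <- agg[order(match(names(agg), names(coefficients)))]
  agg <- agg[agg != 0]
  out <- tibble::tibble(species = names(agg), coef = unname(as.numeric(agg)))
  structure(out, label = label, degenerate = isTRUE(degenerate),
            class = c("alk_reaction", class(out)))
}

#' @noRd
reaction_coefs <- function(rxn) {
  stats::setNames(rxn$coef, rxn$species)
}

#' @export
print.alk_reaction <- function(x, ..., table = NULL) {
  lab <- attr(x, "label")
  if (nzchar(lab %||% "")) cat("<reaction>", lab, "\n") else cat("<reaction>\n")
  if (nrow(x) == 0) {
    cat(if (isTRUE(attr(x, "degenerate"))) "  (degenerate: nets to zero)\n"
        else "  (empty)\n")
  } else {
    cat(" ", as_equation(x, table = table), "\n")
  }
  invisible(x)
}

#' Render a reaction as equation text
#'
#' @param rxn An `alk_reaction`.
#' @param table Optional species table; when given, species are shown by
#'   molecular formula (with charge suffix) instead of id.
#' @param arrow Arrow string between the two sides.
#' @return A single string like `"4 C16H34 + 30 H2O -> 49 CH4 + 15 CO2"`.
#' @export
as_equation <- function(rxn, table = NULL, arrow = "->") {
  if (nrow(rxn) == 0) return(paste("(nothing)", arrow, "(nothing)"))
  disp <- function(id) {
    if (is.null(table) || !(id %in% table$id)) return(id)
    row <- species_row(table, id)
    f <- row$formula
    if (!nzchar(f)) f <- "e"
    ch <- row$charge
    suf <- if (ch == 0) "" else if (ch == 1) "+" else if (ch == -1) "-"
           else paste0(abs(ch), if (ch > 0) "+" else "-")
    paste0(f, suf)
  }
  side <- function(coefs, ids) {
    paste(mapply(function(c, id) {
      if (c == 1) disp(id) else paste(format(c, scientific = FALSE), disp(id))
    }, coefs, ids), collapse = " + ")
  }
  lhs <- rxn$coef < 0
  paste(side(-rxn$coef[lhs], rxn$species[lhs]), arrow,
        side(rxn$coef[!lhs], rxn$species[!lhs]))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a reaction into a species/coefficient tibble
#'
#' @param x An `alk_reaction`.
#' @param ... Unused.
#' @return Tibble with columns `species`, `coef`, `role`
#'   (reactant/product).
#' @method tidy alk_reaction
#' @export
tidy.alk_reaction <- function(x, ...) {
  tibble::tibble(species = x$species, coef = x$coef,
                 role = ifelse(x$coef < 0, "reactant", "product"))
}

#' Serialize a reaction to JSON
#'
#' Coefficients are written as exact rational strings (`"p/q"`, or `"p"`
#' when integral).
#'
#' @param rxn An `alk_reaction`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly, when `path` is given).
#' @export
reaction_to_json <- function(rxn, path = NULL) {
  coef_str <- vapply(rxn$coef, function(co) q_format(q_from_numeric(co)),
                     character(1))
  obj <- list(label = attr(rxn, "label"),
              stoichiometry = as.list(stats::setNames(coef_str, rxn$species)))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' Read a reaction from its JSON serialization
#'
#' @param path_or_text File path or JSON string.
#' @return An `alk_reaction`.
#' @export
reaction_from_json <- function(path_or_text) {
  obj <- jsonlite::fromJSON(path_or_text)
  coefs <- vapply(obj$stoichiometry, function(s) q_as_numeric(q_parse(s)),
                  numeric(1))
  reaction(coefs, label = obj$label %||% "")
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
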