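#' Check element and charge balance of a reaction
#'
#' Computes per-element and charge residuals `sum_i nu_i * count_i`
#' exactly (coefficients in this package are integers, so integer
#' arithmetic is exact). A reaction is balanced iff every residual is
#' zero. The formal electron species contributes charge -1 and no
#' elements.
#'
#' @param rxn An [reaction()] object.
#' @param table Species table containing every species in the reaction.
#' @return Tibble of class `balance_report` with columns `quantity`
#'   (element symbol or `"charge"`) and `residual`; attribute `balanced`
#'   (also via [is_balanced()]).
#' @export
check_balance <- function(rxn, table) {
  missing <- setdiff(rxn$species, table$id)
  if (length(missing)) {
    stop("species not in table: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  comps <- lapply(rxn$species, species_composition, table = table)
  elements <- unique(unlist(lapply(comps, names)))
  res <- vapply(elements, function(el) {
    sum(vapply(seq_len(nrow(rxn)), function(i) {
      cnt <- comps[[i]]
      rxn$coef[i] * (if (el %in% names(cnt)) cnt[[el]] else 0)
    }, numeric(1)))
  }, numeric(1))
  charge_res <- sum(vapply(seq_len(nrow(rxn)), function(i) {
    rxn$coef[i] * species_row(table, rxn$species[i])$charge
  }, numeric(1)))
  out <- tibble::tibble(quantity = c(elements, "charge"),
                        residual = c(unname(res), charge_res))
  structure(out, balanced = all(out$residual == 0),
            class = c("balance_report", class(out)))
}

#' @rdname check_balance
#' @export
is_balanced <- function(rxn, table) {
  attr(check_balance(rxn, table), "balanced")
}

#' Balance a reaction over a species set (matrix null-space oracle)
#'
#' Generic balancer: builds the exact integer element-and-charge matrix
#' over the given species and solves for the unique stoichiometry that
#' honors the fixed coefficient(s). This is the brute-force oracle the
#' closed-form stoichiometries of [balance_alkane()] are verified
#' against. With one fixed coefficient it requires a one-dimensional
#' null space; supplying several fixed coefficients resolves higher
#' null-space dimensions (needed for the half-reactions, where the
#' carrier pair adds a degree of freedom).
#'
#' @param species_ids Character vector of species ids (order is
#'   immaterial up to identical coefficients).
#' @param fixed Named numeric vector pinning one or more coefficients,
#'   e.g. `c(c16h34 = -4)`.
#' @param table Species table.
#' @return An [reaction()] balanced exactly; coefficients are rational
#'   (numerically exact for the small systems arising here).
#' @examples
#' tab <- default_species_table()
#' general_balance(c("c16h34", "h2o", "ch4_g", "co2_aq"),
#'                 fixed = c(c16h34 = -4), table = tab)
#' @export
general_balance <- function(species_ids, fixed, table = default_species_table()) {
  if (is.null(names(fixed)) || any(!nzchar(names(fixed)))) {
    stop("'fixed' must be a named numeric vector", call. = FALSE)
  }
  if (!all(names(fixed) %in% species_ids)) {
    stop("fixed species must be among species_ids", call. = FALSE)
  }
  if (anyDuplicated(species_ids)) {
    stop("duplicate species ids", call. = FALSE)
  }
  comps <- lapply(species_ids, species_composition, table = table)
  charges <- vapply(species_ids, function(id) species_row(table, id)$charge,
                    numeric(1))
  elements <- unique(unlist(lapply(comps, names)))
  M <- matrix(0, nrow = length(elements) + 1, ncol = length(species_ids),
              dimnames = list(c(elements, "charge"), species_ids))
  for (j in seq_along(species_ids)) {
    cnt <- comps[[j]]
    for (el in names(cnt)) M[el, j] <- cnt[[el]]
    M["charge", j] <- charges[j]
  }
  free_ids <- setdiff(species_ids, names(fixed))
  if (length(free_ids) == 0) stop("no free species to solve for", call. = FALSE)
  # move fixed columns to the right-hand side (exact rational rhs)
  b <- vector("list", nrow(M))
  for (i in seq_len(nrow(M))) {
    acc <- q_from_int(0)
    for (fid in names(fixed)) {
      acc <- q_add(acc, q_mul(q_from_numeric(fixed[[fid]]),
                              q_from_int(M[i, fid])))
    }
    b[[i]] <- q_mul(q_from_int(-1), acc)
  }
  sol <- q_solve(M[, free_ids, drop = FALSE], b)
  if (sol$status == "underdetermined") {
    stop("ambiguous stoichiometry: null space dimension > ", length(fixed),
         "; pin more coefficients", call. = FALSE)
  }
  if (sol$status == "inconsistent") {
    stop("infeasible: no balanced reaction exists with the fixed coefficient(s)",
         call. = FALSE)
  }
  coefs <- stats::setNames(numeric(length(species_ids)), species_ids)
  coefs[names(fixed)] <- fixed
  coefs[free_ids] <- vapply(sol$x, q_as_numeric, numeric(1))
  if (all(coefs == 0)) {
    stop("infeasible: only the zero solution exists", call. = FALSE)
  }
  reaction(coefs, label = "general_balance solution")
}

#' Normalize reaction coefficients to smallest integers
#'
#' Divides all coefficients by their greatest common divisor (after
#' clearing denominators). This is an explicit, separate step so that
#' fixed-basis reactions (the printed 4-alkane normalization of the
#' methanogenic fate) are reproducible.
#'
#' @param rxn An `alk_reaction` with rational coefficients.
#' @return The reaction scaled to coprime integer coefficients, with the
#'   first coefficient's sign preserved.
#' @export
normalize_reaction <- function(rxn) {
  if (nrow(rxn) == 0) return(rxn)
  qs <- lapply(rxn$coef, q_from_numeric)
  dens <- vapply(qs, function(q) q[2], numeric(1))
  lcm2 <- function(a, b) a / q_gcd(a, b) * b
  L <- Reduce(lcm2, dens, accumulate = FALSE)
  ints <- vapply(qs, function(q) q[1] * (L / q[2]), numeric(1))
  g <- Reduce(q_gcd, abs(ints))
  ints <- ints / g
  reaction(stats::setNames(ints, rxn$species), label = attr(rxn, "label"),
           degenerate = attr(rxn, "degenerate"))
}
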