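#' Degradation fates of an n-alkane
#'
#' The fates modelled for anaerobic degradation of a CnH2n+2 alkane
#' without an external electron acceptor:
#'
#' * `complete_oxidation`: oxidation to CO2 with H2 as the electron sink,
#'   `CnH2n+2 + 2n H2O -> n CO2 + (3n+1) H2`;
#' * `acetogenic`: incomplete oxidation to acetate,
#'   `CnH2n+2 + n H2O -> (n/2) CH3COO- + (n/2) H+ + (n+1) H2`
#'   (emitted on a 2-alkane basis when n is odd so coefficients stay
#'   integral);
#' * `methanogenic`: disproportionation to methane and CO2,
#'   `4 CnH2n+2 + (2n-2) H2O -> (3n+1) CH4 + (n-1) CO2`, printed on the
#'   4-alkane basis;
#' * the three half-steps of the single-cell pathway model
#'   (`oxidation_half`, `methyl_reduction_half`, `co2_reduction_half`),
#'   written with the H4MPT methyl carrier `R-H`/`R-CH3` and the formal
#'   electron, all on the 4-alkane basis.
#'
#' @return Character vector of fate names.
#' @export
alkane_fates <- function() {
  c("complete_oxidation", "acetogenic", "methanogenic",
    "oxidation_half", "methyl_reduction_half", "co2_reduction_half")
}

#' Balanced stoichiometry of an alkane degradation fate
#'
#' Closed-form balanced reactions for each [alkane_fates()] entry. Every
#' output satisfies exact element and charge conservation
#' ([check_balance()]) and agrees with the generic matrix balancer
#' ([general_balance()]) on the same species set.
#'
#' @param n Alkane chain length (carbon atoms), integer >= 1.
#' @param fate One of [alkane_fates()].
#' @param basis `"paper"` keeps the conventional basis (4 alkanes for the
#'   methanogenic fate and the half-steps, 1 or 2 for the others);
#'   `"min"` rescales to smallest integer coefficients.
#' @param ch4,co2,h2 Species ids used for the products. Defaults follow
#'   the package convention for anoxic marine sediments: CH4 and H2
#'   referenced to 1 bar gas, CO2 to the dissolved (1 M) standard state
#'   (it joins the porewater DIC pool).
#' @return An [reaction()]; for n = 1 the methanogenic fate nets to zero
#'   (methane "disproportionating" to methane) and is returned as an
#'   empty reaction flagged `degenerate`.
#' @examples
#' balance_alkane(16, "methanogenic")
#' balance_alkane(16, "acetogenic")
#' @export
balance_alkane <- function(n, fate = alkane_fates(), basis = c("paper", "min"),
                           ch4 = "ch4_g", co2 = "co2_aq", h2 = "h2_g") {
  n <- check_chain_length(n)
  fate <- match.arg(fate)
  basis <- match.arg(basis)
  alk <- alkane_id(n)
  coefs <- switch(fate,
    complete_oxidation = stats::setNames(
      c(-1, -2 * n, n, 3 * n + 1), c(alk, "h2o", co2, h2)),
    acetogenic = {
      k <- if (n %% 2 == 0) 1 else 2 # 2-alkane basis keeps acetate integral
      stats::setNames(
        c(-k, -k * n, k * n / 2, k * n / 2, k * (n + 1)),
        c(alk, "h2o", "acetate", "h_plus", h2))
    },
    methanogenic = stats::setNames(
      c(-4, -(2 * n - 2), 3 * n + 1, n - 1), c(alk, "h2o", ch4, co2)),
    oxidation_half = stats::setNames(
      c(-4, -4 * n, -2 * n, 2 * n, 2 * n, 12 * n + 8, 12 * n + 8),
      c(alk, "h2o", "rh", "rch3", co2, "h_plus", "e_minus")),
    methyl_reduction_half = stats::setNames(
      c(-2 * n, -4 * n, -4 * n, 2 * n, 2 * n),
      c("rch3", "e_minus", "h_plus", ch4, "rh")),
    co2_reduction_half = stats::setNames(
      c(-(n + 1), -(8 * n + 8), -(8 * n + 8), n + 1, 2 * n + 2),
      c(co2, "h_plus", "e_minus", ch4, "h2o"))
  )
  rxn <- reaction(coefs,
                  label = sprintf("%s, n=%d", fate, n),
                  degenerate = fate == "methanogenic" && n == 1)
  if (basis == "min" && nrow(rxn) > 0) rxn <- normalize_reaction(rxn)
  rxn
}

#' Sum of the three pathway half-steps
#'
#' Formal sum of the alkane-oxidation, methyl-reduction and CO2-reduction
#' half-reactions on the 4-alkane basis. The carrier pair, protons and
#' electrons cancel exactly, leaving the overall methanogenic
#' disproportionation `4 CnH2n+2 + (2n-2) H2O -> (3n+1) CH4 + (n-1) CO2`.
#'
#' @inheritParams balance_alkane
#' @return An [reaction()] equal to
#'   `balance_alkane(n, "methanogenic")`.
#' @examples
#' compose_half_steps(16)
#' @export
compose_half_steps <- function(n, ch4 = "ch4_g", co2 = "co2_aq") {
  n <- check_chain_length(n)
  halves <- lapply(c("oxidation_half", "methyl_reduction_half",
                     "co2_reduction_half"),
                   function(f) balance_alkane(n, f, ch4 = ch4, co2 = co2))
  total <- unlist(lapply(halves, reaction_coefs))
  reaction(total, label = sprintf("sum of half-steps, n=%d", n),
           degenerate = n == 1)
}

#' @noRd
same_reaction <- function(a, b) {
  ca <- reaction_coefs(a); cb <- reaction_coefs(b)
  ids <- union(names(ca), names(cb))
  get <- function(v, id) if (id %in% names(v)) v[[id]] else 0
  all(vapply(ids, function(id) get(ca, id) == get(cb, id), logical(1)))
}
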