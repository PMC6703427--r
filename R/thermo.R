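# gas constant, kJ mol^-1 K^-1
.R_kJ <- 8.31446e-3
.T_STD <- 298.15

#' Thermodynamic evaluation conditions
#'
#' Bundles the temperature, pH and species activities defining an in-situ
#' Gibbs-energy evaluation. Activities are partial pressures in bar for
#' gases and molar concentrations (relative to 1 M) for aqueous solutes;
#' unlisted species default to activity 1 (the convention for pure
#' liquids/solids and the standard state). The proton activity is always
#' `10^-pH` and must not be listed in `activities`.
#'
#' @param temperature_k Temperature in kelvin (> 0).
#' @param ph pH, in `[0, 14]`.
#' @param activities Named numeric vector, species id -> activity (> 0).
#' @return List of class `alk_conditions`.
#' @examples
#' conditions(277, ph = 7.5, activities = c(ch4_g = 0.5, co2_aq = 0.1))
#' @export
conditions <- function(temperature_k = 298.15, ph = 7,
                       activities = numeric(0)) {
  if (!is.numeric(temperature_k) || length(temperature_k) != 1 ||
      is.na(temperature_k) || temperature_k <= 0) {
    stop("temperature_k must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(ph) || length(ph) != 1 || is.na(ph) || ph < 0 || ph > 14) {
    stop("ph must be in [0, 14]", call. = FALSE)
  }
  if (length(activities)) {
    if (is.null(names(activities)) || any(!nzchar(names(activities)))) {
      stop("activities must be a named numeric vector", call. = FALSE)
    }
    if (any(is.na(activities)) || any(activities <= 0)) {
      stop("all activities must be > 0", call. = FALSE)
    }
    if ("h_plus" %in% names(activities)) {
      stop("set proton activity via 'ph', not 'activities'", call. = FALSE)
    }
  }
  structure(list(temperature_k = temperature_k, ph = ph,
                 activities = activities),
            class = "alk_conditions")
}

#' Read a conditions file
#'
#' Flat YAML with keys `temperature_k`, `ph` and an `activities` mapping
#' of species id to activity.
#'
#' @param path Path to the YAML file.
#' @return An [conditions()] object.
#' @export
read_conditions <- function(path) {
  y <- yaml::read_yaml(path)
  conditions(temperature_k = y$temperature_k %||% 298.15,
             ph = y$ph %||% 7,
             activities = unlist(y$activities %||% list()))
}

#' Standard Gibbs energy of a reaction
#'
#' `sum_i nu_i * dGf0_i` at 298.15 K with all species at standard state
#' (gases 1 bar, solutes 1 M, pure liquids/solids). Exact within the
#' shipped table's precision.
#'
#' @param rxn An [reaction()].
#' @param table Species table with `dGf0_kJ_mol` for every species that
#'   appears with a nonzero coefficient.
#' @return Gibbs energy change in kJ per reaction as written.
#' @export
delta_g_standard <- function(rxn, table = default_species_table()) {
  if (nrow(rxn) == 0) return(0)
  gf <- vapply(rxn$species, function(id) species_row(table, id)$dGf0_kJ_mol,
               numeric(1))
  if (anyNA(gf)) {
    stop("missing dGf0 for species: ",
         paste(rxn$species[is.na(gf)], collapse = ", "), call. = FALSE)
  }
  sum(rxn$coef * gf)
}

#' @noRd
dg0_at_temperature <- function(rxn, table, temperature_k,
                               temperature_model = c("isothermal",
                                                     "gibbs_helmholtz")) {
  temperature_model <- match.arg(temperature_model)
  dg0 <- delta_g_standard(rxn, table)
  if (temperature_model == "isothermal" || nrow(rxn) == 0 ||
      temperature_k == .T_STD) {
    return(dg0)
  }
  hf <- vapply(rxn$species, function(id) species_row(table, id)$dHf0_kJ_mol,
               numeric(1))
  if (anyNA(hf)) {
    stop("gibbs_helmholtz model needs dHf0 for species: ",
         paste(rxn$species[is.na(hf)], collapse = ", "), call. = FALSE)
  }
  dh0 <- sum(rxn$coef * hf)
  dh0 - temperature_k / .T_STD * (dh0 - dg0)
}

#' pH-transformed standard Gibbs energy
#'
#' The standard value corrected for a fixed proton activity of `10^-pH`
#' (all other species remain at standard state):
#' `dG0' = dG0 + nu_net(H+) * R * T * ln(10^-pH)`. At pH 0 this equals
#' [delta_g_standard()].
#'
#' @inheritParams delta_g_standard
#' @param ph pH at which protons are buffered (Table-2 convention: 7).
#' @param temperature_k Temperature used in the `R*T` factor, kelvin.
#' @param temperature_model `"isothermal"` keeps dG0 at its 298.15 K
#'   value; `"gibbs_helmholtz"` extrapolates it via shipped dHf0 values.
#' @return kJ per reaction as written.
#' @export
delta_g_prime <- function(rxn, table = default_species_table(), ph = 7,
                          temperature_k = 298.15,
                          temperature_model = "isothermal") {
  dg0 <- dg0_at_temperature(rxn, table, temperature_k, temperature_model)
  nu_h <- if ("h_plus" %in% rxn$species) {
    rxn$coef[rxn$species == "h_plus"]
  } else 0
  dg0 + nu_h * .R_kJ * temperature_k * log(10^(-ph))
}

#' In-situ Gibbs energy under stated conditions
#'
#' `dG = dG0(T) + R * T * sum_i nu_i * ln(a_i)`, with proton activity
#' `10^-pH`, user-supplied activities for gases and solutes, and activity
#' 1 for everything unlisted (pure liquids, solids, water). Hydrostatic
#' pressure is not corrected for (deep-sea overpressure is ignored; the
#' returned object notes this in [energy_report()] metadata).
#'
#' @inheritParams delta_g_prime
#' @param cond An [conditions()] object.
#' @return kJ per reaction as written.
#' @export
delta_g_insitu <- function(rxn, table = default_species_table(),
                           cond = conditions(),
                           temperature_model = "isothermal") {
  stopifnot(inherits(cond, "alk_conditions"))
  tk <- cond$temperature_k
  dg0 <- dg0_at_temperature(rxn, table, tk, temperature_model)
  if (nrow(rxn) == 0) return(dg0)
  act <- vapply(rxn$species, function(id) {
    if (id == "h_plus") return(10^(-cond$ph))
    if (id %in% names(cond$activities)) return(cond$activities[[id]])
    1
  }, numeric(1))
  if (any(act <= 0)) stop("activities must be > 0", call. = FALSE)
  dg0 + .R_kJ * tk * sum(rxn$coef * log(act))
}

#' Energy report for an alkane degradation fate
#'
#' Builds the balanced reaction for the fate, evaluates dG0, dG0' and
#' (when conditions are supplied) the in-situ dG, and normalizes per mol
#' alkane and per mol electrons transferred. For the methanogenic fate
#' the electron count is the ledger's `12n + 8` released electrons per
#' 4-alkane reaction; for the other fates it is 2 x (H2 produced), the
#' electrons captured in H2.
#'
#' @inheritParams balance_alkane
#' @param cond Optional [conditions()]; when `NULL` only standard and
#'   pH-transformed values are reported.
#' @param table Species table (extended with the n-alkane if absent).
#' @param ph pH for the transformed value (default 7).
#' @param temperature_k Temperature for the transformed value, kelvin.
#' @param temperature_model See [delta_g_prime()].
#' @return Object of class `alk_energy`; see [glance.alk_energy()] for the
#'   one-row summary and [tidy.alk_energy()] for per-species
#'   contributions.
#' @examples
#' glance(energy_report(16, "methanogenic"))
#' @export
energy_report <- function(n, fate = alkane_fates(), cond = NULL,
                          table = default_species_table(), ph = 7,
                          temperature_k = 298.15,
                          temperature_model = "isothermal", ...) {
  n <- check_chain_length(n)
  fate <- match.arg(fate)
  if (fate %in% c("oxidation_half", "methyl_reduction_half",
                  "co2_reduction_half")) {
    stop("fate '", fate, "' carries uncancelled carrier species; ",
         "energy evaluation is not applicable (sum the half-steps with ",
         "compose_half_steps() instead)", call. = FALSE)
  }
  table <- with_alkane(table, n)
  rxn <- balance_alkane(n, fate, ...)
  alk_coef <- if (fate == "methanogenic") 4 else
    abs(reaction_coefs(rxn)[[alkane_id(n)]])
  electrons <- if (fate == "methanogenic") {
    electron_ledger(n)$e_released
  } else {
    # electrons captured in the H2 produced, whatever H2 species id is used
    is_h2 <- vapply(rxn$species, function(id) {
      identical(species_composition(table, id), c(H = 2L)) &&
        species_row(table, id)$charge == 0
    }, logical(1))
    2 * sum(rxn$coef[is_h2 & rxn$coef > 0])
  }
  dg0 <- delta_g_standard(rxn, table)
  dg0p <- delta_g_prime(rxn, table, ph = ph, temperature_k = temperature_k,
                        temperature_model = temperature_model)
  dgis <- if (!is.null(cond)) {
    delta_g_insitu(rxn, table, cond, temperature_model = temperature_model)
  } else NA_real_
  effective <- if (!is.null(cond)) dgis else dg0p
  structure(list(
    n = n, fate = fate, reaction = rxn, table = table,
    alkane_coef = alk_coef, electrons = electrons,
    ph = if (!is.null(cond)) cond$ph else ph,
    temperature_k = if (!is.null(cond)) cond$temperature_k else temperature_k,
    dG0_kJ = dg0, dG0_prime_kJ = dg0p, dG_insitu_kJ = dgis,
    per_mol_alkane_kJ = effective / alk_coef,
    per_electron_kJ = effective / electrons,
    pressure_corrected = FALSE
  ), class = "alk_energy")
}

#' @export
print.alk_energy <- function(x, ...) {
  cat(sprintf("<energy report> %s, n=%d\n", x$fate, x$n))
  cat(" ", as_equation(x$reaction, table = x$table), "\n")
  cat(sprintf("  dG0      = %10.1f kJ/reaction\n", x$dG0_kJ))
  cat(sprintf("  dG0' pH%g = %9.1f kJ/reaction\n", x$ph, x$dG0_prime_kJ))
  if (!is.na(x$dG_insitu_kJ)) {
    cat(sprintf("  dG in-situ = %8.1f kJ/reaction (T=%.1f K)\n",
                x$dG_insitu_kJ, x$temperature_k))
  }
  cat(sprintf("  per mol alkane = %.1f kJ; per mol e- = %.2f kJ\n",
              x$per_mol_alkane_kJ, x$per_electron_kJ))
  invisible(x)
}

#' One-row summary of an energy report
#'
#' @param x An `alk_energy` object from [energy_report()].
#' @param ... Unused.
#' @return One-row tibble with the fate, normalization metadata and all
#'   Gibbs-energy values (kJ).
#' @method glance alk_energy
#' @export
glance.alk_energy <- function(x, ...) {
  tibble::tibble(
    n = x$n, fate = x$fate, alkane_coef = x$alkane_coef,
    electrons = x$electrons, ph = x$ph, temperature_k = x$temperature_k,
    dG0_kJ = x$dG0_kJ, dG0_prime_kJ = x$dG0_prime_kJ,
    dG_insitu_kJ = x$dG_insitu_kJ,
    per_mol_alkane_kJ = x$per_mol_alkane_kJ,
    per_electron_kJ = x$per_electron_kJ,
    pressure_corrected = x$pressure_corrected
  )
}

#' Per-species formation-energy contributions of an energy report
#'
#' @param x An `alk_energy` object.
#' @param ... Unused.
#' @return Tibble with one row per species: coefficient, formation
#'   energy, and its `coef * dGf0` contribution to dG0.
#' @method tidy alk_energy
#' @export
tidy.alk_energy <- function(x, ...) {
  rxn <- x$reaction
  gf <- vapply(rxn$species, function(id) {
    species_row(x$table, id)$dGf0_kJ_mol
  }, numeric(1))
  tibble::tibble(species = rxn$species, coef = rxn$coef,
                 dGf0_kJ_mol = unname(gf),
                 contribution_kJ = rxn$coef * unname(gf))
}

#' Formation energy of a liquid n-alkane
#'
#' Returns the tabulated value when the species table carries the alkane;
#' otherwise predicts from the linear group-additivity fit
#' `dGf0(n) = a + b * n` (least squares over the shipped liquid n-alkane
#' rows, n >= 5). On the shipped table the fitted slope b is positive:
#' formation energy grows roughly +5.4 kJ/mol per CH2 group.
#'
#' @param n Chain length, integer >= 1.
#' @param table Species table.
#' @return dGf0 in kJ/mol.
#' @export
alkane_gf_estimate <- function(n, table = default_species_table()) {
  n <- check_chain_length(n)
  id <- alkane_id(n)
  if (id %in% table$id) {
    v <- species_row(table, id)$dGf0_kJ_mol
    if (!is.na(v)) return(v)
  }
  if (n < 5) {
    stop("no tabulated value for the C", n, " alkane and the linear fit ",
         "applies only to the liquid regime (n >= 5)", call. = FALSE)
  }
  fit <- alkane_gf_fit(table)
  unname(fit[1] + fit[2] * n)
}

#' @noRd
alkane_gf_fit <- function(table) {
  liq <- table[table$phase == "liquid" & !is.na(table$dGf0_kJ_mol) &
                 grepl("^c[0-9]+h[0-9]+$", table$id), ]
  ns <- as.integer(sub("^c([0-9]+)h.*$", "\\1", liq$id))
  keep <- ns >= 5 & liq$formula == vapply(ns, function(k) {
    write_formula(c(C = as.integer(k), H = as.integer(2 * k + 2)))
  }, character(1))
  liq <- liq[keep, ]; ns <- ns[keep]
  if (nrow(liq) < 2) stop("species table lacks liquid n-alkane rows to fit",
                          call. = FALSE)
  stats::coef(stats::lm(liq$dGf0_kJ_mol ~ ns))
}

#' Gibbs-energy scan over alkane chain length
#'
#' One [energy_report()] per chain length, collected into a tibble. On
#' the shipped table the per-mol-alkane dG0' of the methanogenic fate is
#' strictly decreasing (more exergonic) with chain length.
#'
#' @param n_min,n_max Chain-length range (1-40).
#' @param fate One of [alkane_fates()] (overall fates only).
#' @param cond Optional [conditions()].
#' @inheritParams energy_report
#' @return Tibble of class `alk_chain_scan`, one row per n, with the
#'   [glance.alk_energy()] columns.
#' @examples
#' chain_scan(6, 20, "methanogenic")
#' @export
chain_scan <- function(n_min, n_max, fate = "methanogenic", cond = NULL,
                       table = default_species_table(), ph = 7,
                       temperature_k = 298.15, ...) {
  n_min <- check_chain_length(n_min); n_max <- check_chain_length(n_max)
  if (n_min > n_max || n_max > 40) {
    stop("need 1 <= n_min <= n_max <= 40", call. = FALSE)
  }
  rows <- purrr::map_dfr(seq(n_min, n_max), function(k) {
    glance(energy_report(k, fate, cond = cond, table = table, ph = ph,
                         temperature_k = temperature_k, ...))
  })
  structure(rows, class = c("alk_chain_scan", class(rows)))
}
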