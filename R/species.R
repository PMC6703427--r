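#' Construct a chemical species record
#'
#' A species is a chemical entity with an elemental composition, a charge,
#' a phase and (optionally) standard formation energetics at 298.15 K.
#' Phases follow the bioenergetics convention: `gas` (standard state
#' 1 bar), `aqueous` (1 M), `liquid` / `solid` (pure phase, activity 1),
#' and `carrier` for bookkeeping species such as the H4MPT methyl carrier
#' and the formal electron, which cancel in any energy-evaluable reaction.
#'
#' @param id Unique token identifying the species within a table.
#' @param name Human-readable name.
#' @param formula Molecular formula string (see [parse_formula()]); the
#'   empty string is permitted only for the formal electron.
#' @param charge Signed integer charge in elementary units.
#' @param phase One of `"gas"`, `"liquid"`, `"aqueous"`, `"solid"`,
#'   `"carrier"`.
#' @param dGf0 Standard Gibbs energy of formation at 298.15 K, kJ/mol
#'   (`NA` allowed for carrier species only).
#' @param dHf0 Optional standard enthalpy of formation, kJ/mol.
#' @param source Free-text provenance.
#' @return A one-row tibble in species-table form.
#' @export
species <- function(id, name = id, formula = "", charge = 0L,
                    phase = c("aqueous", "gas", "liquid", "solid", "carrier"),
                    dGf0 = NA_real_, dHf0 = NA_real_, source = "") {
  phase <- match.arg(phase)
  charge <- as.integer(charge)
  if (!nzchar(formula)) {
    if (!(charge == -1L && phase == "carrier")) {
      stop("empty composition is reserved for the formal electron ",
           "(charge -1, phase 'carrier')", call. = FALSE)
    }
  } else {
    parse_formula(formula) # validates
  }
  tibble::tibble(id = id, name = name, formula = formula,
                 charge = charge, phase = phase,
                 dGf0_kJ_mol = as.numeric(dGf0),
                 dHf0_kJ_mol = as.numeric(dHf0), source = source)
}

#' Read a species table
#'
#' Reads a TSV species table with columns `id`, `name`, `formula`,
#' `charge`, `phase`, `dGf0_kJ_mol`, `dHf0_kJ_mol`, `source`. Lines
#' starting with `#` are comments. Ids must be unique.
#'
#' @param path Path to the TSV file.
#' @return Tibble with one row per species.
#' @seealso [default_species_table()] for the table shipped with the
#'   package.
#' @export
read_species_table <- function(path) {
  tab <- readr::read_tsv(path, comment = "#", col_types = readr::cols(
    id = readr::col_character(), name = readr::col_character(),
    formula = readr::col_character(), charge = readr::col_integer(),
    phase = readr::col_character(), dGf0_kJ_mol = readr::col_double(),
    dHf0_kJ_mol = readr::col_double(), source = readr::col_character()
  ), progress = FALSE)
  tab$formula[is.na(tab$formula)] <- ""
  if (anyDuplicated(tab$id)) {
    stop("duplicate species ids in table: ",
         paste(unique(tab$id[duplicated(tab$id)]), collapse = ", "),
         call. = FALSE)
  }
  bad_phase <- setdiff(unique(tab$phase),
                       c("gas", "liquid", "aqueous", "solid", "carrier"))
  if (length(bad_phase)) {
    stop("unknown phase value(s): ", paste(bad_phase, collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_len(nrow(tab))) {
    if (nzchar(tab$formula[i])) parse_formula(tab$formula[i])
  }
  tab
}

#' The shipped standard formation-energy table
#'
#' Standard Gibbs energies of formation at 298.15 K for the species needed
#' to evaluate the alkane degradation fates: water, proton, methane and
#' CO2 in both gaseous and dissolved standard states, dihydrogen, acetate,
#' the carrier pair, and n-alkanes up to C20 (gas-phase values for C1-C4,
#' liquid-phase for C5 and longer). Values follow the classic anaerobic
#' bioenergetics compilations (Thauer-style small-molecule values; CRC
#' liquid n-alkane values extended by group additivity at +5.4 kJ/mol per
#' CH2). See the `source` column for per-row provenance.
#'
#' @param path Optional path to an alternative table.
#' @return Tibble with one row per species.
#' @export
default_species_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "species_gf0.tsv", package = "alkanogen",
                        mustWork = TRUE)
  }
  read_species_table(path)
}

#' @noRd
species_row <- function(table, id) {
  i <- match(id, table$id)
  if (is.na(i)) stop("species '", id, "' not found in species table",
                     call. = FALSE)
  table[i, ]
}

#' @noRd
species_composition <- function(table, id) {
  f <- species_row(table, id)$formula
  if (!nzchar(f)) integer(0) else parse_formula(f)
}

#' Species id of the n-alkane substrate
#'
#' C1-C4 alkanes are gases at 298 K and carry gas-phase ids; pentane and
#' longer are treated as pure liquids (the oil phase).
#'
#' @param n Chain length (number of carbon atoms), integer >= 1.
#' @return Species id string, e.g. `"c16h34"`.
#' @export
alkane_id <- function(n) {
  check_chain_length(n)
  if (n == 1) return("ch4_g")
  sprintf("c%dh%d", n, 2 * n + 2)
}

#' @noRd
check_chain_length <- function(n) {
  if (length(n) != 1 || is.na(n) || !is.numeric(n) || n < 1 ||
      n != as.integer(n)) {
    stop("chain length n must be a single integer >= 1", call. = FALSE)
  }
  invisible(as.integer(n))
}

#' Ensure the species table contains the n-alkane
#'
#' Appends an alkane species row when absent, with its formation energy
#' from [alkane_gf_estimate()].
#'
#' @inheritParams alkane_id
#' @param table Species table tibble.
#' @return The (possibly extended) species table.
#' @export
with_alkane <- function(table, n) {
  check_chain_length(n)
  id <- alkane_id(n)
  if (id %in% table$id) return(table)
  est <- alkane_gf_estimate(n, table = table)
  dplyr::bind_rows(table, species(
    id = id, name = sprintf("n-alkane C%d", n),
    formula = write_formula(c(C = as.integer(n), H = as.integer(2 * n + 2))),
    charge = 0L, phase = if (n <= 4) "gas" else "liquid",
    dGf0 = est, source = "linear group-additivity fit over shipped liquid n-alkanes"
  ))
}
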