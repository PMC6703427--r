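#' Electron ledger of the alkane disproportionation pathway
#'
#' Per four alkane molecules (the conventional basis of the pathway
#' model), the oxidation of 4 CnH2n+2 to 2n H4MPT-bound methyl groups and
#' 2n CO2 releases `12n + 8` electrons. Of these, `4n` are used to reduce
#' the methyl groups to methane (the energy-conserving Mtr/MCR step) and
#' the remaining `8n + 8` reduce `n + 1` CO2 to methane as the electron
#' sink. For hexadecane (n = 16) this is the familiar bookkeeping: 200
#' electrons released, 64 to methyl reduction, 136 to CO2 reduction, 32
#' methyl groups, 17 CH4 from CO2 reduction, and 49 CH4 in total.
#'
#' The ledger is defined for the methanogenic (disproportionation) fate
#' only; electron accounting for the other fates is reported by
#' [energy_report()] as 2 x (H2 produced).
#'
#' @param n Alkane chain length, integer >= 1.
#' @return One-row tibble of class `electron_ledger` with columns `n`,
#'   `basis` (always 4), `e_released`, `e_to_methyl_reduction`,
#'   `e_to_co2_reduction`, `methyl_groups`, `ch4_from_methyl`,
#'   `ch4_from_co2_reduction`, `ch4_total`, `co2_net`.
#' @examples
#' electron_ledger(16)
#' @export
electron_ledger <- function(n) {
  n <- check_chain_length(n)
  out <- tibble::tibble(
    n = n,
    basis = 4L,
    e_released = 12L * n + 8L,
    e_to_methyl_reduction = 4L * n,
    e_to_co2_reduction = 8L * n + 8L,
    methyl_groups = 2L * n,
    ch4_from_methyl = 2L * n,
    ch4_from_co2_reduction = n + 1L,
    ch4_total = 3L * n + 1L,
    co2_net = n - 1L
  )
  stopifnot(out$e_released ==
              out$e_to_methyl_reduction + out$e_to_co2_reduction,
            out$ch4_from_methyl + out$ch4_from_co2_reduction == out$ch4_total)
  structure(out, class = c("electron_ledger", class(out)))
}
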