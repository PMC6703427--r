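# shared fixtures: the shipped table is read once per test run
tab <- alkanogen::default_species_table()

coef_map <- function(rxn) {
  stats::setNames(rxn$coef, rxn$species)
}

expect_same_reaction <- function(a, b) {
  ca <- coef_map(a); cb <- coef_map(b)
  ids <- union(names(ca), names(cb))
  get0 <- function(v, id) if (id %in% names(v)) v[[id]] else 0
  for (id in ids) {
    expect_identical(get0(ca, id), get0(cb, id),
                     label = paste("coefficient of", id))
  }
  invisible(TRUE)
}

expect_coefs <- function(rxn, expected) {
  expect_same_reaction(rxn, alkanogen::reaction(expected))
}
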