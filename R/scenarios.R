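#' Scenario specification for the synthetic condition generator
#'
#' Defines the sampled ranges, sampling design and size of a set of
#' synthetic environmental conditions. The default ranges (shipped in
#' `extdata/scenario_ranges.yaml`) emulate the cold, sulfate-depleted,
#' oil-rich deep-sea seep sediment the package's feasibility questions
#' are posed for: T 275-298 K, pH 6.5-8.5, p(CH4) and dissolved-CO2
#' activity each 10^-3 to 1 (sampled uniformly in log10 space), alkane
#' fixed as a pure oil phase (activity 1).
#'
#' @param ranges List with entries `temperature_k`, `ph` (each
#'   `list(min, max)`) and `activities` (named list of
#'   `list(min, max, log10)`); defaults to the shipped file.
#' @param design Sampling design: `"lhs"` (latin hypercube), `"random"`
#'   (uniform), or `"grid"` (full factorial over `n_levels` per free
#'   axis).
#' @param n_scenarios Number of scenarios for `lhs`/`random`.
#' @param n_levels Levels per free axis for the `grid` design.
#' @param seed Integer seed; scenario generation is bit-reproducible
#'   given `(spec, seed)` via R's default Mersenne-Twister generator.
#' @return List of class `alk_scenario_spec`.
#' @export
scenario_spec <- function(ranges = default_scenario_ranges(),
                          design = c("lhs", "random", "grid"),
                          n_scenarios = 1000, n_levels = 3, seed = 1) {
  design <- match.arg(design)
  if (n_scenarios < 1) stop("n_scenarios must be >= 1", call. = FALSE)
  if (design == "grid" && n_levels < 1) {
    stop("n_levels must be >= 1", call. = FALSE)
  }
  check_range <- function(r, what) {
    if (is.null(r$min) || is.null(r$max) || r$min > r$max) {
      stop("invalid range for ", what, ": need min <= max", call. = FALSE)
    }
  }
  check_range(ranges$temperature_k, "temperature_k")
  check_range(ranges$ph, "ph")
  for (id in names(ranges$activities)) {
    check_range(ranges$activities[[id]], paste0("activities.", id))
    if (ranges$activities[[id]]$min <= 0) {
      stop("activity range for ", id, " must be > 0", call. = FALSE)
    }
  }
  structure(list(ranges = ranges, design = design,
                 n_scenarios = as.integer(n_scenarios),
                 n_levels = as.integer(n_levels), seed = as.integer(seed)),
            class = "alk_scenario_spec")
}

#' @rdname scenario_spec
#' @param path Optional alternative ranges file (same YAML layout).
#' @export
default_scenario_ranges <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "scenario_ranges.yaml",
                        package = "alkanogen", mustWork = TRUE)
  }
  yaml::read_yaml(path)
}

#' Generate synthetic environmental condition sets
#'
#' Samples the scenario specification's axes with the chosen design. Axes whose range is
#' degenerate (min == max) are held constant; for the grid design only
#' free axes contribute levels (3 levels over 4 free axes gives 81
#' scenarios). Activity axes flagged `log10` are sampled uniformly in
#' log10 space.
#'
#' @param spec An [scenario_spec()].
#' @return Tibble with columns `scenario`, `temperature_k`, `ph` and one
#'   activity column per species id in the ranges; attribute `spec`
#'   records the generator settings and seed.
#' @examples
#' generate_scenarios(scenario_spec(n_scenarios = 5, seed = 42))
#' @export
generate_scenarios <- function(spec) {
  stopifnot(inherits(spec, "alk_scenario_spec"))
  r <- spec$ranges
  axes <- c(list(temperature_k = c(r$temperature_k$min, r$temperature_k$max,
                                   FALSE),
                 ph = c(r$ph$min, r$ph$max, FALSE)),
            stats::setNames(lapply(r$activities, function(a) {
              lg <- isTRUE(a$log10)
              if (lg) c(log10(a$min), log10(a$max), TRUE)
              else c(a$min, a$max, FALSE)
            }), names(r$activities)))
  lo <- vapply(axes, `[`, numeric(1), 1)
  hi <- vapply(axes, `[`, numeric(1), 2)
  is_log <- vapply(axes, `[`, numeric(1), 3) == 1
  free <- hi > lo
  k <- length(axes)
  u <- switch(spec$design,
    lhs = {
      set.seed(spec$seed)
      if (any(free)) {
        m <- matrix(0.5, spec$n_scenarios, k)
        m[, free] <- lhs::randomLHS(spec$n_scenarios, sum(free))
        m
      } else matrix(0.5, spec$n_scenarios, k)
    },
    random = {
      set.seed(spec$seed)
      matrix(stats::runif(spec$n_scenarios * k), ncol = k)
    },
    grid = {
      lv <- function(f) if (f && spec$n_levels > 1) {
        seq(0, 1, length.out = spec$n_levels)
      } else 0.5
      as.matrix(expand.grid(lapply(free, lv)))
    }
  )
  vals <- sapply(seq_len(k), function(j) {
    x <- lo[j] + u[, j] * (hi[j] - lo[j])
    if (is_log[j]) 10^x else x
  })
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1)
  colnames(vals) <- names(axes)
  out <- tibble::as_tibble(as.data.frame(vals))
  out <- dplyr::bind_cols(tibble::tibble(scenario = seq_len(nrow(out))), out)
  structure(out, spec = spec, class = c("alk_scenarios", class(out)))
}

#' Thermodynamic feasibility screen over scenarios
#'
#' Evaluates the in-situ Gibbs energy of a fate's reaction under every
#' scenario and summarizes how often it is exergonic (dG < threshold,
#' strict). The default threshold 0 follows the sign-only feasibility
#' argument; a "biological energy quantum" offset (e.g. -20 kJ/mol
#' alkane) can be supplied to ask for physiologically useful energy
#' instead.
#'
#' @inheritParams energy_report
#' @param scenarios Tibble from [generate_scenarios()] (or any tibble
#'   with `temperature_k`, `ph` and activity columns named by species
#'   id).
#' @param threshold_kJ Exergonicity threshold on the per-mol-alkane
#'   value, default 0.
#' @return One-row tibble of class `feasibility_summary`:
#'   `n_scenarios`, `n_exergonic`, `fraction_exergonic`, min / median /
#'   max per-mol-alkane dG, and the threshold. The per-scenario values
#'   are attached as attribute `details` and returned by `tidy()`.
#' @examples
#' sc <- generate_scenarios(scenario_spec(n_scenarios = 50, seed = 42))
#' feasibility_screen(16, "methanogenic", sc)
#' @export
feasibility_screen <- function(n, fate = "methanogenic", scenarios,
                               table = default_species_table(),
                               threshold_kJ = 0, ...) {
  n <- check_chain_length(n)
  if (nrow(scenarios) == 0) stop("empty scenario list", call. = FALSE)
  table <- with_alkane(table, n)
  rxn <- balance_alkane(n, fate, ...)
  alk_coef <- abs(reaction_coefs(rxn)[alkane_id(n)])
  if (is.na(alk_coef)) alk_coef <- if (fate == "methanogenic") 4 else 1
  act_cols <- setdiff(names(scenarios), c("scenario", "temperature_k", "ph"))
  dg <- vapply(seq_len(nrow(scenarios)), function(i) {
    row <- scenarios[i, ]
    cond <- conditions(temperature_k = row$temperature_k, ph = row$ph,
                       activities = unlist(row[act_cols]))
    delta_g_insitu(rxn, table, cond) / alk_coef
  }, numeric(1))
  details <- dplyr::bind_cols(scenarios,
                              tibble::tibble(dG_per_mol_alkane_kJ = dg,
                                             exergonic = dg < threshold_kJ))
  out <- tibble::tibble(
    n = n, fate = fate,
    n_scenarios = nrow(scenarios),
    n_exergonic = sum(dg < threshold_kJ),
    fraction_exergonic = mean(dg < threshold_kJ),
    dG_min_kJ = min(dg), dG_median_kJ = stats::median(dg),
    dG_max_kJ = max(dg), threshold_kJ = threshold_kJ
  )
  structure(out, details = details,
            class = c("feasibility_summary", class(out)))
}

#' Per-scenario results of a feasibility screen
#'
#' @param x A `feasibility_summary`.
#' @param ... Unused.
#' @return Tibble with one row per scenario: the conditions, the
#'   per-mol-alkane in-situ dG, and the exergonicity flag.
#' @method tidy feasibility_summary
#' @export
tidy.feasibility_summary <- function(x, ...) attr(x, "details")

#' @rdname tidy.feasibility_summary
#' @return For `glance()`, the one-row summary as a plain tibble.
#' @method glance feasibility_summary
#' @export
glance.feasibility_summary <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x))
}
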