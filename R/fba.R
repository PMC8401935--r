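#' Flux balance analysis
#'
#' Solves the steady-state LP: optimise the model's objective reaction
#' subject to `S v = 0` and the flux bounds. Uptake follows the standard
#' sign convention: a negative exchange flux imports the metabolite.
#'
#' @param model a `metabolic_model`.
#' @param tol solver feasibility tolerance.
#' @return a `flux_solution`: list with `status` ("optimal", "infeasible"
#'   or "unbounded"), `objective_value` and `fluxes` (named vector; `NULL`
#'   unless optimal).
#' @export
fba <- function(model, tol = 1e-9) {
  S <- stoich_matrix(model)
  rx <- model$reactions
  obj <- as.numeric(rx$id == model$objective$reaction)
  res <- solve_lp(obj, S, lb = rx$lower_bound, ub = rx$upper_bound,
                  maximize = model$objective$direction == "maximize",
                  tol = tol)
  sol <- list(status = res$status,
              objective_value = res$objective,
              fluxes = NULL)
  if (res$status == "optimal") {
    sol$fluxes <- stats::setNames(res$x, rx$id)
  }
  structure(sol, class = "flux_solution")
}

#' @exportS3Method base::print
print.flux_solution <- function(x, ...) {
  cat("<flux_solution> status:", x$status,
      " objective:", format(x$objective_value), "\n")
  invisible(x)
}

#' Flux variability analysis
#'
#' For each requested reaction, computes the minimum and maximum flux
#' attainable while the objective is held at (at least) a fraction of its
#' optimum. With `fraction_of_optimum = 1` (the default) the objective is
#' pinned to its optimal value within a small relative slack, so the
#' ranges describe the degeneracy of the optimal flux distribution --
#' the regime used to call core reactions.
#'
#' @param model a `metabolic_model`.
#' @param reactions reaction ids to scan (default: all).
#' @param fraction_of_optimum fraction in `[0, 1]` of the objective
#'   optimum to impose while scanning.
#' @param tol solver tolerance; also the relative slack used when pinning
#'   the objective at its optimum.
#' @return data.frame with columns `reaction_id`, `fmin`, `fmax`.
#' @export
fva <- function(model, reactions = model$reactions$id,
                fraction_of_optimum = 1.0, tol = 1e-9) {
  stopifnot(fraction_of_optimum >= 0, fraction_of_optimum <= 1)
  missing <- setdiff(reactions, model$reactions$id)
  if (length(missing)) {
    stop("unknown reaction(s): ", paste(missing, collapse = ", "))
  }
  base <- fba(model, tol = tol)
  if (base$status != "optimal") {
    stop("FVA requires a feasible, bounded model (FBA status: ", base$status, ")")
  }
  opt <- base$objective_value
  maximize <- model$objective$direction == "maximize"
  ## impose the objective as a bound; at fraction 1 this is an
  ## equality-within-tolerance pin of the optimum
  slack <- max(abs(opt), 1) * 1e-7
  floor_val <- fraction_of_optimum * opt
  obj_id <- model$objective$reaction
  if (maximize) {
    model <- set_bounds(model, obj_id,
                        lower_bound = if (fraction_of_optimum == 1) opt - slack else floor_val)
  } else {
    model <- set_bounds(model, obj_id,
                        upper_bound = if (fraction_of_optimum == 1) opt + slack else floor_val)
  }
  S <- stoich_matrix(model)
  rx <- model$reactions
  out <- data.frame(reaction_id = reactions,
                    fmin = NA_real_, fmax = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_along(reactions)) {
    obj <- as.numeric(rx$id == reactions[k])
    lo <- solve_lp(obj, S, lb = rx$lower_bound, ub = rx$upper_bound,
                   maximize = FALSE, tol = tol)
    hi <- solve_lp(obj, S, lb = rx$lower_bound, ub = rx$upper_bound,
                   maximize = TRUE, tol = tol)
    if (lo$status != "optimal" || hi$status != "optimal") {
      stop("FVA subproblem not optimal for reaction ", reactions[k],
           " (", lo$status, "/", hi$status, ")")
    }
    out$fmin[k] <- lo$objective
    out$fmax[k] <- hi$objective
  }
  out
}

#' Constrain the growth medium
#'
#' Sets the maximum uptake of the named exchange reactions and closes the
#' uptake of every other organic-carbon exchange, leaving inorganic
#' exchanges (water, protons, phosphate, ammonium, gases, salts) open.
#' Uptake rates are given as positive magnitudes; the exchange lower
#' bound is set to their negative, following the uptake-negative sign
#' convention.
#'
#' Carbon exchanges are recognised by the metabolite's elemental formula
#' when available; metabolites without a formula are treated as organic
#' unless their id (stripped of compartment decoration) matches
#' `inorganic_ids`.
#'
#' @param model a `metabolic_model`.
#' @param medium named numeric vector or list: exchange reaction id ->
#'   maximum uptake (mmol/gCDW/h, positive).
#' @param inorganic_ids base metabolite ids never treated as carbon
#'   sources (see [default_inorganic_ids()]).
#' @return the constrained model.
#' @export
set_medium <- function(model, medium, inorganic_ids = default_inorganic_ids()) {
  medium <- unlist(medium)
  ex <- exchange_reactions(model)
  unknown <- setdiff(names(medium), model$reactions$id)
  if (length(unknown)) {
    stop("medium names unknown reaction(s): ", paste(unknown, collapse = ", "))
  }
  not_ex <- setdiff(names(medium), ex)
  if (length(not_ex)) {
    stop("medium names non-exchange reaction(s): ", paste(not_ex, collapse = ", "))
  }
  for (rid in ex) {
    met_id <- names(model$stoichiometry[[rid]])
    if (rid %in% names(medium)) {
      model <- set_bounds(model, rid, lower_bound = -abs(medium[[rid]]))
    } else if (is_carbon_source(model, met_id, inorganic_ids)) {
      i <- match(rid, model$reactions$id)
      model$reactions$lower_bound[i] <- max(model$reactions$lower_bound[i], 0)
    }
  }
  validate_model(model)
}

#' Default inorganic/base-medium metabolite ids
#'
#' Base ids (compartment decoration stripped) of species kept available
#' when a medium is applied and excluded from carbon-source screens:
#' water, protons, inorganic phosphate, ammonium/nitrate, gases and
#' common salt ions.
#'
#' @return character vector of base metabolite ids.
#' @export
default_inorganic_ids <- function() {
  c("h2o", "h", "pi", "ppi", "nh4", "nh3", "no3", "no2", "o2", "co2",
    "so4", "so3", "fe2", "fe3", "mg2", "k", "na1", "na", "cl", "ca2",
    "mn2", "zn2", "cu2", "cobalt2", "mobd", "ni2")
}

#' Strip compartment decoration from a metabolite id
#'
#' Turns `"glc__D_e"` or `"glc__D[e]"` into `"glc__D"` given compartment
#' `"e"`.
#'
#' @param id metabolite id(s).
#' @param compartment matching compartment id(s).
#' @return base id(s).
#' @export
met_base_id <- function(id, compartment) {
  compartment <- rep_len(compartment, length(id))
  vapply(seq_along(id), function(k) {
    out <- sub(paste0("\\[", compartment[k], "\\]$"), "", id[k])
    if (out != id[k]) out else sub(paste0("_", compartment[k], "$"), "", id[k])
  }, character(1), USE.NAMES = FALSE)
}

is_carbon_source <- function(model, met_id, inorganic_ids) {
  i <- match(met_id, model$metabolites$id)
  base <- met_base_id(met_id, model$metabolites$compartment[i])
  if (tolower(base) %in% inorganic_ids) return(FALSE)
  f <- model$metabolites$formula[i]
  if (!is.na(f) && nzchar(f)) {
    return(grepl("C(?![a-z])", f, perl = TRUE))   # carbon, not Ca/Cl/Co/Cu
  }
  TRUE                                            # unknown formula: treat as organic
}

#' Check steady state of a flux solution
#'
#' Returns the largest absolute mass-balance residual `max |S v|` over
#' metabolites -- zero (within solver tolerance) for any valid FBA/FVA
#' solution.
#'
#' @param model a `metabolic_model`.
#' @param solution a `flux_solution` from [fba()].
#' @return numeric scalar.
#' @export
steady_state_residual <- function(model, solution) {
  stopifnot(solution$status == "optimal")
  S <- stoich_matrix(model)
  v <- solution$fluxes[colnames(S)]
  max(abs(as.numeric(S %*% v)))
}
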