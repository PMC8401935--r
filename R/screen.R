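#' Enumerate transportable compounds
#'
#' Lists the unique extracellular metabolites moved across the boundary
#' by at least one transport reaction -- a reaction involving the same
#' chemical species (same base id) in two different compartments.
#' Coupled transporters (antiporters/symporters) contribute every
#' translocated species. Water, protons and other inorganic species are
#' excluded via the blocklist, as amending them is metabolically
#' meaningless.
#'
#' @param model a `metabolic_model` with an extracellular compartment.
#' @param extracellular compartment id treated as outside (default
#'   "e").
#' @param blocklist base metabolite ids to exclude
#'   (default [default_inorganic_ids()]).
#' @return character vector of extracellular metabolite ids, sorted.
#' @export
transported_compounds <- function(model, extracellular = "e",
                                  blocklist = default_inorganic_ids()) {
  mets <- model$metabolites
  if (!extracellular %in% mets$compartment) {
    stop("model has no compartment '", extracellular, "'")
  }
  base <- stats::setNames(met_base_id(mets$id, mets$compartment), mets$id)
  comp <- stats::setNames(mets$compartment, mets$id)
  out <- character(0)
  for (st in model$stoichiometry) {
    ids <- names(st)
    if (length(ids) < 2) next                      # exchanges are not transports
    b <- base[ids]
    k <- comp[ids]
    for (bb in unique(b[duplicated(b)])) {
      span <- unique(k[b == bb])
      if (length(span) > 1 && extracellular %in% span) {
        out <- c(out, ids[b == bb & k == extracellular])
      }
    }
  }
  out <- unique(out)
  keep <- !(tolower(base[out]) %in% tolower(blocklist))
  sort(out[keep])
}

#' Find the exchange reaction of a metabolite
#'
#' @param model a `metabolic_model`.
#' @param met_id metabolite id.
#' @return the exchange reaction id, or `NA` if none exists.
#' @export
find_exchange <- function(model, met_id) {
  ex <- exchange_reactions(model)
  hit <- ex[vapply(ex, function(r) {
    identical(names(model$stoichiometry[[r]]), met_id)
  }, logical(1))]
  if (length(hit)) hit[1] else NA_character_
}

#' Screen single-compound medium amendments
#'
#' For each candidate compound, opens its exchange to at least the
#' stated uptake rate on top of the baseline medium (a bound that is
#' already wider is left alone, so an amendment only ever relaxes the
#' LP) -- growth constraint and baseline uptakes untouched -- then
#' re-maximises the product flux and records the
#' ratio to the baseline optimum. Compounds lacking an exchange
#' reaction get one auto-created at the boundary (flagged in the
#' result). Since each amendment only relaxes the LP, the product
#' optimum can never decrease.
#'
#' @param model the producing condition model ([build_recomb_model()]):
#'   medium set, growth constrained, product as objective.
#' @param compounds extracellular metabolite ids to test, e.g. from
#'   [transported_compounds()].
#' @param amendment_uptake uptake rate granted to the amended compound,
#'   mmol/gCDW/h (study value 0.5).
#' @param top_k optionally keep only the first `top_k` rows of the
#'   ranking.
#' @param log_base base of the reported log fold change (default 10).
#' @return data.frame sorted by descending fold change (ties broken by
#'   compound id): `compound_id`, `exchange_id`, `exchange_created`,
#'   `baseline_flux`, `amended_flux`, `ratio`, `log_fold_change`.
#' @export
screen_amendments <- function(model, compounds, amendment_uptake = 0.5,
                              top_k = NULL, log_base = 10) {
  base_sol <- fba(model)
  if (base_sol$status != "optimal") {
    stop("baseline producing model not solvable (status: ", base_sol$status, ")")
  }
  baseline <- base_sol$objective_value
  if (!length(compounds)) {
    return(data.frame(compound_id = character(0), exchange_id = character(0),
                      exchange_created = logical(0), baseline_flux = numeric(0),
                      amended_flux = numeric(0), ratio = numeric(0),
                      log_fold_change = numeric(0), stringsAsFactors = FALSE))
  }
  rows <- lapply(compounds, function(cmp) {
    if (!cmp %in% model$metabolites$id) {
      stop("compound not in model: ", cmp)
    }
    ex <- find_exchange(model, cmp)
    created <- is.na(ex)
    m <- model
    if (created) {
      ex <- paste0("EX_", cmp)
      m <- add_reaction(m, ex, stats::setNames(-1, cmp),
                        lower_bound = 0, upper_bound = 1000,
                        name = paste("Exchange of", cmp), subsystem = "Exchange")
      message("no exchange for ", cmp, "; created ", ex, " at the boundary")
    }
    cur <- m$reactions$lower_bound[match(ex, m$reactions$id)]
    m <- set_bounds(m, ex, lower_bound = min(cur, -abs(amendment_uptake)))
    sol <- fba(m)
    amended <- if (sol$status == "optimal") sol$objective_value else NA_real_
    data.frame(compound_id = cmp, exchange_id = ex,
               exchange_created = created,
               baseline_flux = baseline, amended_flux = amended,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$ratio <- out$amended_flux / out$baseline_flux
  out$log_fold_change <- log(out$ratio, base = log_base)
  out <- out[order(-out$ratio, out$compound_id), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(top_k)) out <- utils::head(out, top_k)
  out
}

#' Flux shift induced by a medium amendment
#'
#' Compares the producing model grown on the amended medium against the
#' unamended one, using the FVA core filter: only reactions whose flux
#' range stays within the core window in both conditions are
#' considered, and those with increased flux under the amendment are
#' reported.
#'
#' @param model the producing condition model.
#' @param compound extracellular metabolite id to amend.
#' @param amendment_uptake uptake granted to the compound.
#' @param crit a `core_criterion`.
#' @return a `flux_comparison` (condition a = unamended, b = amended).
#' @export
amendment_flux_shift <- function(model, compound, amendment_uptake = 0.5,
                                 crit = core_criterion()) {
  ex <- find_exchange(model, compound)
  m2 <- model
  if (is.na(ex)) {
    ex <- paste0("EX_", compound)
    m2 <- add_reaction(m2, ex, stats::setNames(-1, compound),
                       lower_bound = 0, upper_bound = 1000,
                       name = paste("Exchange of", compound),
                       subsystem = "Exchange")
    model <- add_reaction(model, ex, stats::setNames(-1, compound),
                          lower_bound = 0, upper_bound = 0,
                          name = paste("Exchange of", compound),
                          subsystem = "Exchange")
  }
  cur <- m2$reactions$lower_bound[match(ex, m2$reactions$id)]
  m2 <- set_bounds(m2, ex, lower_bound = min(cur, -abs(amendment_uptake)))
  cmp_a <- list(solution = fba(model), ranges = fva(model))
  cmp_b <- list(solution = fba(m2), ranges = fva(m2))
  increased_flux_reactions(cmp_a, cmp_b, crit, model = model)
}
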