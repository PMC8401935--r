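#' FSEOF scan configuration
#'
#' @param n_steps number of enforced-flux steps (study value 100).
#' @param max_ratio highest enforced fraction of the maximal product
#'   flux, in `(0, 1]` (study value 0.9).
#' @param tol monotonicity tolerance on flux profiles.
#' @return object of class `fseof_config`.
#' @export
fseof_config <- function(n_steps = 100L, max_ratio = 0.9, tol = 1e-6) {
  if (n_steps < 2) stop("n_steps must be at least 2")
  if (max_ratio <= 0 || max_ratio > 1) stop("max_ratio must lie in (0, 1]")
  structure(list(n_steps = as.integer(n_steps), max_ratio = max_ratio,
                 tol = tol), class = "fseof_config")
}

#' Flux scanning with enforced objective flux (FSEOF)
#'
#' Identifies overexpression candidates for a target product: the
#' maximal product flux under the current constraints is computed, then
#' the product flux is enforced (as a rising lower bound) in `n_steps`
#' increments up to `max_ratio` of that maximum while biomass is
#' re-optimised, and every reaction whose flux magnitude rises in
#' concert with the enforced product flux -- increasing from first to
#' last step, never decreasing beyond tolerance between consecutive
#' steps, never changing sign -- is selected. Candidates are ranked by
#' the least-squares slope of `|flux|` against the enforced flux
#' (ties broken by reaction id). Exchange and non-gene-encoded
#' reactions are dropped by default, as overexpression only makes sense
#' for enzyme-catalysed steps.
#'
#' @param model a `metabolic_model` with medium constraints applied.
#' @param biomass_reaction reaction re-optimised at each step.
#' @param target_reaction product synthesis reaction to enforce.
#' @param cfg an `fseof_config`.
#' @param gene_encoded_only drop reactions without a gene rule
#'   (default `TRUE`).
#' @param include_exchanges keep boundary exchanges (default `FALSE`).
#' @return list with `targets` (data.frame `reaction_id`, `slope`,
#'   `flux_first`, `flux_last`, `subsystem`, `gene_encoded`, sorted by
#'   descending slope), `profiles` (matrix, steps x reactions, all
#'   fluxes at every step) and `enforced` (the enforced flux grid).
#' @export
fseof_scan <- function(model, biomass_reaction, target_reaction,
                       cfg = fseof_config(), gene_encoded_only = TRUE,
                       include_exchanges = FALSE) {
  stopifnot(inherits(cfg, "fseof_config"))
  ids <- model$reactions$id
  stopifnot(biomass_reaction %in% ids, target_reaction %in% ids)

  vmax <- fba(set_objective(model, target_reaction, "maximize"))
  if (vmax$status != "optimal") {
    stop("target maximisation failed (status: ", vmax$status, ")")
  }
  if (vmax$objective_value <= cfg$tol) {
    stop("product not producible: maximal ", target_reaction, " flux is zero")
  }
  enforced <- (seq_len(cfg$n_steps) / cfg$n_steps) *
    cfg$max_ratio * vmax$objective_value

  base <- set_objective(model, biomass_reaction, "maximize")
  profiles <- matrix(NA_real_, nrow = cfg$n_steps, ncol = length(ids),
                     dimnames = list(NULL, ids))
  for (k in seq_len(cfg$n_steps)) {
    mk <- set_bounds(base, target_reaction, lower_bound = enforced[k])
    sol <- fba(mk)
    if (sol$status != "optimal") {
      stop("FSEOF step ", k, " (enforced flux ", format(enforced[k]),
           ") is ", sol$status)
    }
    profiles[k, ] <- sol$fluxes[ids]
  }

  selected <- vapply(ids, function(r) {
    p <- profiles[, r]
    if (abs(p[cfg$n_steps]) <= abs(p[1]) + cfg$tol) return(FALSE)
    if (any(diff(abs(p)) < -cfg$tol)) return(FALSE)
    s <- sign(p[abs(p) > cfg$tol])
    length(unique(s)) <= 1                         # never changes sign
  }, logical(1))
  keep <- ids[selected]
  keep <- setdiff(keep, target_reaction)           # the enforced flux itself
  if (!include_exchanges) keep <- setdiff(keep, exchange_reactions(model))
  if (gene_encoded_only) keep <- keep[gene_encoded(model, keep)]

  slope <- vapply(keep, function(r) {
    stats::cov(abs(profiles[, r]), enforced) / stats::var(enforced)
  }, numeric(1))
  i <- match(keep, model$reactions$id)
  targets <- data.frame(reaction_id = keep,
                        slope = unname(slope),
                        flux_first = abs(profiles[1, keep]),
                        flux_last = abs(profiles[cfg$n_steps, keep]),
                        name = model$reactions$name[i],
                        subsystem = model$reactions$subsystem[i],
                        gene_encoded = gene_encoded(model, keep),
                        stringsAsFactors = FALSE)
  targets <- targets[order(-targets$slope, targets$reaction_id), ,
                     drop = FALSE]
  rownames(targets) <- NULL
  list(targets = targets, profiles = profiles, enforced = enforced)
}

#' Group overexpression targets by pathway
#'
#' Counts targets per subsystem and keeps pathways represented by at
#' least `min_count` reactions, sorted by descending count.
#'
#' @param targets the `targets` data.frame from [fseof_scan()].
#' @param min_count minimum reactions per pathway (default 2).
#' @return data.frame `subsystem`, `n`.
#' @export
group_by_pathway <- function(targets, min_count = 2L) {
  if (NROW(targets) == 0) {
    return(data.frame(subsystem = character(0), n = integer(0)))
  }
  tab <- table(targets$subsystem[!is.na(targets$subsystem)])
  tab <- tab[tab >= min_count]
  out <- data.frame(subsystem = names(tab), n = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n, out$subsystem), , drop = FALSE]
  rownames(out) <- NULL
  out
}
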