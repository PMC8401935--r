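#' Core-reaction criterion
#'
#' A reaction is *core* when it carries flux and its FVA range under the
#' same constraints stays within a window around the FBA flux: for
#' flux v > 0, `fmin > (1 - window) * v` and `fmax < (1 + window) * v`;
#' for v < 0 the mirrored window applies. Core reactions are the ones
#' whose flux value is robust to the degeneracy of the optimum.
#'
#' @param window half-width of the admissible relative window (study
#'   value 0.3, i.e. a 30% band).
#' @param zero_tolerance fluxes below this magnitude count as zero.
#' @return object of class `core_criterion`.
#' @export
core_criterion <- function(window = 0.3, zero_tolerance = 1e-9) {
  if (window <= 0 || window >= 1) stop("window must lie in (0, 1)")
  structure(list(window = window, zero_tolerance = zero_tolerance),
            class = "core_criterion")
}

#' Identify core reactions
#'
#' @param solution a `flux_solution` from [fba()].
#' @param ranges FVA ranges from [fva()] obtained under the same
#'   constraints (data.frame `reaction_id`, `fmin`, `fmax`); must cover
#'   every flux-carrying reaction tested.
#' @param crit a `core_criterion`.
#' @param reactions reaction ids to classify (default: all in the
#'   solution).
#' @return character vector of core reaction ids.
#' @export
core_reactions <- function(solution, ranges, crit = core_criterion(),
                           reactions = names(solution$fluxes)) {
  stopifnot(inherits(crit, "core_criterion"), solution$status == "optimal")
  missing <- setdiff(reactions, ranges$reaction_id)
  carrying <- reactions[abs(solution$fluxes[reactions]) > crit$zero_tolerance]
  missing_needed <- intersect(missing, carrying)
  if (length(missing_needed)) {
    stop("no FVA range for flux-carrying reaction(s): ",
         paste(missing_needed, collapse = ", "))
  }
  keep <- vapply(carrying, function(r) {
    v <- solution$fluxes[[r]]
    i <- match(r, ranges$reaction_id)
    lo <- ranges$fmin[i]; hi <- ranges$fmax[i]
    if (v > 0) {
      lo > (1 - crit$window) * v && hi < (1 + crit$window) * v
    } else {
      ## mirrored window for negative flux: [ (1+w)v, (1-w)v ]
      lo > (1 + crit$window) * v && hi < (1 - crit$window) * v
    }
  }, logical(1))
  carrying[keep]
}

#' Differential flux comparison between two conditions
#'
#' Runs the core filter on both conditions and reports, per reaction,
#' the fluxes, FVA ranges, core status in each condition and whether the
#' flux increased (in magnitude, beyond the zero tolerance) in the
#' second condition. The `increased` set is restricted to reactions
#' core in BOTH conditions, so it is robust to alternate optima.
#'
#' @param cmp_a,cmp_b lists `list(solution =, ranges =)` for the two
#'   conditions (e.g. wild type and producing strain), both under their
#'   documented constraints.
#' @param crit a `core_criterion`.
#' @param model optional `metabolic_model` used to annotate subsystem
#'   and gene-encoded status.
#' @return a `flux_comparison`: data.frame with one row per reaction and
#'   columns `reaction_id`, `flux_a`, `flux_b`, `fmin_a`, `fmax_a`,
#'   `fmin_b`, `fmax_b`, `core_a`, `core_b`, `increased`, plus
#'   `subsystem` and `gene_encoded` when a model is given.
#' @export
increased_flux_reactions <- function(cmp_a, cmp_b, crit = core_criterion(),
                                     model = NULL) {
  ids_a <- names(cmp_a$solution$fluxes)
  ids_b <- names(cmp_b$solution$fluxes)
  if (!setequal(ids_a, ids_b)) {
    stop("the two conditions expose different reaction sets; compare like with like")
  }
  ids <- ids_a
  core_a <- core_reactions(cmp_a$solution, cmp_a$ranges, crit, ids)
  core_b <- core_reactions(cmp_b$solution, cmp_b$ranges, crit, ids)
  fa <- cmp_a$solution$fluxes[ids]
  fb <- cmp_b$solution$fluxes[ids]
  ra <- cmp_a$ranges[match(ids, cmp_a$ranges$reaction_id), ]
  rb <- cmp_b$ranges[match(ids, cmp_b$ranges$reaction_id), ]
  out <- data.frame(reaction_id = ids,
                    flux_a = unname(fa), flux_b = unname(fb),
                    fmin_a = ra$fmin, fmax_a = ra$fmax,
                    fmin_b = rb$fmin, fmax_b = rb$fmax,
                    core_a = ids %in% core_a, core_b = ids %in% core_b,
                    stringsAsFactors = FALSE)
  out$increased <- out$core_a & out$core_b &
    (abs(out$flux_b) > abs(out$flux_a) + crit$zero_tolerance)
  if (!is.null(model)) {
    i <- match(ids, model$reactions$id)
    out$name <- model$reactions$name[i]
    out$subsystem <- model$reactions$subsystem[i]
    out$gene_encoded <- gene_encoded(model, ids)
  }
  class(out) <- c("flux_comparison", "data.frame")
  out
}

#' Reactions with increased flux
#'
#' @param cmp a `flux_comparison`.
#' @return the rows with `increased == TRUE`, ordered by the flux gain.
#' @export
increased_set <- function(cmp) {
  out <- cmp[cmp$increased, , drop = FALSE]
  out[order(abs(out$flux_b) - abs(out$flux_a), decreasing = TRUE), ,
      drop = FALSE]
}
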