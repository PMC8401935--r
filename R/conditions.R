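#' Condition configuration for the paired wt/recomb models
#'
#' @param uptake_bounds named vector: exchange reaction id -> maximum
#'   uptake, mmol/gCDW/h.
#' @param growth_fraction fraction of the wild-type optimal growth rate
#'   imposed (as a lower bound) on the producing model; the study value
#'   0.74 is the measured recombinant/wild-type growth-rate ratio
#'   (0.125/0.169), rounded to two digits.
#' @param biomass_reaction,product_reaction reaction ids.
#' @return object of class `condition_config`.
#' @export
condition_config <- function(uptake_bounds, growth_fraction = 0.74,
                             biomass_reaction, product_reaction) {
  if (growth_fraction < 0 || growth_fraction > 1) {
    stop("growth_fraction must lie in [0, 1]")
  }
  structure(list(uptake_bounds = unlist(uptake_bounds),
                 growth_fraction = growth_fraction,
                 biomass_reaction = biomass_reaction,
                 product_reaction = product_reaction),
            class = "condition_config")
}

#' Build the wild-type condition model
#'
#' Applies the medium (uptake bounds; all other organic-carbon uptakes
#' closed) and sets biomass as the objective. The product synthesis
#' reaction stays in the network, unconstrained: carrying it at zero
#' flux imposes no burden beyond any plasmid term in the biomass
#' reaction.
#'
#' @param base a `metabolic_model` containing biomass and product
#'   reactions.
#' @param cfg a `condition_config`.
#' @return the constrained model.
#' @export
build_wt_model <- function(base, cfg) {
  stopifnot(inherits(cfg, "condition_config"))
  missing <- setdiff(c(cfg$biomass_reaction, cfg$product_reaction),
                     base$reactions$id)
  if (length(missing)) {
    stop("model lacks reaction(s): ", paste(missing, collapse = ", "))
  }
  m <- set_medium(base, cfg$uptake_bounds)
  set_objective(m, cfg$biomass_reaction, "maximize")
}

#' Build the producing (recomb) condition model
#'
#' Same medium as the wild type, with growth constrained to
#' `growth_fraction` of the wild-type FBA optimum -- imposed as a lower
#' bound on the biomass flux, which binds at the product optimum but
#' avoids spurious infeasibility -- and the product synthesis reaction
#' as the objective.
#'
#' @param base a `metabolic_model`.
#' @param cfg a `condition_config`.
#' @param wt_growth optionally, the wild-type optimum to scale; computed
#'   from [build_wt_model()] by default.
#' @return the constrained model.
#' @export
build_recomb_model <- function(base, cfg, wt_growth = NULL) {
  wt <- build_wt_model(base, cfg)
  if (is.null(wt_growth)) {
    sol <- fba(wt)
    if (sol$status != "optimal") {
      stop("wild-type model not solvable (status: ", sol$status, ")")
    }
    wt_growth <- sol$objective_value
  }
  m <- set_bounds(wt, cfg$biomass_reaction,
                  lower_bound = cfg$growth_fraction * wt_growth)
  m <- set_objective(m, cfg$product_reaction, "maximize")
  chk <- fba(m)
  if (chk$status != "optimal") {
    stop("growth constraint ", cfg$growth_fraction, " x ",
         format(wt_growth), " makes the producing model ", chk$status)
  }
  m
}

#' Production envelope
#'
#' Traces the attainable (growth, product) region: for growth values on
#' a uniform grid from 0 to the biomass optimum, the biomass flux is
#' fixed and the product flux minimised and maximised by LP. On
#' competing-resource networks the upper edge decreases monotonically --
#' the biomass/product trade-off.
#'
#' @param model a `metabolic_model` (any objective; biomass and product
#'   ids given explicitly).
#' @param biomass_reaction,product_reaction reaction ids.
#' @param n_points grid size (>= 2).
#' @return data.frame with columns `growth`, `product_min`,
#'   `product_max`; infeasible grid points are dropped.
#' @export
production_envelope <- function(model, biomass_reaction, product_reaction,
                                n_points = 20) {
  stopifnot(n_points >= 2)
  m0 <- set_objective(model, biomass_reaction, "maximize")
  top <- fba(m0)
  if (top$status != "optimal") {
    stop("cannot anchor envelope: biomass FBA status ", top$status)
  }
  grid <- seq(0, top$objective_value, length.out = n_points)
  rows <- lapply(grid, function(g) {
    mg <- set_bounds(m0, biomass_reaction, lower_bound = g, upper_bound = g)
    mg <- set_objective(mg, product_reaction, "maximize")
    hi <- fba(mg)
    if (hi$status != "optimal") return(NULL)
    lo <- fba(set_objective(mg, product_reaction, "minimize"))
    if (lo$status != "optimal") return(NULL)
    data.frame(growth = g, product_min = lo$objective_value,
               product_max = hi$objective_value)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  out[order(out$growth), , drop = FALSE]
}
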