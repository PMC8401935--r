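#' Constraint-based metabolic model
#'
#' A `metabolic_model` is a stoichiometric reaction network with flux
#' bounds, gene-reaction rules, subsystems and one designated objective
#' reaction -- the in-memory form of an SBML Level 3 + FBC model. It is a
#' plain list with components:
#'
#' * `id`: model identifier.
#' * `metabolites`: data.frame with columns `id`, `name`, `compartment`,
#'   `formula`.
#' * `reactions`: data.frame with columns `id`, `name`, `lower_bound`,
#'   `upper_bound`, `gene_association`, `subsystem` (bounds in
#'   mmol/gCDW/h; `gene_association` a boolean expression over gene ids,
#'   `NA` for spontaneous/exchange reactions).
#' * `stoichiometry`: named list, one entry per reaction id, each a named
#'   numeric vector of metabolite coefficients (negative = consumed).
#' * `objective`: list with `reaction` (a reaction id) and `direction`
#'   ("maximize" or "minimize").
#'
#' @param id model identifier.
#' @param metabolites data.frame as above (missing `name`/`formula`
#'   columns are filled with `NA`).
#' @param reactions data.frame as above (missing optional columns filled).
#' @param stoichiometry named list of named numeric vectors.
#' @param objective objective reaction id, or a list
#'   `list(reaction =, direction =)`.
#' @return object of class `metabolic_model`.
#' @export
metabolic_model <- function(id, metabolites, reactions, stoichiometry,
                            objective) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  for (col in c("name", "formula")) {
    if (is.null(metabolites[[col]])) metabolites[[col]] <- NA_character_
  }
  for (col in c("name", "gene_association", "subsystem")) {
    if (is.null(reactions[[col]])) reactions[[col]] <- NA_character_
  }
  if (is.character(objective)) {
    objective <- list(reaction = objective, direction = "maximize")
  }
  m <- structure(
    list(id = id,
         metabolites = metabolites[, c("id", "name", "compartment", "formula")],
         reactions = reactions[, c("id", "name", "lower_bound", "upper_bound",
                                   "gene_association", "subsystem")],
         stoichiometry = stoichiometry[reactions$id],
         objective = objective),
    class = "metabolic_model")
  validate_model(m)
  m
}

#' Validate a metabolic model
#'
#' Checks the structural invariants: unique metabolite/reaction ids,
#' non-empty compartments, `lower_bound <= upper_bound`, non-empty
#' stoichiometries referencing only known metabolites, and an existing
#' objective reaction.
#'
#' @param model a `metabolic_model`.
#' @return the model, invisibly; errors describe the first violation.
#' @export
validate_model <- function(model) {
  mets <- model$metabolites
  rxns <- model$reactions
  if (nrow(mets) == 0 || nrow(rxns) == 0) {
    stop("model must contain at least one metabolite and one reaction")
  }
  if (anyDuplicated(mets$id)) stop("duplicate metabolite ids")
  if (anyDuplicated(rxns$id)) stop("duplicate reaction ids")
  if (any(is.na(mets$compartment) | !nzchar(mets$compartment))) {
    stop("every metabolite needs a non-empty compartment")
  }
  bad <- rxns$id[rxns$lower_bound > rxns$upper_bound]
  if (length(bad)) {
    stop("lower_bound > upper_bound for reaction(s): ", paste(bad, collapse = ", "))
  }
  if (!setequal(names(model$stoichiometry), rxns$id)) {
    stop("stoichiometry entries do not match reaction ids")
  }
  for (rid in rxns$id) {
    st <- model$stoichiometry[[rid]]
    if (!length(st)) stop("empty stoichiometry for reaction ", rid)
    if (any(!is.finite(st))) stop("non-finite coefficient in reaction ", rid)
    unknown <- setdiff(names(st), mets$id)
    if (length(unknown)) {
      stop("reaction ", rid, " references unknown metabolite(s): ",
           paste(unknown, collapse = ", "))
    }
  }
  if (!model$objective$reaction %in% rxns$id) {
    stop("objective reaction '", model$objective$reaction, "' not in model")
  }
  if (!model$objective$direction %in% c("maximize", "minimize")) {
    stop("objective direction must be 'maximize' or 'minimize'")
  }
  invisible(model)
}

#' @exportS3Method base::print
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$id, "\n",
      "  metabolites: ", nrow(x$metabolites),
      "  reactions: ", nrow(x$reactions), "\n",
      "  objective: ", x$objective$direction, " ", x$objective$reaction,
      "\n", sep = "")
  invisible(x)
}

#' Sparse stoichiometric matrix
#'
#' @param model a `metabolic_model`.
#' @return a sparse `Matrix` S (metabolites x reactions); `S[i, j]` is the
#'   coefficient of metabolite i in reaction j.
#' @export
stoich_matrix <- function(model) {
  mets <- model$metabolites$id
  rxns <- model$reactions$id
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (j in seq_along(rxns)) {
    st <- model$stoichiometry[[rxns[j]]]
    ii <- c(ii, match(names(st), mets))
    jj <- c(jj, rep.int(j, length(st)))
    xx <- c(xx, unname(st))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(length(mets), length(rxns)),
                       dimnames = list(mets, rxns))
}

#' Add a reaction to a model
#'
#' @param model a `metabolic_model`.
#' @param id new reaction id (must not exist).
#' @param stoichiometry named numeric vector of metabolite coefficients;
#'   metabolites unknown to the model are rejected unless listed in
#'   `new_metabolites`.
#' @param lower_bound,upper_bound flux bounds, mmol/gCDW/h.
#' @param name,gene_association,subsystem optional annotation.
#' @param new_metabolites optional data.frame of metabolites to add first
#'   (columns as in [metabolic_model()]).
#' @return the extended model.
#' @export
add_reaction <- function(model, id, stoichiometry,
                         lower_bound = 0, upper_bound = 1000,
                         name = NA_character_,
                         gene_association = NA_character_,
                         subsystem = NA_character_,
                         new_metabolites = NULL) {
  if (id %in% model$reactions$id) stop("reaction id already present: ", id)
  if (!is.null(new_metabolites)) {
    new_metabolites <- as.data.frame(new_metabolites, stringsAsFactors = FALSE)
    for (col in c("name", "formula")) {
      if (is.null(new_metabolites[[col]])) new_metabolites[[col]] <- NA_character_
    }
    new_metabolites <- new_metabolites[, c("id", "name", "compartment", "formula")]
    model$metabolites <- rbind(model$metabolites, new_metabolites)
  }
  model$reactions <- rbind(
    model$reactions,
    data.frame(id = id, name = name, lower_bound = lower_bound,
               upper_bound = upper_bound, gene_association = gene_association,
               subsystem = subsystem, stringsAsFactors = FALSE))
  model$stoichiometry[[id]] <- stoichiometry
  validate_model(model)
}

#' Set flux bounds on a reaction
#'
#' @param model a `metabolic_model`.
#' @param id reaction id.
#' @param lower_bound,upper_bound new bounds; `NULL` leaves a bound as is.
#' @return the modified model.
#' @export
set_bounds <- function(model, id, lower_bound = NULL, upper_bound = NULL) {
  i <- match(id, model$reactions$id)
  if (is.na(i)) stop("unknown reaction: ", id)
  if (!is.null(lower_bound)) model$reactions$lower_bound[i] <- lower_bound
  if (!is.null(upper_bound)) model$reactions$upper_bound[i] <- upper_bound
  validate_model(model)
}

#' Set the model objective
#'
#' @param model a `metabolic_model`.
#' @param reaction reaction id to optimise.
#' @param direction "maximize" or "minimize".
#' @return the modified model.
#' @export
set_objective <- function(model, reaction, direction = "maximize") {
  model$objective <- list(reaction = reaction, direction = direction)
  validate_model(model)
}

#' Exchange reactions of a model
#'
#' An exchange reaction touches exactly one metabolite: it moves mass
#' across the model boundary.
#'
#' @param model a `metabolic_model`.
#' @return character vector of reaction ids.
#' @export
exchange_reactions <- function(model) {
  n <- vapply(model$stoichiometry, length, integer(1))
  model$reactions$id[n[model$reactions$id] == 1L]
}

#' Is a reaction gene-encoded?
#'
#' @param model a `metabolic_model`.
#' @param id reaction id(s).
#' @return logical: `TRUE` where the gene-reaction rule is non-empty.
#' @export
gene_encoded <- function(model, id = model$reactions$id) {
  g <- model$reactions$gene_association[match(id, model$reactions$id)]
  !is.na(g) & nzchar(trimws(g))
}

#' Human-readable reaction equation
#'
#' @param model a `metabolic_model`.
#' @param id reaction id.
#' @param digits coefficient formatting precision.
#' @return a string like `"1 A + 2 B -> 1 C"` (`<=>` when reversible).
#' @export
reaction_string <- function(model, id, digits = 6) {
  st <- model$stoichiometry[[id]]
  if (is.null(st)) stop("unknown reaction: ", id)
  i <- match(id, model$reactions$id)
  fmt <- function(v) {
    paste(vapply(seq_along(v), function(k) {
      co <- signif(abs(v[k]), digits)
      if (co == 1) names(v)[k] else paste(format(co, scientific = FALSE), names(v)[k])
    }, character(1)), collapse = " + ")
  }
  lhs <- fmt(st[st < 0])
  rhs <- fmt(st[st > 0])
  arrow <- if (model$reactions$lower_bound[i] < 0) "<=>" else "->"
  paste(lhs, arrow, rhs)
}

#' Dump the reaction table as TSV
#'
#' Writes one row per reaction: id, name, subsystem, bounds, gene rule and
#' equation -- a quick inspection format.
#'
#' @param model a `metabolic_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_reaction_tsv <- function(model, path) {
  df <- model$reactions
  df$equation <- vapply(df$id, function(r) reaction_string(model, r), character(1))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
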