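## Minimal SBML Level 3 + FBC v2 I/O.
##
## Covers exactly the fields the pipeline consumes: compartments, species
## (with chemical formulas), reactions with flux-bound parameters, the
## active FBC objective, gene-product associations and a COBRA-style
## SUBSYSTEM note. Identifiers are escaped to valid SBML SIds using the
## COBRA "__<ascii>__" convention, so files round-trip through COBRApy.

SBML_CORE_NS <- "http://www.sbml.org/sbml/level3/version1/core"
SBML_FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

sid_encode <- function(x, prefix) {
  enc <- vapply(x, function(s) {
    chars <- strsplit(s, "")[[1]]
    bad <- !grepl("[A-Za-z0-9_]", chars)
    chars[bad] <- sprintf("__%d__", utf8ToInt(paste(chars[bad], collapse = ""))[seq_len(sum(bad))])
    paste(chars, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  paste0(prefix, enc)
}

sid_decode <- function(x, prefix) {
  x <- sub(paste0("^", prefix), "", x)
  vapply(x, function(s) {
    m <- gregexpr("__([0-9]+)__", s)[[1]]
    if (m[1] == -1) return(s)
    regmatches(s, gregexpr("__([0-9]+)__", s)) <- lapply(
      regmatches(s, gregexpr("__([0-9]+)__", s)),
      function(tok) vapply(tok, function(t) {
        intToUtf8(as.integer(gsub("__", "", t)))
      }, character(1)))
    s
  }, character(1), USE.NAMES = FALSE)
}

num_attr <- function(x) sprintf("%.17g", x + 0)   # + 0 folds -0 into 0

## ---- gene-reaction rules ---------------------------------------------

## tiny recursive-descent parser for boolean gene rules:
##   expr := term ('or' term)* ; term := factor ('and' factor)* ;
##   factor := gene | '(' expr ')'
parse_gpr <- function(s) {
  tokens <- regmatches(s, gregexpr("\\(|\\)|[^\\s()]+", s, perl = TRUE))[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[pos] else NA_character_
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  parse_expr <- function() {
    terms <- list(parse_term())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      take()
      terms <- c(terms, list(parse_term()))
    }
    if (length(terms) == 1) terms[[1]] else list(op = "or", args = terms)
  }
  parse_term <- function() {
    factors <- list(parse_factor())
    while (!is.na(peek()) && tolower(peek()) == "and") {
      take()
      factors <- c(factors, list(parse_factor()))
    }
    if (length(factors) == 1) factors[[1]] else list(op = "and", args = factors)
  }
  parse_factor <- function() {
    t <- take()
    if (is.na(t)) stop("malformed gene rule: ", s)
    if (t == "(") {
      e <- parse_expr()
      if (!identical(take(), ")")) stop("unbalanced parentheses in gene rule: ", s)
      return(e)
    }
    if (t == ")" || tolower(t) %in% c("and", "or")) {
      stop("malformed gene rule: ", s)
    }
    list(op = "gene", gene = t)
  }
  out <- parse_expr()
  if (!is.na(peek())) stop("trailing tokens in gene rule: ", s)
  out
}

gpr_to_string <- function(node) {
  if (node$op == "gene") return(node$gene)
  parts <- vapply(node$args, function(a) {
    s <- gpr_to_string(a)
    if (a$op != "gene") paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = paste0(" ", node$op, " "))
}

gpr_genes <- function(node) {
  if (node$op == "gene") return(node$gene)
  unique(unlist(lapply(node$args, gpr_genes)))
}

#' Canonical form of a gene-reaction rule
#'
#' Reparses a boolean gene rule and prints it with normalised spacing and
#' parentheses, so that logically identical rules compare equal as
#' strings.
#'
#' @param s gene rule string (e.g. `"(g1 and g2) or g3"`); `NA` passes
#'   through.
#' @return canonical string.
#' @export
canonical_gpr <- function(s) {
  if (is.na(s) || !nzchar(trimws(s))) return(NA_character_)
  gpr_to_string(parse_gpr(s))
}

## ---- writer -----------------------------------------------------------

#' Write a model as SBML Level 3 + FBC v2
#'
#' @param model a `metabolic_model` (validated before writing).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sbml_model <- function(model, path) {
  validate_model(model)
  doc <- xml2::xml_new_root(
    "sbml",
    xmlns = SBML_CORE_NS, "xmlns:fbc" = SBML_FBC_NS,
    level = "3", version = "1", "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model",
                             id = sid_encode(model$id, ""),
                             "fbc:strict" = "true")

  comps <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cid in unique(model$metabolites$compartment)) {
    xml2::xml_add_child(comps, "compartment", id = cid, constant = "true")
  }

  sps <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites))) {
    met <- model$metabolites[i, ]
    node <- xml2::xml_add_child(
      sps, "species",
      id = sid_encode(met$id, "M_"),
      compartment = met$compartment,
      hasOnlySubstanceUnits = "false",
      boundaryCondition = "false", constant = "false")
    if (!is.na(met$name)) xml2::xml_set_attr(node, "name", met$name)
    if (!is.na(met$formula) && nzchar(met$formula)) {
      xml2::xml_set_attr(node, "fbc:chemicalFormula", met$formula)
    }
  }

  ## flux-bound parameters, shared where values coincide
  bounds <- sort(unique(c(model$reactions$lower_bound, model$reactions$upper_bound)))
  bid <- stats::setNames(sprintf("fb_%d", seq_along(bounds)), num_attr(bounds))
  pars <- xml2::xml_add_child(mdl, "listOfParameters")
  for (v in bounds) {
    xml2::xml_add_child(pars, "parameter", id = bid[[num_attr(v)]],
                        value = num_attr(v), constant = "true",
                        sboTerm = "SBO:0000625")
  }

  objs <- xml2::xml_add_child(mdl, "fbc:listOfObjectives",
                              "fbc:activeObjective" = "obj")
  obj <- xml2::xml_add_child(objs, "fbc:objective", "fbc:id" = "obj",
                             "fbc:type" = model$objective$direction)
  fol <- xml2::xml_add_child(obj, "fbc:listOfFluxObjectives")
  xml2::xml_add_child(fol, "fbc:fluxObjective",
                      "fbc:reaction" = sid_encode(model$objective$reaction, "R_"),
                      "fbc:coefficient" = "1")

  gprs <- model$reactions$gene_association
  genes <- unique(unlist(lapply(gprs[!is.na(gprs) & nzchar(gprs)],
                                function(g) gpr_genes(parse_gpr(g)))))
  if (length(genes)) {
    gl <- xml2::xml_add_child(mdl, "fbc:listOfGeneProducts")
    for (g in genes) {
      xml2::xml_add_child(gl, "fbc:geneProduct",
                          "fbc:id" = sid_encode(g, "G_"), "fbc:label" = g)
    }
  }

  rl <- xml2::xml_add_child(mdl, "listOfReactions")
  for (i in seq_len(nrow(model$reactions))) {
    rx <- model$reactions[i, ]
    st <- model$stoichiometry[[rx$id]]
    node <- xml2::xml_add_child(
      rl, "reaction",
      id = sid_encode(rx$id, "R_"),
      reversible = if (rx$lower_bound < 0) "true" else "false",
      fast = "false",
      "fbc:lowerFluxBound" = bid[[num_attr(rx$lower_bound)]],
      "fbc:upperFluxBound" = bid[[num_attr(rx$upper_bound)]])
    if (!is.na(rx$name)) xml2::xml_set_attr(node, "name", rx$name)
    if (!is.na(rx$subsystem) && nzchar(rx$subsystem)) {
      notes <- xml2::xml_add_child(node, "notes")
      body <- xml2::xml_add_child(notes, "body",
                                  xmlns = "http://www.w3.org/1999/xhtml")
      p <- xml2::xml_add_child(body, "p")
      xml2::xml_set_text(p, paste0("SUBSYSTEM: ", rx$subsystem))
    }
    if (any(st < 0)) {
      lr <- xml2::xml_add_child(node, "listOfReactants")
      for (mid in names(st)[st < 0]) {
        xml2::xml_add_child(lr, "speciesReference",
                            species = sid_encode(mid, "M_"),
                            stoichiometry = num_attr(-st[[mid]]),
                            constant = "true")
      }
    }
    if (any(st > 0)) {
      lp <- xml2::xml_add_child(node, "listOfProducts")
      for (mid in names(st)[st > 0]) {
        xml2::xml_add_child(lp, "speciesReference",
                            species = sid_encode(mid, "M_"),
                            stoichiometry = num_attr(st[[mid]]),
                            constant = "true")
      }
    }
    if (!is.na(rx$gene_association) && nzchar(rx$gene_association)) {
      gpa <- xml2::xml_add_child(node, "fbc:geneProductAssociation")
      add_gpr_node <- function(parent, ast) {
        if (ast$op == "gene") {
          xml2::xml_add_child(parent, "fbc:geneProductRef",
                              "fbc:geneProduct" = sid_encode(ast$gene, "G_"))
        } else {
          sub <- xml2::xml_add_child(parent, paste0("fbc:", ast$op))
          for (a in ast$args) add_gpr_node(sub, a)
        }
      }
      add_gpr_node(gpa, parse_gpr(rx$gene_association))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

## ---- reader -----------------------------------------------------------

#' Read an SBML Level 3 + FBC model
#'
#' Parses the fields the pipeline uses: species, compartments, reactions
#' with flux-bound parameters, gene-product associations, COBRA-style
#' SUBSYSTEM notes and the active FBC objective. Errors if the file
#' carries no FBC objective or no flux-bound information.
#'
#' @param path SBML file.
#' @return a `metabolic_model`.
#' @export
read_sbml_model <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("cannot parse SBML file: ",
                                           conditionMessage(e)))
  core <- xml2::xml_ns(doc)
  ns <- c(s = unname(xml2::xml_attr(doc, "xmlns") %||%
                       xml2::xml_ns(doc)[["d1"]]),
          fbc = SBML_FBC_NS)
  if (is.na(ns[["s"]])) ns[["s"]] <- SBML_CORE_NS

  mdl <- xml2::xml_find_first(doc, "./s:model", ns)
  if (inherits(mdl, "xml_missing")) stop("no <model> element in SBML file")
  model_id <- xml2::xml_attr(mdl, "id")

  sp_nodes <- xml2::xml_find_all(mdl, ".//s:listOfSpecies/s:species", ns)
  if (!length(sp_nodes)) stop("SBML file declares no species")
  mets <- data.frame(
    id = sid_decode(xml2::xml_attr(sp_nodes, "id"), "M_"),
    name = xml2::xml_attr(sp_nodes, "name"),
    compartment = xml2::xml_attr(sp_nodes, "compartment"),
    formula = xml2::xml_attr(sp_nodes, "chemicalFormula"),
    stringsAsFactors = FALSE)
  sid_by_raw <- stats::setNames(mets$id, xml2::xml_attr(sp_nodes, "id"))

  par_nodes <- xml2::xml_find_all(mdl, ".//s:listOfParameters/s:parameter", ns)
  par_val <- stats::setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                             xml2::xml_attr(par_nodes, "id"))

  ## active objective
  obj_list <- xml2::xml_find_first(mdl, ".//fbc:listOfObjectives", ns)
  if (inherits(obj_list, "xml_missing")) {
    stop("SBML file declares no FBC objective (fbc:listOfObjectives missing)")
  }
  active <- xml2::xml_attr(obj_list, "activeObjective")
  objs <- xml2::xml_find_all(obj_list, "./fbc:objective", ns)
  if (!length(objs)) stop("SBML file declares no FBC objective")
  ids <- xml2::xml_attr(objs, "id")
  pick <- if (!is.na(active) && active %in% ids) match(active, ids) else 1L
  if (length(objs) > 1 && (is.na(active) || !active %in% ids)) {
    warning("multiple objectives with no resolvable active one; using the first")
  }
  obj_node <- objs[[pick]]
  direction <- xml2::xml_attr(obj_node, "type")
  flux_obj <- xml2::xml_find_first(obj_node, ".//fbc:fluxObjective", ns)
  if (inherits(flux_obj, "xml_missing")) {
    stop("active FBC objective lists no flux objective")
  }
  obj_rxn_raw <- xml2::xml_attr(flux_obj, "reaction")

  gp_nodes <- xml2::xml_find_all(mdl, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  gene_label <- stats::setNames(xml2::xml_attr(gp_nodes, "label"),
                                xml2::xml_attr(gp_nodes, "id"))

  rx_nodes <- xml2::xml_find_all(mdl, ".//s:listOfReactions/s:reaction", ns)
  if (!length(rx_nodes)) stop("SBML file declares no reactions")

  read_gpr <- function(node) {
    gpa <- xml2::xml_find_first(node, "./fbc:geneProductAssociation", ns)
    if (inherits(gpa, "xml_missing")) return(NA_character_)
    walk <- function(n) {
      nm <- xml2::xml_name(n)
      if (nm == "geneProductRef") {
        gid <- xml2::xml_attr(n, "geneProduct")
        g <- gene_label[[gid]]
        return(list(op = "gene",
                    gene = if (!is.null(g) && !is.na(g)) g else sid_decode(gid, "G_")))
      }
      kids <- xml2::xml_children(n)
      list(op = nm, args = lapply(kids, walk))
    }
    root <- xml2::xml_children(gpa)
    if (!length(root)) return(NA_character_)
    gpr_to_string(walk(root[[1]]))
  }

  n <- length(rx_nodes)
  rxns <- data.frame(id = character(n), name = character(n),
                     lower_bound = numeric(n), upper_bound = numeric(n),
                     gene_association = character(n), subsystem = character(n),
                     stringsAsFactors = FALSE)
  stoich <- vector("list", n)
  raw_ids <- character(n)
  for (i in seq_len(n)) {
    node <- rx_nodes[[i]]
    raw_ids[i] <- xml2::xml_attr(node, "id")
    rxns$id[i] <- sid_decode(raw_ids[i], "R_")
    rxns$name[i] <- xml2::xml_attr(node, "name")
    lb_ref <- xml2::xml_attr(node, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(node, "upperFluxBound")
    if (is.na(lb_ref) || is.na(ub_ref)) {
      stop("reaction ", rxns$id[i], " carries no FBC flux-bound attributes")
    }
    rxns$lower_bound[i] <- par_val[[lb_ref]]
    rxns$upper_bound[i] <- par_val[[ub_ref]]
    rxns$gene_association[i] <- read_gpr(node)
    note <- xml2::xml_text(xml2::xml_find_first(
      node, ".//s:notes//*[starts-with(normalize-space(text()), 'SUBSYSTEM:')]", ns))
    rxns$subsystem[i] <- if (!is.na(note)) {
      trimws(sub("^\\s*SUBSYSTEM:", "", note))
    } else NA_character_
    reac <- xml2::xml_find_all(node, "./s:listOfReactants/s:speciesReference", ns)
    prod <- xml2::xml_find_all(node, "./s:listOfProducts/s:speciesReference", ns)
    st <- c(
      stats::setNames(-as.numeric(xml2::xml_attr(reac, "stoichiometry")),
                      sid_by_raw[xml2::xml_attr(reac, "species")]),
      stats::setNames(as.numeric(xml2::xml_attr(prod, "stoichiometry")),
                      sid_by_raw[xml2::xml_attr(prod, "species")]))
    stoich[[i]] <- st
  }
  names(stoich) <- rxns$id

  metabolic_model(
    id = if (is.na(model_id)) "model" else sid_decode(model_id, ""),
    metabolites = mets, reactions = rxns, stoichiometry = stoich,
    objective = list(reaction = rxns$id[match(obj_rxn_raw, raw_ids)],
                     direction = if (is.na(direction)) "maximize" else direction))
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
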