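#' SBML subset export
#'
#' Writes a `reaction_network` plus a rate-constant set as SBML Level 2
#' Version 4: one compartment, species with initial concentrations
#' (clamped species as boundary conditions), global parameters, and
#' per-reaction kinetic laws in canonical MathML for the three supported
#' law kinds. Events, rules, function definitions and multi-compartment
#' models are out of scope.
#'
#' @param net a `reaction_network`.
#' @param params named rate-constant vector.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_sbml <- function(net, params, path) {
  params <- check_params(net, params)
  esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", x))
  num <- function(x) sprintf("%.17g", x)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    '<model id="selenium_metabolism">',
    '<listOfCompartments><compartment id="cell" size="1"/></listOfCompartments>',
    '<listOfSpecies>')
  for (i in seq_len(nrow(net$species)))
    lines <- c(lines, sprintf(
      '<species id="%s" compartment="cell" initialConcentration="%s" boundaryCondition="%s"/>',
      esc(net$species$name[i]), num(net$species$initial_concentration[i]),
      tolower(net$species$clamped[i])))
  lines <- c(lines, '</listOfSpecies>', '<listOfParameters>')
  for (nm in net$parameter_names)
    lines <- c(lines, sprintf('<parameter id="%s" value="%s"/>',
                              esc(nm), num(params[[nm]])))
  lines <- c(lines, '</listOfParameters>', '<listOfReactions>')
  ci <- function(x) sprintf("<ci>%s</ci>", esc(x))
  for (rx in net$reactions) {
    lines <- c(lines, sprintf('<reaction id="%s" reversible="false">',
                              esc(rx$id)))
    sref <- function(tag, st) {
      if (length(st) == 0) return(character())
      c(sprintf("<listOf%s>", tag),
        sprintf('<speciesReference species="%s" stoichiometry="%d"/>',
                esc(names(st)), st),
        sprintf("</listOf%s>", tag))
    }
    lines <- c(lines, sref("Reactants", rx$reactants),
               sref("Products", rx$products))
    if (length(rx$modifiers) > 0)
      lines <- c(lines, "<listOfModifiers>",
                 sprintf('<modifierSpeciesReference species="%s"/>',
                         esc(rx$modifiers)), "</listOfModifiers>")
    math <- rate_law_mathml(rx, ci)
    lines <- c(lines, "<kineticLaw>",
               '<math xmlns="http://www.w3.org/1998/Math/MathML">',
               math, "</math>", "</kineticLaw>", "</reaction>")
  }
  lines <- c(lines, "</listOfReactions>", "</model>", "</sbml>")
  writeLines(lines, path)
  invisible(path)
}

## Canonical MathML per law kind. Linear factors are every reactant
## (by stoichiometry) and modifier other than the dedicated saturating /
## amplifying species.
rate_law_mathml <- function(rx, ci) {
  skip <- switch(rx$rate_law, saturating = rx$sat,
                 amplified = c(rx$sat, rx$lin), character())
  lin <- c(rep(names(rx$reactants), rx$reactants), rx$modifiers)
  lin <- lin[!lin %in% skip]
  times_of <- function(parts) {
    parts <- parts[nzchar(parts)]
    if (length(parts) == 1) parts
    else paste0("<apply><times/>", paste0(parts, collapse = ""), "</apply>")
  }
  switch(rx$rate_law,
    mass_action = times_of(c(ci(rx$constants[1]), ci(lin))),
    saturating = {
      extra <- if (rx$sat %in% names(rx$reactants) &&
                   rx$reactants[[rx$sat]] > 1L)
        rep(ci(rx$sat), rx$reactants[[rx$sat]] - 1L) else character()
      num <- times_of(c(ci(rx$constants[1]), ci(rx$sat), ci(lin), extra))
      den <- paste0("<apply><plus/>", ci(rx$constants[2]), ci(rx$sat),
                    "</apply>")
      paste0("<apply><divide/>", num, den, "</apply>")
    },
    amplified = {
      t1 <- times_of(c(ci(rx$constants[1]), ci(rx$lin)))
      num <- times_of(c(ci(rx$constants[3]), ci(rx$lin), ci(rx$sat)))
      den <- paste0("<apply><plus/>", ci(rx$constants[2]), ci(rx$sat),
                    "</apply>")
      t2 <- paste0("<apply><divide/>", num, den, "</apply>")
      core <- paste0("<apply><plus/>", t1, t2, "</apply>")
      times_of(c(core, ci(lin)))
    })
}

## ---- import ----------------------------------------------------------

## MathML -> nested list {op, args} | {ci, name} | {cn, value}
parse_mathml <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "math") {
    kids <- xml2::xml_children(node)
    if (length(kids) != 1) stop("math element must have one child")
    return(parse_mathml(kids[[1]]))
  }
  if (nm == "ci")
    return(list(kind = "ci", name = trimws(xml2::xml_text(node))))
  if (nm == "cn")
    return(list(kind = "cn", value = as.numeric(xml2::xml_text(node))))
  if (nm == "apply") {
    kids <- xml2::xml_children(node)
    op <- xml2::xml_name(kids[[1]])
    args <- lapply(kids[-1], parse_mathml)
    return(list(kind = "op", op = op, args = args))
  }
  stop(sprintf("unsupported MathML element <%s>", nm))
}

## Normalize an expression into a flat numerator factor list and a list
## of denominator expressions. Nested times/divide are flattened.
collect_factors <- function(expr) {
  if (expr$kind == "op" && expr$op == "times") {
    parts <- lapply(expr$args, collect_factors)
    return(list(num = do.call(c, lapply(parts, `[[`, "num")),
                den = do.call(c, lapply(parts, `[[`, "den"))))
  }
  if (expr$kind == "op" && expr$op == "divide") {
    a <- collect_factors(expr$args[[1]])
    b <- collect_factors(expr$args[[2]])
    return(list(num = c(a$num, b$den), den = c(a$den, b$num)))
  }
  list(num = list(expr), den = list())
}

factor_names <- function(factors, ids) {
  out <- character()
  for (f in factors) {
    if (f$kind != "ci" || !(f$name %in% ids)) return(NULL)
    out <- c(out, f$name)
  }
  out
}

## plus(k, S) -> c(constant = k, species = S); NULL if not that shape
match_mm_denominator <- function(expr, param_ids, species_ids) {
  if (!(expr$kind == "op" && expr$op == "plus" && length(expr$args) == 2))
    return(NULL)
  kinds <- vapply(expr$args, function(a)
    if (a$kind == "ci" && a$name %in% param_ids) "param"
    else if (a$kind == "ci" && a$name %in% species_ids) "species"
    else "other", "")
  if (setequal(kinds, c("param", "species"))) {
    k <- expr$args[[which(kinds == "param")]]$name
    s <- expr$args[[which(kinds == "species")]]$name
    c(constant = k, species = s)
  } else NULL
}

classify_kinetic_law <- function(expr, param_ids, species_ids, rx_id) {
  fail <- function(what)
    stop(sprintf("reaction %s: unsupported kinetic-law construct (%s)",
                 rx_id, what), call. = FALSE)

  ## amplified: times(plus(times(k0,L), divide(times(k2,L,A), plus(k1,A))), ...)
  top <- if (expr$kind == "op" && expr$op == "times") expr$args else list(expr)
  plus_idx <- which(vapply(top, function(a)
    a$kind == "op" && a$op == "plus" && length(a$args) == 2, TRUE))
  if (length(plus_idx) == 1 && length(top) >= 1 &&
      is.null(match_mm_denominator(top[[plus_idx]], param_ids, species_ids))) {
    core <- top[[plus_idx]]
    rest <- top[-plus_idx]
    lin_names <- factor_names(rest, species_ids)
    t1 <- collect_factors(core$args[[1]])
    t2 <- collect_factors(core$args[[2]])
    if (length(t2$den) == 0 && length(t1$den) == 1) { tmp <- t1; t1 <- t2; t2 <- tmp }
    if (length(t1$den) == 0 && length(t2$den) == 1 && !is.null(lin_names)) {
      den <- match_mm_denominator(t2$den[[1]], param_ids, species_ids)
      n1 <- vapply(t1$num, function(f) f$name, "")
      n2 <- vapply(t2$num, function(f) f$name, "")
      k0 <- intersect(n1, param_ids); L1 <- intersect(n1, species_ids)
      k2 <- intersect(n2, param_ids); s2 <- intersect(n2, species_ids)
      if (!is.null(den) && length(k0) == 1 && length(L1) == 1 &&
          length(k2) == 1 && setequal(s2, c(L1, den[["species"]]))) {
        return(list(rate_law = "amplified",
                    constants = c(k0, den[["constant"]], k2),
                    sat = den[["species"]], lin = L1,
                    lin_factors = lin_names))
      }
    }
  }

  f <- collect_factors(expr)
  if (length(f$den) == 0) {
    nm <- vapply(f$num, function(x)
      if (x$kind == "ci") x$name else NA_character_, "")
    if (anyNA(nm)) fail("non-identifier factor")
    k <- nm[nm %in% param_ids]
    sp <- nm[nm %in% species_ids]
    if (length(k) != 1 || length(k) + length(sp) != length(nm))
      fail("mass-action form needs exactly one rate constant")
    return(list(rate_law = "mass_action", constants = k,
                sat = NA_character_, lin = NA_character_,
                lin_factors = sp))
  }
  if (length(f$den) == 1) {
    den <- match_mm_denominator(f$den[[1]], param_ids, species_ids)
    if (is.null(den)) fail("denominator is not (constant + species)")
    nm <- vapply(f$num, function(x)
      if (x$kind == "ci") x$name else NA_character_, "")
    if (anyNA(nm)) fail("non-identifier factor")
    k <- nm[nm %in% param_ids]
    sp <- nm[nm %in% species_ids]
    if (length(k) != 1 || !(den[["species"]] %in% sp) ||
        length(k) + length(sp) != length(nm))
      fail("Michaelis-Menten form needs one constant and the saturating species")
    sp <- sp[-match(den[["species"]], sp)] # MM factor supplies one power
    return(list(rate_law = "saturating",
                constants = c(k, den[["constant"]]),
                sat = den[["species"]], lin = NA_character_,
                lin_factors = sp))
  }
  fail("nested or multiple denominators")
}

#' Import an SBML subset model
#'
#' Reads SBML Level 2/3 restricted to: one compartment, species with
#' initial concentrations, global parameters, and kinetic laws that are
#' mass-action, Michaelis-Menten-style saturating, or the composite
#' amplified damage form. Unparseable kinetic laws raise an error naming
#' the reaction.
#'
#' @param path SBML file.
#' @return list of class `sbml_model`: `network` (a `reaction_network`)
#'   and `params` (named rate-constant vector from the file).
#' @export
import_sbml <- function(path) {
  doc <- xml2::read_xml(path) # malformed XML errors here
  xml2::xml_ns_strip(doc)
  sp_nodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  if (length(sp_nodes) == 0) stop("SBML model has no species", call. = FALSE)
  species <- tibble::tibble(
    name = xml2::xml_attr(sp_nodes, "id"),
    initial_concentration = {
      v <- as.numeric(xml2::xml_attr(sp_nodes, "initialConcentration"))
      ifelse(is.na(v), 0, v)
    },
    clamped = xml2::xml_attr(sp_nodes, "boundaryCondition") %in%
      c("true", "1"))
  par_nodes <- xml2::xml_find_all(
    doc, ".//model/listOfParameters/parameter")
  params <- stats::setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                            xml2::xml_attr(par_nodes, "id"))
  rx_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  if (length(rx_nodes) == 0)
    stop("SBML model has no reactions (empty network)", call. = FALSE)

  reactions <- lapply(rx_nodes, function(nd) {
    id <- xml2::xml_attr(nd, "id")
    get_refs <- function(xp) {
      refs <- xml2::xml_find_all(nd, xp)
      if (length(refs) == 0) return(NULL)
      st <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      st[is.na(st)] <- 1
      stats::setNames(as.integer(st), xml2::xml_attr(refs, "species"))
    }
    reactants <- get_refs(".//listOfReactants/speciesReference")
    products <- get_refs(".//listOfProducts/speciesReference")
    modifiers <- xml2::xml_attr(
      xml2::xml_find_all(nd, ".//listOfModifiers/modifierSpeciesReference"),
      "species")
    math <- xml2::xml_find_first(nd, ".//kineticLaw/math")
    if (inherits(math, "xml_missing"))
      stop(sprintf("reaction %s: missing kinetic law", id), call. = FALSE)
    ## local kinetic-law parameters are folded into the global table
    loc <- xml2::xml_find_all(nd, ".//kineticLaw//parameter")
    if (length(loc) > 0) {
      lv <- stats::setNames(as.numeric(xml2::xml_attr(loc, "value")),
                            xml2::xml_attr(loc, "id"))
      params <<- c(params, lv[setdiff(names(lv), names(params))])
    }
    expr <- parse_mathml(math)
    law <- classify_kinetic_law(expr, names(params), species$name, id)
    ## consistency: law factors implied by reactants/modifiers
    reaction(id, reactants = reactants, products = products,
             modifiers = if (length(modifiers)) modifiers else character(),
             rate_law = law$rate_law, constants = law$constants,
             sat = law$sat, lin = law$lin)
  })
  used <- unlist(lapply(reactions, `[[`, "constants"))
  net <- reaction_network(species, reactions, parameter_names = used)
  net <- detect_reference_topology(net)
  structure(list(network = net, params = params[used]),
            class = "sbml_model")
}

## Mark a structurally-reference network so the fast cascade solver and
## dose/damage conventions apply after an SBML round trip.
detect_reference_topology <- function(net) {
  ref <- reference_selenium_network()
  if (same_network_structure(net, ref)) {
    net$topology <- "selenium_reference"
    net$dose_species <- "Se_ext"
    net$damage_species <- "dmDNA"
  }
  net
}

#' Structural equality of two reaction networks
#'
#' Species (names, clamping), reactions (stoichiometry, modifiers, law
#' kind, constant names, saturating/amplifying roles) and the parameter
#' list must all agree; initial concentrations are compared to 1e-12.
#'
#' @param a,b `reaction_network` objects.
#' @return logical.
#' @export
same_network_structure <- function(a, b) {
  sa <- dplyr::arrange(a$species, .data$name)
  sb <- dplyr::arrange(b$species, .data$name)
  if (!identical(sa$name, sb$name) || !identical(sa$clamped, sb$clamped) ||
      max(abs(sa$initial_concentration - sb$initial_concentration)) > 1e-12)
    return(FALSE)
  if (!setequal(a$parameter_names, b$parameter_names)) return(FALSE)
  ids_a <- vapply(a$reactions, `[[`, "", "id")
  ids_b <- vapply(b$reactions, `[[`, "", "id")
  if (!setequal(ids_a, ids_b)) return(FALSE)
  for (id in ids_a) {
    ra <- a$reactions[[match(id, ids_a)]]
    rb <- b$reactions[[match(id, ids_b)]]
    sort_stoich <- function(x) {
      if (length(x) == 0) return(stats::setNames(integer(), character()))
      x[order(names(x))]
    }
    same <- identical(sort_stoich(ra$reactants), sort_stoich(rb$reactants)) &&
      identical(sort_stoich(ra$products), sort_stoich(rb$products)) &&
      setequal(ra$modifiers, rb$modifiers) &&
      identical(ra$rate_law, rb$rate_law) &&
      identical(ra$constants, rb$constants) &&
      identical(ra$sat, rb$sat) && identical(ra$lin, rb$lin)
    if (!same) return(FALSE)
  }
  TRUE
}

## ---- JSON serialization ----------------------------------------------

#' Write / read a network (plus rate constants) as JSON
#'
#' A plain-text serialization of the full network structure — species,
#' reactions, rate-law roles and parameter order — together with an
#' optional rate-constant set. Round-trips exactly.
#'
#' @param net a `reaction_network`.
#' @param params optional named rate-constant vector.
#' @param path output (input) file path.
#' @return `write_network_json()` returns `path` invisibly;
#'   `read_network_json()` returns a list with `network` and `params`
#'   (`NULL` when the file carries none).
#' @export
write_network_json <- function(net, path, params = NULL) {
  if (!is.null(params)) params <- as.list(check_params(net, params))
  obj <- list(
    species = net$species,
    reactions = lapply(net$reactions, function(rx)
      list(id = rx$id,
           reactants = as.list(rx$reactants),
           products = as.list(rx$products),
           modifiers = as.list(rx$modifiers),
           rate_law = rx$rate_law, constants = as.list(rx$constants),
           sat = rx$sat, lin = rx$lin)),
    parameter_names = as.list(net$parameter_names),
    dose_species = net$dose_species, damage_species = net$damage_species,
    params = params)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       na = "null", null = "null")
  invisible(path)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::read_json(path)
  to_chr <- function(x) if (is.null(x) || length(x) == 0) NA_character_
    else as.character(x)
  reactions <- lapply(obj$reactions, function(rx) {
    to_stoich <- function(x) {
      if (length(x) == 0) return(NULL)
      stats::setNames(as.integer(unlist(x)), names(x))
    }
    reaction(rx$id, reactants = to_stoich(rx$reactants),
             products = to_stoich(rx$products),
             modifiers = as.character(unlist(rx$modifiers)),
             rate_law = rx$rate_law,
             constants = as.character(unlist(rx$constants)),
             sat = to_chr(rx$sat), lin = to_chr(rx$lin))
  })
  species <- tibble::tibble(
    name = vapply(obj$species, `[[`, "", "name"),
    initial_concentration = vapply(obj$species, `[[`, 0,
                                   "initial_concentration"),
    clamped = vapply(obj$species, `[[`, TRUE, "clamped"))
  net <- reaction_network(
    species, reactions,
    parameter_names = as.character(unlist(obj$parameter_names)),
    dose_species = to_chr(obj$dose_species),
    damage_species = to_chr(obj$damage_species))
  net <- detect_reference_topology(net)
  params <- if (is.null(obj$params)) NULL else
    stats::setNames(as.numeric(unlist(obj$params)), names(obj$params))
  list(network = net, params = params)
}
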