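# Model-definition file: a sectioned tab-separated text format holding the
# rate table, the species table and the reaction table (each reaction as a
# (BCR, coefficient) pair plus reactant/product terms), with a round-trip
# guarantee. An SBML Level 3 export is provided for interchange.

fmt_side <- function(v) {
  if (!length(v)) return("-")
  paste(paste0(ifelse(v == 1, "", paste0(v, "*")), names(v)), collapse = " + ")
}

parse_side <- function(s) {
  s <- trimws(s)
  if (s == "-" || s == "") return(numeric(0))
  terms <- strsplit(s, "\\+")[[1]]
  out <- numeric(0)
  for (tm in terms) {
    tm <- trimws(tm)
    if (grepl("\\*", tm)) {
      parts <- strsplit(tm, "\\*")[[1]]
      out[trimws(parts[2])] <- as.numeric(parts[1])
    } else out[tm] <- 1
  }
  out
}

#' Serialize a model to a text file
#'
#' @param model an \code{iir_model}
#' @param path output path
#' @export
serialize_model <- function(model, path) {
  con <- file(path, "w"); on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("# iir model definition")
  w("# reconstruction of the dsRNA-stimulated innate-immune cross-talk")
  w("# network; species beyond the published simplified schematic are")
  w("# reconstruction intermediates (adapters, phospho-forms, the IRF3")
  w("# dimer, constitutive receptor mRNAs, endosomal dsRNA, secreted IFNb).")
  w("# coefficients are this package's own calibration of the network.")
  w("name\t", model$metadata$name)
  w("version\t", model$metadata$version)
  w("[rates]")
  for (nm in names(model$rate_table))
    w(nm, "\t", format(model$rate_table[[nm]], digits = 17))
  w("[species]")
  w("name\tcompartment\trole\tinitial_count")
  for (i in seq_len(nrow(model$species)))
    w(model$species$name[i], "\t", model$species$compartment[i], "\t",
      model$species$role[i], "\t", model$species$initial_count[i])
  w("[reactions]")
  w("id\tbcr\tcoef\treactants\tproducts")
  for (r in model$reactions)
    w(r$id, "\t", r$bcr, "\t", format(r$coef, digits = 17), "\t",
      fmt_side(r$reactants), "\t", fmt_side(r$products))
  invisible(path)
}

#' Deserialize a model from a text file
#'
#' @param path file written by [serialize_model()]
#' @return an \code{iir_model}; malformed files raise an error naming the
#'   offending line
#' @export
deserialize_model <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  sec <- ""
  meta <- list(name = "model", version = "1")
  rates <- list(); sp <- list(); rx <- list()
  header_skipped <- FALSE
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln))) next
    if (grepl("^\\[", ln)) {
      sec <- gsub("[][]", "", trimws(ln)); header_skipped <- FALSE
      next
    }
    f <- strsplit(ln, "\t")[[1]]
    if (sec == "") {
      if (length(f) != 2) stop("malformed metadata at line ", i, ": ", ln)
      meta[[f[1]]] <- f[2]
    } else if (sec == "rates") {
      if (length(f) != 2) stop("malformed rate entry at line ", i, ": ", ln)
      rates[[f[1]]] <- as.numeric(f[2])
    } else if (sec == "species") {
      if (!header_skipped && f[1] == "name") { header_skipped <- TRUE; next }
      if (length(f) != 4) stop("malformed species at line ", i, ": ", ln)
      sp[[length(sp) + 1L]] <- new_species(f[1], f[2], f[3], as.numeric(f[4]))
    } else if (sec == "reactions") {
      if (!header_skipped && f[1] == "id") { header_skipped <- TRUE; next }
      if (length(f) != 5) stop("malformed reaction at line ", i, ": ", ln)
      rx[[length(rx) + 1L]] <- reaction(f[1], parse_side(f[4]),
                                        parse_side(f[5]), f[2],
                                        as.numeric(f[3]))
    } else stop("unknown section [", sec, "] at line ", i)
  }
  rates <- do.call(bcr_table, rates)
  model <- structure(list(species = do.call(rbind, sp), reactions = rx,
                          rate_table = rates,
                          metadata = list(name = meta$name,
                                          version = meta$version)),
                     class = "iir_model")
  # referential integrity: every reaction species must exist
  validate_model(model)
  model
}

#' Export a model to SBML Level 3
#'
#' Mass-action kinetic laws; species are amounts (molecule counts) in one
#' of three compartments. Requires the xml2 package.
#'
#' @param model an \code{iir_model}
#' @param path output path (.xml)
#' @export
export_sbml <- function(model, path) {
  if (!requireNamespace("xml2", quietly = TRUE))
    stop("SBML export requires the xml2 package")
  doc <- xml2::xml_new_root(
    "sbml", xmlns = "http://www.sbml.org/sbml/level3/version2/core",
    level = "3", version = "2")
  mdl <- xml2::xml_add_child(doc, "model",
                             id = gsub("[^A-Za-z0-9_]", "_",
                                       model$metadata$name))
  lc <- xml2::xml_add_child(mdl, "listOfCompartments")
  comps <- unique(model$species$compartment)
  comp_id <- function(x) gsub("[^A-Za-z0-9_]", "_", x)
  for (cp in comps)
    xml2::xml_add_child(lc, "compartment", id = comp_id(cp), size = "1",
                        constant = "true")
  ls <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model$species)))
    xml2::xml_add_child(
      ls, "species", id = model$species$name[i],
      compartment = comp_id(model$species$compartment[i]),
      initialAmount = as.character(model$species$initial_count[i]),
      hasOnlySubstanceUnits = "true", boundaryCondition = "false",
      constant = "false")
  lp <- xml2::xml_add_child(mdl, "listOfParameters")
  lr <- xml2::xml_add_child(mdl, "listOfReactions")
  for (r in model$reactions) {
    k <- effective_rate(r, model$rate_table)
    pid <- paste0("k_", r$id)
    xml2::xml_add_child(lp, "parameter", id = pid, value = format(k, digits = 17),
                        constant = "true")
    rn <- xml2::xml_add_child(lr, "reaction", id = r$id, reversible = "false")
    if (length(r$reactants)) {
      lre <- xml2::xml_add_child(rn, "listOfReactants")
      for (s in names(r$reactants))
        xml2::xml_add_child(lre, "speciesReference", species = s,
                            stoichiometry = as.character(r$reactants[[s]]),
                            constant = "true")
    }
    if (length(r$products)) {
      lpr <- xml2::xml_add_child(rn, "listOfProducts")
      for (s in names(r$products))
        xml2::xml_add_child(lpr, "speciesReference", species = s,
                            stoichiometry = as.character(r$products[[s]]),
                            constant = "true")
    }
    kl <- xml2::xml_add_child(rn, "kineticLaw")
    math <- xml2::xml_add_child(kl, "math",
                                xmlns = "http://www.w3.org/1998/Math/MathML")
    # k * prod(reactants)
    terms <- c(pid, rep(names(r$reactants), times = r$reactants))
    if (length(terms) == 1) {
      xml2::xml_add_child(math, "ci", terms)
    } else {
      ap <- xml2::xml_add_child(math, "apply")
      xml2::xml_add_child(ap, "times")
      for (tm in terms) xml2::xml_add_child(ap, "ci", tm)
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
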