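# Lipid species nomenclature: parsing, validation, classification.
#
# Annotations follow the shotgun-lipidomics shorthand
#   "Class - Carbons:Unsaturations:Hydroxylations"
# with one triple for sphingolipids and sterol esters (totals over the
# molecule) and ";"-separated per-chain triples for glycerophospholipids
# (two), DAG (two), TAG (three) and cardiolipin (four). Sphingolipid rows may
# carry a parenthetical fatty-acid alias such as "(C14:0 Cer)" which is
# checked against the totals assuming a d18:1;2 sphingoid base.

.lipid_class_registry <- function() {
  reg <- list(
    list(token = "Cer",     long = "Ceramide",                          category = "sphingolipid",        n_chains = 1L, ether = FALSE),
    list(token = "HexCer",  long = "Hexosylceramide",                   category = "sphingolipid",        n_chains = 1L, ether = FALSE),
    list(token = "SM",      long = "Sphingomyelin",                     category = "sphingolipid",        n_chains = 1L, ether = FALSE),
    list(token = "PC",      long = "Phosphatidylcholine",               category = "glycerophospholipid", n_chains = 2L, ether = FALSE),
    list(token = "PC O-",   long = "Phosphatidylcholine ether",         category = "glycerophospholipid", n_chains = 2L, ether = TRUE),
    list(token = "PE",      long = "Phosphatidylethanolamine",          category = "glycerophospholipid", n_chains = 2L, ether = FALSE),
    list(token = "PE O-",   long = "Phosphatidylethanolamine ether",    category = "glycerophospholipid", n_chains = 2L, ether = TRUE),
    list(token = "PA",      long = c("Phosphatidic acid", "Phosphatidate"), category = "glycerophospholipid", n_chains = 2L, ether = FALSE),
    list(token = "PG",      long = "Phosphatidylglycerol",              category = "glycerophospholipid", n_chains = 2L, ether = FALSE),
    list(token = "PI",      long = "Phosphatidylinositol",              category = "glycerophospholipid", n_chains = 2L, ether = FALSE),
    list(token = "PS",      long = "Phosphatidylserine",                category = "glycerophospholipid", n_chains = 2L, ether = FALSE),
    list(token = "LPA",     long = c("Lysophosphatidic acid", "Lysophosphatidate"), category = "glycerophospholipid", n_chains = 1L, ether = FALSE),
    list(token = "LPC",     long = "Lysophosphatidylcholine",           category = "glycerophospholipid", n_chains = 1L, ether = FALSE),
    list(token = "LPC O-",  long = "Lysophosphatidylcholine ether",     category = "glycerophospholipid", n_chains = 1L, ether = TRUE),
    list(token = "LPE",     long = "Lysophosphatidylethanolamine",      category = "glycerophospholipid", n_chains = 1L, ether = FALSE),
    list(token = "LPE O-",  long = "Lysophosphatidylethanolamine ether", category = "glycerophospholipid", n_chains = 1L, ether = TRUE),
    list(token = "LPG",     long = "Lysophosphatidylglycerol",          category = "glycerophospholipid", n_chains = 1L, ether = FALSE),
    list(token = "LPI",     long = "Lysophosphatidylinositol",          category = "glycerophospholipid", n_chains = 1L, ether = FALSE),
    list(token = "LPS",     long = "Lysophosphatidylserine",            category = "glycerophospholipid", n_chains = 1L, ether = FALSE),
    list(token = "DAG",     long = "Diacylglycerol",                    category = "glycerolipid",        n_chains = 2L, ether = FALSE),
    list(token = "TAG",     long = "Triacylglycerol",                   category = "glycerolipid",        n_chains = 3L, ether = FALSE),
    list(token = "CL",      long = "Cardiolipin",                       category = "glycerophospholipid", n_chains = 4L, ether = FALSE),
    list(token = "CE",      long = c("Cholesterol ester", "Cholesteryl ester"), category = "sterol",      n_chains = 1L, ether = FALSE),
    list(token = "Chol",    long = "Cholesterol",                       category = "sterol",              n_chains = 0L, ether = FALSE)
  )
  names(reg) <- vapply(reg, `[[`, "", "token")
  reg
}

.lipid_registry <- .lipid_class_registry()

#' Known lipid class tokens
#'
#' @return Character vector of the short class tokens the parser accepts
#'   (e.g. `"Cer"`, `"PC"`, `"PC O-"`, `"TAG"`).
#' @export
lipid_classes <- function() names(.lipid_registry)

#' Construct a chain descriptor
#'
#' A chain descriptor holds carbon count, number of unsaturations (double
#' bonds) and number of hydroxylations of either a single fatty-acid moiety
#' or, for sphingolipids, the whole molecule.
#'
#' @param carbons,unsaturations,hydroxylations Non-negative integer counts.
#' @return Object of class `chain_descriptor` (named integer vector).
#' @export
chain_descriptor <- function(carbons, unsaturations, hydroxylations = 0L) {
  x <- c(carbons = as.integer(carbons), unsaturations = as.integer(unsaturations),
         hydroxylations = as.integer(hydroxylations))
  if (any(is.na(x)) || any(x < 0))
    stop("chain descriptor counts must be non-negative integers")
  if (x["carbons"] > 0 && x["unsaturations"] >= x["carbons"])
    stop(sprintf("chain %d:%d:%d has at least as many unsaturations as carbons",
                 x["carbons"], x["unsaturations"], x["hydroxylations"]))
  class(x) <- "chain_descriptor"
  x
}

.format_chain <- function(ch) sprintf("%d:%d:%d", ch[1L], ch[2L], ch[3L])

.parse_chain_triple <- function(txt, context) {
  parts <- strsplit(trimws(txt), ":", fixed = TRUE)[[1L]]
  if (length(parts) != 3L || anyNA(suppressWarnings(as.integer(parts))))
    stop(sprintf("cannot parse chain descriptor '%s' in '%s'", txt, context))
  chain_descriptor(as.integer(parts[1L]), as.integer(parts[2L]), as.integer(parts[3L]))
}

#' Parse a lipid species annotation
#'
#' Accepts both the long class spelling ("Phosphatidylcholine") and the short
#' token ("PC"), an en dash or hyphen between class and chains, ";"-separated
#' per-chain descriptors, and an optional parenthetical sphingolipid alias
#' (e.g. "(C14:0 Cer)") which is verified against the totals under a d18:1;2
#' sphingoid base.
#'
#' @param text Annotation string (or character vector; a list is returned for
#'   more than one element).
#' @return A `lipid_species` object: list with elements `lipid_class`
#'   (short token), `chains` (list of [chain_descriptor()]), `ether_flag`,
#'   `category` and `raw_annotation`.
#' @examples
#' parse_species_annotation("Ceramide - 32:1:2 (C14:0 Cer)")
#' parse_species_annotation("PC - 17:0:0;17:1:0")
#' @export
parse_species_annotation <- function(text) {
  if (length(text) > 1L) return(lapply(text, parse_species_annotation))
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(trimws(text)))
    stop("annotation must be a non-empty string")
  raw <- text
  s <- trimws(text)

  # optional parenthetical alias
  alias <- NULL
  m <- regmatches(s, regexec("\\(([^()]*)\\)\\s*$", s))[[1L]]
  if (length(m) == 2L) {
    alias <- trimws(m[2L])
    s <- trimws(sub("\\([^()]*\\)\\s*$", "", s))
  }

  # class name: longest match first so "PC O-" wins over "PC"
  reg <- .lipid_registry
  all_names <- unname(unlist(lapply(reg, function(r) c(r$long, r$token))))
  all_tokens <- rep(names(reg), vapply(reg, function(r) length(r$long) + 1L, 0L))
  ord <- order(nchar(all_names), decreasing = TRUE)
  cls <- NULL
  rest <- NULL
  for (i in ord) {
    nm <- all_names[i]
    if (identical(tolower(substr(s, 1L, nchar(nm))), tolower(nm))) {
      tail_txt <- substr(s, nchar(nm) + 1L, nchar(s))
      if (nzchar(trimws(tail_txt)) && !grepl("^\\s*[–—-]", tail_txt)) next
      cls <- all_tokens[i]
      rest <- trimws(sub("^\\s*[–—-]\\s*", "", tail_txt))
      break
    }
  }
  if (is.null(cls))
    stop(sprintf("unknown lipid class in annotation '%s'", raw))
  info <- reg[[cls]]

  chains <- list()
  if (nzchar(rest)) {
    chains <- lapply(strsplit(rest, ";", fixed = TRUE)[[1L]], .parse_chain_triple, context = raw)
  }
  if (length(chains) != info$n_chains)
    stop(sprintf("class %s expects %d chain descriptor(s) but '%s' has %d",
                 cls, info$n_chains, raw, length(chains)))

  sp <- structure(list(lipid_class = cls, chains = chains,
                       ether_flag = info$ether, category = info$category,
                       raw_annotation = raw),
                  class = "lipid_species")

  if (!is.null(alias)) {
    if (info$category != "sphingolipid")
      stop(sprintf("alias '(%s)' on non-sphingolipid annotation '%s'", alias, raw))
    am <- regmatches(alias, regexec("^C(\\d+):(\\d+)", alias))[[1L]]
    if (length(am) != 3L)
      stop(sprintf("cannot parse sphingolipid alias '(%s)' in '%s'", alias, raw))
    fa <- sphingolipid_fa_chain(chains[[1L]])
    if (fa["carbons"] != as.integer(am[2L]) || fa["unsaturations"] != as.integer(am[3L]))
      stop(sprintf("alias 'C%s:%s' inconsistent with totals %s (implies C%d:%d) in '%s'",
                   am[2L], am[3L], .format_chain(chains[[1L]]),
                   fa["carbons"], fa["unsaturations"], raw))
  }
  sp
}

#' @export
print.lipid_species <- function(x, ...) {
  cat(sprintf("<lipid_species> %s  [%s%s]\n", format_species(x), x$category,
              if (x$ether_flag) ", ether" else ""))
  invisible(x)
}

#' Canonical annotation string of a lipid species
#'
#' The canonical form is `"<token> - <c>:<u>:<h>[;...]"`; it round-trips
#' through [parse_species_annotation()] and is the identity used when
#' intersecting discriminant sets across experiments.
#'
#' @param species A `lipid_species` or list of them.
#' @return Character vector of canonical annotations.
#' @export
format_species <- function(species) {
  if (inherits(species, "lipid_species")) species <- list(species)
  vapply(species, function(sp) {
    if (length(sp$chains) == 0L) return(sp$lipid_class)
    paste0(sp$lipid_class, " - ",
           paste(vapply(sp$chains, .format_chain, ""), collapse = ";"))
  }, "")
}

#' Fatty-acid chain of a sphingolipid from molecular totals
#'
#' Sphingolipid annotations give totals over the molecule; subtracting the
#' sphingoid base (default d18:1 with 2 hydroxylations) recovers the
#' fatty-acid moiety, e.g. total 32:1:2 implies a C14:0 fatty acid.
#'
#' @param total [chain_descriptor()] of molecular totals.
#' @param base Sphingoid base; default `chain_descriptor(18, 1, 2)`.
#' @return [chain_descriptor()] of the fatty-acid moiety.
#' @export
sphingolipid_fa_chain <- function(total, base = chain_descriptor(18L, 1L, 2L)) {
  d <- unclass(total) - unclass(base)
  if (any(d < 0))
    stop(sprintf("totals %s are smaller than the sphingoid base %s",
                 .format_chain(total), .format_chain(base)))
  structure(c(carbons = d[["carbons"]], unsaturations = d[["unsaturations"]],
              hydroxylations = d[["hydroxylations"]]),
            class = "chain_descriptor")
}

#' Lipid category of a species
#'
#' Deterministic class-to-category mapping: Cer/HexCer/SM are sphingolipids;
#' PA/PC/PE/PG/PI/PS plus their ether and lyso forms (and cardiolipin) are
#' glycerophospholipids; DAG/TAG are glycerolipids; CE/Chol are sterols.
#'
#' @param species A `lipid_species`, a list of them, or annotation strings.
#' @return Character vector of categories.
#' @export
classify_category <- function(species) {
  if (is.character(species)) species <- parse_species_annotation(species)
  if (inherits(species, "lipid_species")) species <- list(species)
  vapply(species, `[[`, "", "category")
}

#' Class and category composition of a species list
#'
#' Counts are over unique species (canonical annotation); duplicates are
#' counted once. Category counts always partition the unique species.
#'
#' @param species_list Annotation strings or `lipid_species` objects.
#' @return List with `n_unique`, `class_counts` (named integer vector) and
#'   `category_counts`.
#' @export
tabulate_composition <- function(species_list) {
  if (length(species_list) == 0L)
    return(list(n_unique = 0L, class_counts = integer(0), category_counts = integer(0)))
  if (is.character(species_list)) species_list <- parse_species_annotation(species_list)
  if (inherits(species_list, "lipid_species")) species_list <- list(species_list)
  keys <- format_species(species_list)
  keep <- !duplicated(keys)
  sp <- species_list[keep]
  cls <- vapply(sp, `[[`, "", "lipid_class")
  cat <- vapply(sp, `[[`, "", "category")
  list(n_unique = length(sp),
       class_counts = c(table(cls)),
       category_counts = c(table(cat)))
}

#' Read a one-annotation-per-line species list file
#'
#' Blank lines and lines starting with `#` are ignored.
#'
#' @param path Text file path.
#' @return Character vector of annotations.
#' @export
read_species_list <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}
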