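# Precursor map: which glucose-derived precursor molecule each amino-acid
# carbon comes from.  The map itself is data (inst/extdata/precursor_map.tsv),
# reviewed against standard E. coli biosynthesis; this file only loads,
# validates and queries it.

.fracnmr_cache <- new.env(parent = emptyenv())

TCA_FAMILIES <- c("oxaloacetate", "2-oxoglutarate")

#' Load the amino-acid carbon precursor map
#'
#' Returns the package's table of carbon precursor origins: one row per
#' carbon site with its precursor molecule id (scoped within the residue),
#' pathway family and carbon index within the precursor, plus the covalent
#' carbon-bond list used for validation.  Carbons sharing a molecule id are
#' co-labeled under fractional labeling; bonded carbons of one molecule with
#' adjacent precursor indices form the intact-bond set.
#'
#' @param path optional path to an alternative map TSV (same columns);
#'   default is the table shipped with the package.
#' @return a list with elements `sites` (data.frame: residue, atom,
#'   molecule, family, precursor_carbon) and `bonds` (data.frame: residue,
#'   atom1, atom2).
#' @export
pathway_map <- function(path = NULL) {
  if (is.null(path) && !is.null(.fracnmr_cache$map)) return(.fracnmr_cache$map)
  site_path <- path %||% system.file("extdata", "precursor_map.tsv",
                                     package = "fracnmr", mustWork = TRUE)
  bond_path <- system.file("extdata", "carbon_bonds.tsv",
                           package = "fracnmr", mustWork = TRUE)
  sites <- utils::read.delim(site_path, comment.char = "#",
                             stringsAsFactors = FALSE)
  bonds <- utils::read.delim(bond_path, comment.char = "#",
                             stringsAsFactors = FALSE)
  map <- list(sites = sites, bonds = bonds)
  validate_pathway_map(map)
  if (is.null(path)) .fracnmr_cache$map <- map
  map
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_pathway_map <- function(map) {
  s <- map$sites
  if (anyDuplicated(paste(s$residue, s$atom))) {
    abort_fracnmr("duplicate carbon site in precursor map", "fracnmr_bad_map")
  }
  if (!setequal(unique(s$residue), AA3)) {
    abort_fracnmr("precursor map must cover exactly the 20 standard residues",
                  "fracnmr_bad_map")
  }
  # every bond endpoint must be a mapped site; same-molecule bonded pairs
  # must have adjacent precursor carbons
  b <- map$bonds
  key <- paste(s$residue, s$atom)
  for (i in seq_len(nrow(b))) {
    k1 <- paste(b$residue[i], b$atom1[i]); k2 <- paste(b$residue[i], b$atom2[i])
    if (!(k1 %in% key) || !(k2 %in% key)) {
      abort_fracnmr(sprintf("bond %s %s-%s references unmapped atom",
                            b$residue[i], b$atom1[i], b$atom2[i]),
                    "fracnmr_bad_map")
    }
    s1 <- s[key == k1, ]; s2 <- s[key == k2, ]
    if (s1$molecule == s2$molecule &&
        abs(s1$precursor_carbon - s2$precursor_carbon) != 1L) {
      abort_fracnmr(sprintf("non-adjacent same-molecule bond %s %s-%s",
                            b$residue[i], b$atom1[i], b$atom2[i]),
                    "fracnmr_bad_map")
    }
  }
  invisible(TRUE)
}

# Carbon sites of one residue type, ordered as in the map.
residue_sites <- function(aa_type, map = pathway_map()) {
  aa <- aa_three(aa_type)
  map$sites[map$sites$residue == aa, , drop = FALSE]
}

#' Covalent carbon-carbon bonds of a residue type
#'
#' @param aa_type residue type (one- or three-letter code).
#' @param map precursor map, see [pathway_map()].
#' @return data.frame with columns `atom1`, `atom2`, and logical `intact`
#'   marking bonds whose carbons derive from adjacent carbons of a single
#'   precursor molecule.
#' @export
carbon_bonds <- function(aa_type, map = pathway_map()) {
  aa <- aa_three(aa_type)
  b <- map$bonds[map$bonds$residue == aa, c("atom1", "atom2"), drop = FALSE]
  s <- residue_sites(aa, map)
  m1 <- s$molecule[match(b$atom1, s$atom)]
  m2 <- s$molecule[match(b$atom2, s$atom)]
  b$intact <- m1 == m2
  rownames(b) <- NULL
  b
}

#' Is a carbon-carbon bond intact under fractional labeling?
#'
#' A bond is intact when both carbons derive from one precursor molecule, so
#' they are 13C-labeled or unlabeled together (before any TCA scrambling).
#'
#' @inheritParams carbon_bonds
#' @param atom1,atom2 atom names (e.g. `"CA"`, `"CB"`).
#' @return logical scalar.
#' @export
is_intact_bond <- function(aa_type, atom1, atom2, map = pathway_map()) {
  b <- carbon_bonds(aa_type, map)
  hit <- (b$atom1 == atom1 & b$atom2 == atom2) |
         (b$atom1 == atom2 & b$atom2 == atom1)
  if (!any(hit)) {
    abort_fracnmr(sprintf(
      "no carbon-carbon bond %s-%s in %s; valid bonds: %s",
      atom1, atom2, aa_three(aa_type),
      paste(paste0(b$atom1, "-", b$atom2), collapse = ", ")),
      "fracnmr_unknown_bond")
  }
  b$intact[hit][1]
}
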