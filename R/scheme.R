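#' Fractional 13C labeling scheme
#'
#' Describes an isotope dilution experiment in which cells grow on a mixture
#' of U-13C6 glucose and unlabeled glucose as sole carbon source.  Every
#' glucose-derived precursor molecule is then either fully 13C-labeled (with
#' probability `f_labeled * isotopic_purity`) or carries 13C only at natural
#' abundance, independently per carbon.
#'
#' @param f_labeled molar fraction of U-13C6 glucose in the carbon source,
#'   in \[0, 1\].  The classic fractional scheme uses 0.2.
#' @param nat_abund 13C natural abundance fraction (default 0.011).
#' @param scramble TCA-cycle bond-scrambling parameter in \[0, 1\] applied
#'   to oxaloacetate- and 2-oxoglutarate-derived precursor units: with
#'   probability `scramble` such a unit loses its intact bonds and its
#'   carbons are labeled independently.  Default 0.5; the true value depends
#'   on aeration during expression and is not identifiable from the scheme
#'   alone.
#' @param isotopic_purity 13C enrichment of the labeled glucose
#'   (default 0.99).
#'
#' @return an object of class `labeling_scheme`.
#' @examples
#' labeling_scheme(0.2)
#' labeling_scheme(1, nat_abund = 0, isotopic_purity = 1)  # uniform labeling
#' @export
labeling_scheme <- function(f_labeled, nat_abund = 0.011, scramble = 0.5,
                            isotopic_purity = 0.99) {
  stopifnot_prob(f_labeled, "f_labeled")
  stopifnot_prob(nat_abund, "nat_abund")
  stopifnot_prob(scramble, "scramble")
  stopifnot_prob(isotopic_purity, "isotopic_purity")
  structure(
    list(f_labeled = f_labeled, nat_abund = nat_abund,
         scramble = scramble, isotopic_purity = isotopic_purity),
    class = "labeling_scheme"
  )
}

#' @export
print.labeling_scheme <- function(x, ...) {
  cat(sprintf(
    "<labeling_scheme> f_labeled=%.4g nat_abund=%.4g scramble=%.4g purity=%.4g\n",
    x$f_labeled, x$nat_abund, x$scramble, x$isotopic_purity))
  invisible(x)
}

as_labeling_scheme <- function(x) {
  if (inherits(x, "labeling_scheme")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(labeling_scheme(x))
  if (is.list(x)) return(do.call(labeling_scheme, x))
  abort_fracnmr("cannot interpret object as a labeling scheme",
                "fracnmr_invalid_scheme")
}
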