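# Internal helpers shared across modules.

# Typed condition constructor so callers can distinguish error classes
# (e.g. tryCatch(..., fracnmr_unknown_residue = ...)).
abort_fracnmr <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "fracnmr_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")
AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
         "F", "P", "S", "T", "W", "Y", "V")

#' Normalize an amino-acid type to a three-letter code
#'
#' Accepts one-letter or three-letter codes in any case and returns the
#' upper-case three-letter code, erroring (class
#' `fracnmr_unknown_residue`) on anything else.
#'
#' @param aa character scalar, e.g. `"Ala"`, `"ALA"` or `"A"`.
#' @return upper-case three-letter residue code.
#' @export
aa_three <- function(aa) {
  if (!is.character(aa) || length(aa) != 1L || is.na(aa)) {
    abort_fracnmr("residue type must be a single character string",
                  "fracnmr_unknown_residue")
  }
  x <- toupper(trimws(aa))
  if (x %in% AA3) return(x)
  if (nchar(x) == 1L && x %in% AA1) return(AA3[match(x, AA1)])
  abort_fracnmr(sprintf("unknown residue type '%s'", aa),
                "fracnmr_unknown_residue")
}

stopifnot_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort_fracnmr(sprintf("'%s' must be a single number in [0, 1]", name),
                  "fracnmr_invalid_scheme")
  }
}

# Write a data.frame as CSV preceded by '# key: value' provenance lines.
write_csv_meta <- function(df, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(list(tool = paste0("fracnmr ",
                               as.character(utils::packageVersion("fracnmr")))),
            meta)
  for (k in names(meta)) {
    writeLines(sprintf("# %s: %s", k, paste(meta[[k]], collapse = " ")), con)
  }
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

# Read a CSV written by write_csv_meta (comment lines ignored).
read_csv_meta <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

# Derive a child seed from a base seed and a stream label, staying below
# 2^31 so it is a valid R integer.
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}
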