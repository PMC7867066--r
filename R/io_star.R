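# Minimal NMR-STAR v3 chemical-shift loop reader/writer.  Only the
# atom-chemical-shift loop subset is supported: enough to carry BMRB-style
# assigned shift tables; unknown tags are ignored.

#' Read a chemical-shift table from a minimal NMR-STAR v3 file
#'
#' Finds the first `loop_` whose tags include `_Atom_chem_shift.Seq_ID`,
#' `_Atom_chem_shift.Comp_ID`, `_Atom_chem_shift.Atom_ID` and
#' `_Atom_chem_shift.Val` and parses its data rows (whitespace-separated
#' tokens, one row per line) until `stop_`.
#'
#' @param path path to an NMR-STAR text file.
#' @return data.frame of class `shift_table`: residue, restype, atom,
#'   shift_ppm, ambiguity (NA when the tag is absent).
#' @export
read_nmrstar_shifts <- function(path) {
  lines <- readLines(path, warn = FALSE)
  strip <- trimws(lines)
  loop_starts <- which(strip == "loop_")
  if (!length(loop_starts)) {
    abort_fracnmr(sprintf("%s: no loop_ found", path), "fracnmr_parse_error")
  }
  for (ls in loop_starts) {
    i <- ls + 1L
    tags <- character()
    while (i <= length(strip) && startsWith(strip[i], "_")) {
      tags <- c(tags, strip[i])
      i <- i + 1L
    }
    need <- paste0("_Atom_chem_shift.",
                   c("Seq_ID", "Comp_ID", "Atom_ID", "Val"))
    if (!all(need %in% tags)) next
    rows <- list()
    while (i <= length(strip) && strip[i] != "stop_") {
      if (nzchar(strip[i]) && !startsWith(strip[i], "#")) {
        tok <- strsplit(strip[i], "[[:space:]]+")[[1]]
        if (length(tok) != length(tags)) {
          abort_fracnmr(sprintf(
            "%s line %d: %d tokens for %d loop tags", path, i,
            length(tok), length(tags)), "fracnmr_parse_error")
        }
        rows[[length(rows) + 1L]] <- stats::setNames(as.list(tok), tags)
      }
      i <- i + 1L
    }
    if (!length(rows)) {
      abort_fracnmr(sprintf("%s: chemical-shift loop has no data rows", path),
                    "fracnmr_parse_error")
    }
    get <- function(tag) vapply(rows, function(r) r[[tag]], character(1))
    val <- suppressWarnings(as.numeric(get("_Atom_chem_shift.Val")))
    if (any(is.na(val))) {
      bad <- which(is.na(val))[1]
      abort_fracnmr(sprintf(
        "%s: malformed shift value '%s' in loop row %d", path,
        get("_Atom_chem_shift.Val")[bad], bad), "fracnmr_parse_error")
    }
    amb_tag <- "_Atom_chem_shift.Ambiguity_code"
    amb <- if (amb_tag %in% tags) {
      suppressWarnings(as.integer(get(amb_tag)))
    } else NA_integer_
    out <- data.frame(
      residue = as.integer(get("_Atom_chem_shift.Seq_ID")),
      restype = vapply(get("_Atom_chem_shift.Comp_ID"), aa_three,
                       character(1), USE.NAMES = FALSE),
      atom = get("_Atom_chem_shift.Atom_ID"),
      shift_ppm = val,
      ambiguity = amb,
      stringsAsFactors = FALSE)
    if (anyDuplicated(paste(out$residue, out$atom))) {
      abort_fracnmr(sprintf("%s: duplicate (residue, atom) in shift loop",
                            path), "fracnmr_parse_error")
    }
    class(out) <- c("shift_table", "data.frame")
    return(out)
  }
  abort_fracnmr(sprintf(
    "%s: no loop with the _Atom_chem_shift tags (Seq_ID, Comp_ID, Atom_ID, Val)",
    path), "fracnmr_parse_error")
}

#' Write a chemical-shift table as a minimal NMR-STAR v3 loop
#'
#' @param shifts a `shift_table` (see [read_nmrstar_shifts()]).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_nmrstar_shifts <- function(shifts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("data_fracnmr_shifts", "", "save_assigned_chemical_shifts",
               "   loop_",
               "      _Atom_chem_shift.Seq_ID",
               "      _Atom_chem_shift.Comp_ID",
               "      _Atom_chem_shift.Atom_ID",
               "      _Atom_chem_shift.Val",
               "      _Atom_chem_shift.Ambiguity_code"), con)
  amb <- shifts$ambiguity
  amb <- ifelse(is.na(amb), ".", as.character(amb))
  writeLines(sprintf("      %d %s %s %.3f %s", shifts$residue,
                     shifts$restype, shifts$atom, shifts$shift_ppm, amb), con)
  writeLines(c("   stop_", "save_"), con)
  invisible(path)
}
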