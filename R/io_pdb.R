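# Minimal text PDB reader/writer for multi-model ensembles (ATOM, MODEL,
# ENDMDL records; column-based format).  No mmCIF support.

#' Read a PDB file as an ensemble of conformers
#'
#' Parses ATOM records; MODEL/ENDMDL blocks delimit conformers, a file
#' without MODEL records yields a single conformer.  Alternate locations:
#' for each (residue, atom) the highest-occupancy altloc is kept, ties
#' broken by first occurrence.  HETATM records are ignored.
#'
#' @param path path to a PDB text file.
#' @param chain optional chain id filter (default: all chains; distinct
#'   chains keep distinct residue numbers as given by the author).
#' @return list of [conformer()] objects (class `ensemble`).
#' @export
read_pdb <- function(path, chain = NULL) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1L, 6L)
  model_id <- 1L
  cur <- integer(length(lines))
  mid <- 1L
  for (i in seq_along(lines)) {
    if (startsWith(rec[i], "MODEL")) {
      mid <- suppressWarnings(as.integer(substr(lines[i], 11L, 14L)))
      if (is.na(mid)) mid <- model_id
      model_id <- mid
    }
    cur[i] <- model_id
  }
  atom_idx <- which(rec == "ATOM  ")
  if (!length(atom_idx)) {
    abort_fracnmr("no ATOM records in PDB file", "fracnmr_parse_error")
  }
  al <- lines[atom_idx]
  df <- data.frame(
    model = cur[atom_idx],
    atom = trimws(substr(al, 13L, 16L)),
    altloc = substr(al, 17L, 17L),
    restype = trimws(substr(al, 18L, 20L)),
    chain = substr(al, 22L, 22L),
    resno = as.integer(substr(al, 23L, 26L)),
    x = as.numeric(substr(al, 31L, 38L)),
    y = as.numeric(substr(al, 39L, 46L)),
    z = as.numeric(substr(al, 47L, 54L)),
    occ = suppressWarnings(as.numeric(substr(al, 55L, 60L))),
    stringsAsFactors = FALSE)
  df$occ[is.na(df$occ)] <- 1
  if (!is.null(chain)) df <- df[df$chain %in% chain, , drop = FALSE]
  if (!nrow(df)) {
    abort_fracnmr("no ATOM records left after chain filter",
                  "fracnmr_parse_error")
  }
  ens <- lapply(split(df, df$model), function(m) {
    # altloc: keep highest occupancy, then first occurrence
    m$ord <- seq_len(nrow(m))
    m <- m[order(paste(m$chain, m$resno, m$atom), -m$occ, m$ord), , drop = FALSE]
    m <- m[!duplicated(paste(m$chain, m$resno, m$atom)), , drop = FALSE]
    m <- m[order(m$ord), , drop = FALSE]
    rownames(m) <- NULL
    conformer(m[, c("resno", "restype", "atom", "x", "y", "z")],
              model = m$model[1], chain = m$chain[1])
  })
  names(ens) <- NULL
  structure(ens, class = "ensemble")
}

#' Write an ensemble (or single conformer) as a multi-model PDB file
#'
#' @param ensemble list of conformers or a single conformer.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_pdb <- function(ensemble, path) {
  if (inherits(ensemble, "conformer")) ensemble <- list(ensemble)
  con <- file(path, "w")
  on.exit(close(con))
  serial <- 0L
  for (m in seq_along(ensemble)) {
    cf <- ensemble[[m]]
    if (length(ensemble) > 1L) writeLines(sprintf("MODEL     %4d", m), con)
    for (i in seq_len(nrow(cf))) {
      serial <- serial + 1L
      an <- cf$atom[i]
      # atom-name column alignment: names < 4 chars start in column 14
      an_fmt <- if (nchar(an) < 4L) sprintf(" %-3s", an) else an
      writeLines(sprintf(
        "ATOM  %5d %s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           %s",
        serial %% 100000L, an_fmt, cf$restype[i],
        attr(cf, "chain") %||% "A", cf$resno[i],
        cf$x[i], cf$y[i], cf$z[i], 1, 0,
        substr(gsub("^[0-9]+", "", an), 1L, 1L)), con)
    }
    if (length(ensemble) > 1L) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
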