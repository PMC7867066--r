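# Peak-list readers: Sparky-style whitespace tables and an explicit CSV
# dialect.  Assignment strings such as "A489N-CA-H" or
# "A489N-A488CA-A489H" are resolved into residue / atom / role fields.

# Parse one Sparky assignment string into per-axis (restype, resno, atom).
parse_assignment <- function(s) {
  toks <- strsplit(s, "-", fixed = TRUE)[[1]]
  out <- vector("list", length(toks))
  last_rt <- NA_character_; last_rn <- NA_integer_
  for (i in seq_along(toks)) {
    m <- regmatches(toks[i], regexec("^([A-Za-z])(\\d+)([A-Za-z0-9']+)$",
                                     toks[i]))[[1]]
    if (length(m) == 4L) {
      last_rt <- m[2]; last_rn <- as.integer(m[3])
      atom <- m[4]
    } else if (grepl("^[A-Za-z0-9']+$", toks[i]) && !is.na(last_rn)) {
      atom <- toks[i]
    } else {
      return(NULL)
    }
    out[[i]] <- list(restype = last_rt, resno = last_rn, atom = toupper(atom))
  }
  out
}

#' Read an assigned triple-resonance peak list
#'
#' Supports two dialects.  `sparky`: whitespace-separated columns
#' `assignment w1 ... wk height`, with Sparky-style assignment strings in
#' which axes missing an explicit residue inherit the previous one
#' (`"A489N-CA-H"`).  `csv`: explicit headers `residue, restype, atom,
#' role, w1..wk, height`.  Rows that cannot be parsed are collected and
#' attached as attribute `"rejected"`, never silently dropped.
#'
#' The amide residue (from the N axis) defines the record's residue; a
#' carbon axis on the same residue is an `intra` correlation, on residue
#' i-1 a `seq` correlation.
#'
#' @param path input file.
#' @param dialect `"sparky"`, `"csv"`, or `"auto"` (sniffs: a header line
#'   containing commas means csv).
#' @param nuclei axis nuclei in column order (default H, N, C... pattern
#'   inferred as `c("N","C","H")` for 3-axis Sparky lists written
#'   w1=N, w2=C, w3=H; pass explicitly when different).
#' @return a [peak_table()].
#' @export
read_peaklist <- function(path, dialect = c("auto", "sparky", "csv"),
                          nuclei = c("N", "C", "H")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (dialect == "auto") {
    dialect <- if (grepl(",", lines[1], fixed = TRUE)) "csv" else "sparky"
  }
  if (dialect == "csv") {
    df <- utils::read.csv(text = paste(lines, collapse = "\n"),
                          stringsAsFactors = FALSE)
    return(peak_table(df, nuclei = nuclei))
  }
  # sparky: drop a header line starting with 'Assignment'
  if (grepl("^\\s*Assignment", lines[1], ignore.case = TRUE)) {
    lines <- lines[-1]
  }
  rows <- list(); rejected <- character()
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    if (length(tok) < 3L) { rejected <- c(rejected, ln); next }
    asg <- parse_assignment(tok[1])
    vals <- suppressWarnings(as.numeric(tok[-1]))
    if (is.null(asg) || any(is.na(vals)) ||
        length(asg) != length(vals) - 1L) {
      rejected <- c(rejected, ln); next
    }
    nuc <- nuclei[seq_along(asg)]
    n_axis <- which(nuc == "N")[1]
    c_axis <- which(nuc == "C")[1]
    if (is.na(n_axis) || is.na(c_axis)) { rejected <- c(rejected, ln); next }
    amide <- asg[[n_axis]]
    carbon <- asg[[c_axis]]
    rt3 <- tryCatch(aa_three(amide$restype), error = function(e) NA_character_)
    if (is.na(rt3) || !carbon$atom %in% c("CA", "CB")) {
      rejected <- c(rejected, ln); next
    }
    role <- if (carbon$resno == amide$resno) "intra"
            else if (carbon$resno == amide$resno - 1L) "seq"
            else { rejected <- c(rejected, ln); next }
    row <- list(residue = amide$resno, restype = rt3,
                atom = carbon$atom, role = role)
    for (k in seq_along(asg)) row[[paste0("w", k)]] <- vals[k]
    row$height <- vals[length(vals)]
    rows[[length(rows) + 1L]] <- row
  }
  if (!length(rows)) {
    abort_fracnmr(sprintf("%s: no parsable peak rows", path),
                  "fracnmr_parse_error")
  }
  df <- do.call(rbind, lapply(rows, as.data.frame))
  pt <- peak_table(df, nuclei = nuclei)
  attr(pt, "rejected") <- rejected
  pt
}

#' Write a peak table in the CSV dialect
#'
#' @param peaks a [peak_table()].
#' @param path output path.
#' @param meta named list of provenance entries for the commented header.
#' @return the path, invisibly.
#' @export
write_peaklist_csv <- function(peaks, path, meta = list()) {
  write_csv_meta(as.data.frame(peaks), path, meta)
}
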