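# Ensemble structure comparison: Kabsch superposition, iterative mean
# structures, bundle RMSD matrices in the mean-vs-bundle convention, and
# per-residue global displacement profiles.

#' Construct a conformer
#'
#' @param df data.frame with columns `resno`, `restype`, `atom`, `x`, `y`,
#'   `z` (Angstrom).
#' @param model optional model id.
#' @param chain optional chain id.
#' @return data.frame of class `conformer`.
#' @export
conformer <- function(df, model = 1L, chain = "A") {
  need <- c("resno", "restype", "atom", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort_fracnmr(paste("conformer missing columns:",
                        paste(miss, collapse = ", ")), "fracnmr_bad_input")
  }
  if (any(!is.finite(df$x)) || any(!is.finite(df$y)) || any(!is.finite(df$z))) {
    abort_fracnmr("coordinates must be finite", "fracnmr_bad_input")
  }
  if (anyDuplicated(paste(df$resno, df$atom))) {
    abort_fracnmr("duplicate (residue, atom) in conformer",
                  "fracnmr_bad_input")
  }
  structure(df, class = c("conformer", "data.frame"),
            model = model, chain = chain)
}

BACKBONE_ATOMS <- c("N", "CA", "C")

# TRUE for heavy (C, N, O) atoms by PDB atom-name convention; sulfur is
# not part of the heavy set used for RMSD reporting.
is_heavy_atom <- function(atom) {
  el <- substr(gsub("^[0-9]+", "", atom), 1L, 1L)
  el %in% c("C", "N", "O")
}

#' Select atoms of a conformer
#'
#' @param conf a [conformer()].
#' @param residues integer vector of residue numbers (inclusive range or
#'   any set), or NULL for all.
#' @param atoms `"backbone"` (N, CA, C), `"heavy"` (all C, N, O), or an
#'   explicit character vector of atom names.
#' @return subset of the conformer rows.
#' @export
select_atoms <- function(conf, residues = NULL, atoms = "backbone") {
  keep <- rep(TRUE, nrow(conf))
  if (!is.null(residues)) keep <- keep & conf$resno %in% residues
  if (identical(atoms, "backbone")) {
    keep <- keep & conf$atom %in% BACKBONE_ATOMS
  } else if (identical(atoms, "heavy")) {
    keep <- keep & is_heavy_atom(conf$atom)
  } else {
    keep <- keep & conf$atom %in% atoms
  }
  conf[keep, , drop = FALSE]
}

# Matched coordinate matrices for atoms present in both conformers.
matched_coords <- function(a, b, residues = NULL, atoms = "backbone") {
  sa <- select_atoms(a, residues, atoms)
  sb <- select_atoms(b, residues, atoms)
  ka <- paste(sa$resno, sa$atom)
  kb <- paste(sb$resno, sb$atom)
  common <- intersect(ka, kb)
  list(a = as.matrix(sa[match(common, ka), c("x", "y", "z")]),
       b = as.matrix(sb[match(common, kb), c("x", "y", "z")]),
       keys = common)
}

# Kabsch rotation (proper, det = +1) aligning centred P onto centred Q.
kabsch_rotation <- function(P, Q) {
  H <- t(P) %*% Q
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  sv$v %*% D %*% t(sv$u)
}

#' Least-squares rigid superposition of two conformers
#'
#' Kabsch algorithm over the selected atom pairs present in both
#' structures; reflections are never applied.
#'
#' @param mobile,target conformers; the transform maps `mobile` onto
#'   `target`.
#' @param residues,atoms selection, see [select_atoms()].
#' @return object of class `superposition`: list with `rotation` (3x3),
#'   `translation` (length 3), `rmsd` (Angstrom), `n_atoms`, `selection`.
#' @export
kabsch_superpose <- function(mobile, target, residues = NULL,
                             atoms = "backbone") {
  mc <- matched_coords(mobile, target, residues, atoms)
  P <- mc$a; Q <- mc$b
  if (nrow(P) < 3L) {
    abort_fracnmr("need >= 3 atom pairs for superposition",
                  "fracnmr_bad_selection")
  }
  Pc <- colMeans(P); Qc <- colMeans(Q)
  P0 <- sweep(P, 2L, Pc); Q0 <- sweep(Q, 2L, Qc)
  if (qr(P0)$rank < 2L) {
    abort_fracnmr("selected atoms are collinear", "fracnmr_bad_selection")
  }
  R <- kabsch_rotation(P0, Q0)
  Pr <- P0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((Pr - Q0)^2)))
  structure(list(rotation = R, translation = as.numeric(Qc - Pc %*% t(R)),
                 rmsd = rmsd, n_atoms = nrow(P),
                 selection = list(residues = residues, atoms = atoms)),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> rmsd = %.4g A over %d atoms\n",
              x$rmsd, x$n_atoms))
  invisible(x)
}

#' Apply a superposition to a whole conformer
#'
#' @param conf a [conformer()].
#' @param sup a result of [kabsch_superpose()].
#' @return the transformed conformer.
#' @export
apply_superposition <- function(conf, sup) {
  xyz <- as.matrix(conf[, c("x", "y", "z")])
  xyz <- xyz %*% t(sup$rotation)
  xyz <- sweep(xyz, 2L, -sup$translation)
  conf$x <- xyz[, 1]; conf$y <- xyz[, 2]; conf$z <- xyz[, 3]
  conf
}

#' RMSD between two conformers over a selection
#'
#' Superposes `a` onto `b` (Kabsch) and returns the residual RMSD.
#'
#' @inheritParams kabsch_superpose
#' @param a,b conformers.
#' @return RMSD in Angstrom.
#' @export
rmsd_between <- function(a, b, residues = NULL, atoms = "backbone") {
  kabsch_superpose(a, b, residues, atoms)$rmsd
}

#' Iterative mean structure of an ensemble
#'
#' Superposes every model onto the current mean, re-averages coordinates,
#' and repeats until the mean moves by less than `tol` per coordinate.
#'
#' @param ensemble list of conformers sharing the same atoms.
#' @param residues,atoms selection used for the superposition (the whole
#'   conformer is averaged).
#' @param tol convergence threshold in Angstrom (default 1e-6).
#' @param max_iter iteration cap (default 100); non-convergence errors.
#' @return the mean [conformer()].
#' @export
ensemble_mean <- function(ensemble, residues = NULL, atoms = "backbone",
                          tol = 1e-6, max_iter = 100L) {
  if (length(ensemble) < 2L) {
    abort_fracnmr("need >= 2 conformers for a mean structure",
                  "fracnmr_bad_input")
  }
  mean_conf <- ensemble[[1]]
  for (it in seq_len(max_iter)) {
    fitted <- lapply(ensemble, function(cf) {
      apply_superposition(cf, kabsch_superpose(cf, mean_conf, residues, atoms))
    })
    key <- paste(mean_conf$resno, mean_conf$atom)
    xyz <- Reduce(`+`, lapply(fitted, function(cf) {
      as.matrix(cf[match(key, paste(cf$resno, cf$atom)), c("x", "y", "z")])
    })) / length(fitted)
    delta <- max(abs(xyz - as.matrix(mean_conf[, c("x", "y", "z")])))
    mean_conf$x <- xyz[, 1]; mean_conf$y <- xyz[, 2]; mean_conf$z <- xyz[, 3]
    if (delta < tol) return(mean_conf)
  }
  abort_fracnmr("mean structure did not converge", "fracnmr_no_convergence")
}

#' Bundle RMSD matrix in the mean-vs-bundle convention
#'
#' Diagonal entries are the mean +/- sd of all pairwise RMSDs within a
#' bundle (ensemble precision).  Off-diagonal entry (row A, column B) is
#' the mean +/- sd of the RMSDs from the mean structure of A to each
#' member of bundle B; the matrix is therefore asymmetric and is reported
#' as such.
#'
#' @param ensembles named list of ensembles (each a list of conformers).
#' @param residues residue numbers to include (e.g. `459:541`).
#' @param atoms `"backbone"` or `"heavy"`.
#' @return list with matrices `mean` and `sd` (rownames = colnames =
#'   ensemble names).
#' @export
rmsd_matrix <- function(ensembles, residues = NULL, atoms = "backbone") {
  nm <- names(ensembles)
  if (is.null(nm) || any(nm == "")) {
    abort_fracnmr("ensembles must be a named list", "fracnmr_bad_input")
  }
  k <- length(ensembles)
  # a single-member "bundle" (e.g. one crystal structure) is its own mean
  means <- lapply(ensembles, function(e) {
    if (length(e) == 1L) e[[1]]
    else ensemble_mean(e, residues = residues, atoms = atoms)
  })
  M <- S <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      vals <- if (i == j) {
        ens <- ensembles[[i]]
        n <- length(ens)
        if (n == 1L) 0 else {
          pr <- utils::combn(n, 2L)
          apply(pr, 2L, function(p) {
            rmsd_between(ens[[p[1]]], ens[[p[2]]], residues, atoms)
          })
        }
      } else {
        vapply(ensembles[[j]], function(cf) {
          rmsd_between(means[[i]], cf, residues, atoms)
        }, numeric(1))
      }
      M[i, j] <- mean(vals)
      S[i, j] <- if (length(vals) > 1L) stats::sd(vals) else 0
    }
  }
  list(mean = M, sd = S)
}

#' Per-residue global displacement between two structures
#'
#' After one global Kabsch superposition on the backbone of the selected
#' range, the global displacement D_glob of each residue is the RMS
#' distance over that residue's atoms, computed separately for the
#' backbone (N, CA, C) and heavy (C, N, O) atom sets.  Residues missing
#' in either structure yield NA (a gap), not zero.
#'
#' @param mean_a,mean_b conformers (typically mean structures).
#' @param residues residue range for both the superposition and profile.
#' @return data.frame of class `displacement_profile`: resno, d_backbone,
#'   d_heavy (Angstrom).
#' @export
displacement_profile <- function(mean_a, mean_b, residues = NULL) {
  sup <- kabsch_superpose(mean_b, mean_a, residues, atoms = "backbone")
  b_fit <- apply_superposition(mean_b, sup)
  if (is.null(residues)) {
    residues <- sort(union(mean_a$resno, mean_b$resno))
  }
  prof <- lapply(residues, function(rn) {
    row <- data.frame(resno = rn, d_backbone = NA_real_, d_heavy = NA_real_)
    for (set in c("backbone", "heavy")) {
      mc <- matched_coords(mean_a, b_fit, residues = rn, atoms = set)
      if (nrow(mc$a) > 0L) {
        d <- sqrt(mean(rowSums((mc$a - mc$b)^2)))
        if (set == "backbone") row$d_backbone <- d else row$d_heavy <- d
      }
    }
    row
  })
  out <- do.call(rbind, prof)
  class(out) <- c("displacement_profile", "data.frame")
  out
}
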