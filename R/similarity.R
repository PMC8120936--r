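# Ground-truth model quality: optimal superposition, RMSD, TM-score and the
# four quality categories.

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares superposition of point set `coords_a` onto `coords_b`, with
#' a proper rotation enforced (determinant +1).
#'
#' @param coords_a,coords_b n x 3 coordinate matrices, equal n >= 3.
#' @return object of class `superposition`: list with `rotation` (3x3),
#'   `translation` (length 3), `rmsd` (Angstrom). Apply as
#'   `coords %*% t(rotation) + translation` (rowwise).
#' @export
kabsch <- function(coords_a, coords_b) {
  a <- as.matrix(coords_a); b <- as.matrix(coords_b)
  if (nrow(a) != nrow(b)) stop("point sets must have equal length")
  if (nrow(a) < 3L) stop("kabsch needs at least 3 points")
  ca <- colMeans(a); cb <- colMeans(b)
  ac <- sweep(a, 2L, ca); bc <- sweep(b, 2L, cb)
  h <- crossprod(ac, bc)             # t(ac) %*% bc
  sv <- svd(h)
  if (sv$d[2L] < 1e-8 * max(sv$d[1L], 1e-12))
    warning("degenerate (near-collinear) point set in kabsch")
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- ac %*% t(rot)
  rmsd <- sqrt(mean(rowSums((fitted - bc)^2)))
  structure(list(rotation = rot,
                 translation = as.numeric(cb - rot %*% ca),
                 rmsd = rmsd),
            class = "superposition")
}

#' Apply a superposition to coordinates
#' @param sup a `superposition`.
#' @param coords n x 3 matrix.
#' @export
apply_superposition <- function(sup, coords) {
  sweep(as.matrix(coords) %*% t(sup$rotation), 2L, sup$translation, "+")
}

# CA coordinates and author residue numbers of a chain.
ca_table <- function(chain) {
  a <- chain$atoms
  ca <- a[a$atom_name == "CA", , drop = FALSE]
  list(xyz = as.matrix(ca[, c("x", "y", "z")]),
       res = paste(ca$res_seq, ca$icode, sep = "_"))
}

#' TM-score of a model against its native structure
#'
#' Length-normalized structural similarity in (0, 1]:
#' `TM = (1/L) * sum_i 1 / (1 + (d_i/d0)^2)` with
#' `d0 = 1.24 (L - 15)^(1/3) - 1.8` (floored at 0.5 Angstrom) and `L` the
#' native chain length. Residues are matched by shared author numbering
#' (decoys of a common target). The superposition is searched from sliding
#' seed fragments of lengths L, L/2 and L/4 (minimum 4), each refined by
#' iterative Kabsch re-inclusion of residues within a d0-based cutoff; the
#' maximum TM over all seeds and iterations is returned.
#'
#' @param model,native `chain` objects with CA atoms.
#' @return TM-score in (0, 1].
#' @export
tm_score <- function(model, native) {
  m <- ca_table(model); n <- ca_table(native)
  shared <- intersect(m$res, n$res)
  if (length(shared) < 3L) stop("fewer than 3 shared residues with CA atoms")
  ma <- m$xyz[match(shared, m$res), , drop = FALSE]
  na <- n$xyz[match(shared, n$res), , drop = FALSE]
  L <- length(n$res)                       # native-length normalization
  d0 <- max(0.5, 1.24 * sign(L - 15) * abs(L - 15)^(1 / 3) - 1.8)
  ns <- length(shared)
  incl_cut <- max(d0, 4.5)
  tm_of <- function(d) sum(1 / (1 + (d / d0)^2)) / L

  best <- 0
  seed_lens <- unique(pmax(4L, c(ns, ns %/% 2L, ns %/% 4L)))
  for (len in seed_lens) {
    for (start in seq_len(ns - len + 1L)) {
      incl <- start:(start + len - 1L)
      for (iter in 1:30) {
        sup <- suppressWarnings(kabsch(ma[incl, , drop = FALSE],
                                       na[incl, , drop = FALSE]))
        d <- sqrt(rowSums((apply_superposition(sup, ma) - na)^2))
        best <- max(best, tm_of(d))
        new_incl <- which(d < incl_cut)
        if (length(new_incl) < 3L) new_incl <- order(d)[1:4]
        if (identical(new_incl, incl)) break
        incl <- new_incl
      }
    }
  }
  best
}

#' RMSD after optimal superposition of shared CA atoms
#' @param model,native `chain` objects with CA atoms.
#' @export
ca_rmsd <- function(model, native) {
  m <- ca_table(model); n <- ca_table(native)
  shared <- intersect(m$res, n$res)
  if (length(shared) < 3L) stop("fewer than 3 shared residues with CA atoms")
  kabsch(m$xyz[match(shared, m$res), , drop = FALSE],
         n$xyz[match(shared, n$res), , drop = FALSE])$rmsd
}

#' Quality category of a TM-score
#'
#' Categories follow half-open TM-score intervals: near-native (0.8, 1.0],
#' good (0.6, 0.8], medium (0.4, 0.6], poor [0, 0.4]. Boundary values fall
#' into the lower category (a TM-score of exactly 0.8 is "good").
#'
#' @param tm numeric vector of TM-scores in [0, 1].
#' @return character vector: `"near_native"`, `"good"`, `"medium"` or
#'   `"poor"`.
#' @export
quality_category <- function(tm) {
  if (any(tm < 0 | tm > 1 | is.na(tm))) stop("TM-score must lie in [0, 1]")
  out <- rep("poor", length(tm))
  out[tm > 0.4] <- "medium"
  out[tm > 0.6] <- "good"
  out[tm > 0.8] <- "near_native"
  out
}

QUALITY_LEVELS <- c("near_native", "good", "medium", "poor")
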