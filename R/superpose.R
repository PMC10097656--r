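# ---------------------------------------------------------------------------
# UniProt-numbering based rigid-body superposition: residue equivalence is
# read from the augmented _atom_site items, pairing is by UniProt residue
# number, and the optimal rotation/translation is the Kabsch solution.
# ---------------------------------------------------------------------------

#' Extract a UniProt-numbered coordinate set from an updated mmCIF file
#'
#' Collects one C-alpha atom per mapped, observed residue of the given
#' accession, keyed by UniProt residue number.  Alternate locations keep
#' the highest-occupancy conformer, ties broken by altloc letter.
#'
#' @param path Path to an mmCIF file carrying the SIFTS `_atom_site` items.
#' @param accession UniProtKB accession to select.
#' @param asym_id Optional chain restriction (label_asym_id).
#' @return Object of class `coordinate_set`: list with `accession`,
#'   `unp_num` (strictly increasing integer vector) and `xyz` (matrix, one
#'   row per residue, in the same order).
#' @export
coordinate_set <- function(path, accession, asym_id = NULL) {
  doc <- cif_read(path)
  as_ <- doc$categories$atom_site
  if (is.null(as_)) stop("no atom_site in ", path)
  if (!all(c("pdbx_sifts_xref_db_acc", "pdbx_sifts_xref_db_num") %in%
           names(as_)))
    stop("atom_site lacks SIFTS items; augment the entry first: ", path)
  keep <- as_$pdbx_sifts_xref_db_acc == accession &
    as_$label_atom_id == "CA"
  if (!is.null(asym_id)) keep <- keep & as_$label_asym_id == asym_id
  if (!is.null(as_$pdbx_PDB_model_num))
    keep <- keep & as_$pdbx_PDB_model_num == as_$pdbx_PDB_model_num[1L]
  sel <- as_[keep, , drop = FALSE]
  if (!nrow(sel)) stop("no mapped C-alpha atoms for ", accession, " in ", path)
  if (!is.null(sel$label_alt_id)) {
    occ <- if (!is.null(sel$occupancy))
      suppressWarnings(as.numeric(sel$occupancy)) else rep(1, nrow(sel))
    occ[is.na(occ)] <- 1
    alt <- ifelse(sel$label_alt_id %in% c(".", "?"), "", sel$label_alt_id)
    o <- order(sel$label_asym_id, as.integer(sel$pdbx_sifts_xref_db_num),
               -occ, alt)
    sel <- sel[o, , drop = FALSE]
    sel <- sel[!duplicated(paste(sel$label_asym_id,
                                 sel$pdbx_sifts_xref_db_num)), , drop = FALSE]
  }
  unp <- as.integer(sel$pdbx_sifts_xref_db_num)
  o <- order(unp)
  unp <- unp[o]
  xyz <- cbind(as.numeric(sel$Cartn_x), as.numeric(sel$Cartn_y),
               as.numeric(sel$Cartn_z))[o, , drop = FALSE]
  dup <- duplicated(unp)
  if (any(dup)) { # repeat copies: keep the first copy of each position
    unp <- unp[!dup]
    xyz <- xyz[!dup, , drop = FALSE]
  }
  structure(list(accession = accession, unp_num = unp, xyz = xyz),
            class = "coordinate_set")
}

#' Construct a coordinate set from raw values
#'
#' @param accession UniProtKB accession.
#' @param unp_num Integer vector of UniProt residue numbers (strictly
#'   increasing).
#' @param xyz Numeric matrix (length(unp_num) x 3) of C-alpha coordinates
#'   in Angstrom.
#' @return A `coordinate_set`.
#' @export
as_coordinate_set <- function(accession, unp_num, xyz) {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3L, nrow(xyz) == length(unp_num),
            !is.unsorted(unp_num, strictly = TRUE))
  structure(list(accession = accession, unp_num = as.integer(unp_num),
                 xyz = xyz),
            class = "coordinate_set")
}

#' Pair two coordinate sets by UniProt residue number
#'
#' @param a,b `coordinate_set` objects for the same accession.
#' @return List with matrices `P` and `Q` (paired coordinates, one row per
#'   common UniProt position) and `unp_num`.
#' @export
pair_by_unp <- function(a, b) {
  stopifnot(inherits(a, "coordinate_set"), inherits(b, "coordinate_set"))
  if (!identical(a$accession, b$accession))
    stop("coordinate sets map to different accessions: ",
         a$accession, " vs ", b$accession)
  common <- intersect(a$unp_num, b$unp_num)
  if (length(common) < 3L)
    stop("insufficient overlap: ", length(common),
         " common UniProt position(s), need >= 3")
  common <- sort(common)
  list(P = a$xyz[match(common, a$unp_num), , drop = FALSE],
       Q = b$xyz[match(common, b$unp_num), , drop = FALSE],
       unp_num = common)
}

#' Kabsch superposition
#'
#' Least-squares optimal proper rotation and translation mapping `P` onto
#' `Q`, via singular value decomposition of the covariance matrix with
#' reflection correction.
#'
#' @param P,Q Numeric matrices of paired coordinates (n x 3, n >= 3,
#'   non-collinear).
#' @return Object of class `superposition_result`: list with `rotation`
#'   (3 x 3, determinant +1), `translation` (length 3; the fit is
#'   `P %*% t(rotation) + translation`), `rmsd` (Angstrom) and `n_pairs`.
#' @export
kabsch <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  stopifnot(ncol(P) == 3L, ncol(Q) == 3L, nrow(P) == nrow(Q))
  n <- nrow(P)
  if (n < 3L) stop("need at least 3 paired points")
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2L, cp); Q0 <- sweep(Q, 2L, cq)
  H <- crossprod(P0, Q0)
  sv <- svd(H)
  if (sv$d[2L] < 1e-8 * max(sv$d[1L], 1))
    stop("degenerate (collinear or coincident) coordinates")
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  fitted <- P0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Q0)^2)))
  structure(list(rotation = R, translation = as.numeric(cq - R %*% cp),
                 rmsd = rmsd, n_pairs = n),
            class = "superposition_result")
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf("superposition over %d pairs: rmsd %.3f A\n", x$n_pairs, x$rmsd))
  invisible(x)
}

#' Quaternion-based superposition (independent reference)
#'
#' Horn's closed-form quaternion solution for the optimal proper rotation,
#' via the leading eigenvector of the 4 x 4 key matrix.  Algebraically
#' independent of the SVD route in [kabsch()]; used as a cross-check.
#'
#' @inheritParams kabsch
#' @return List with `rotation`, `translation`, `rmsd`, `n_pairs`.
#' @export
kabsch_horn <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  stopifnot(nrow(P) == nrow(Q), ncol(P) == 3L)
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2L, cp); Q0 <- sweep(Q, 2L, cq)
  S <- crossprod(P0, Q0)
  Sxx <- S[1,1]; Sxy <- S[1,2]; Sxz <- S[1,3]
  Syx <- S[2,1]; Syy <- S[2,2]; Syz <- S[2,3]
  Szx <- S[3,1]; Szy <- S[3,2]; Szz <- S[3,3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       Syy - Sxx - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       Szz - Sxx - Syy),
    nrow = 4L, byrow = TRUE)
  ev <- eigen(K, symmetric = TRUE)
  q <- ev$vectors[, 1L]
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  R <- matrix(c(
    w*w + x*x - y*y - z*z, 2*(x*y - w*z),         2*(x*z + w*y),
    2*(x*y + w*z),         w*w - x*x + y*y - z*z, 2*(y*z - w*x),
    2*(x*z - w*y),         2*(y*z + w*x),         w*w - x*x - y*y + z*z),
    nrow = 3L, byrow = TRUE)
  fitted <- P0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Q0)^2)))
  list(rotation = R, translation = as.numeric(cq - R %*% cp),
       rmsd = rmsd, n_pairs = nrow(P))
}

#' Superpose several structures mapped to one accession
#'
#' Every unordered pair of coordinate sets is paired by UniProt numbering
#' and independently superposed; the summary statistic is the mean of the
#' pairwise RMSDs (or, with `method = "to_first"`, the mean RMSD of each
#' set against the first).
#'
#' @param sets List of >= 2 `coordinate_set` objects sharing one accession.
#' @param method `"pairwise"` (default) or `"to_first"`.
#' @return List with `average_rmsd`, `pairs` (data.frame `i`, `j`, `rmsd`,
#'   `n_pairs`) and `failed` (character vector describing any pair that
#'   could not be superposed; such pairs are excluded from the mean with a
#'   warning).
#' @export
multi_superpose <- function(sets, method = c("pairwise", "to_first")) {
  method <- match.arg(method)
  stopifnot(length(sets) >= 2L)
  idx <- if (method == "pairwise")
    utils::combn(length(sets), 2L, simplify = FALSE)
  else lapply(seq_along(sets)[-1L], function(j) c(1L, j))
  rows <- list()
  failed <- character(0)
  for (ij in idx) {
    res <- tryCatch({
      pq <- pair_by_unp(sets[[ij[1L]]], sets[[ij[2L]]])
      kabsch(pq$P, pq$Q)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, sprintf("pair (%d, %d): %s", ij[1L], ij[2L],
                                  conditionMessage(res)))
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(i = ij[1L], j = ij[2L],
                                            rmsd = res$rmsd,
                                            n_pairs = res$n_pairs)
  }
  if (length(failed))
    warning("excluded from average: ", paste(failed, collapse = "; "),
            call. = FALSE)
  if (!length(rows)) stop("no superposable pair among the coordinate sets")
  pairs <- do.call(rbind, rows)
  list(average_rmsd = mean(pairs$rmsd), pairs = pairs, failed = failed)
}
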