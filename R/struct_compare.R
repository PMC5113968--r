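# Rigid-body superposition and model-quality scores (RMSD, TM-score,
# GDT-HA, lDDT) used to compare models with their reference structures.

#' Construct a labeled coordinate set
#'
#' @param points Numeric n x 3 matrix of coordinates in Angstrom.
#' @param labels Residue labels (one per row), used for pairing across
#'   structures; never raw author numbers across different proteins.
#' @return A \code{CoordSet}.
#' @export
coord_set <- function(points, labels) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3, nrow(points) == length(labels))
  structure(list(labels = as.character(labels), xyz = unname(points)),
            class = "CoordSet")
}

#' Extract a CA coordinate set from a structure model
#'
#' @param model A \code{StructureModel}.
#' @param chain Optional chain filter.
#' @param atom Atom name (default CA).
#' @param labels Optional replacement labels (e.g. alignment-derived target
#'   positions); defaults to \code{chain:resno:icode}.
#' @return A \code{CoordSet}.
#' @export
as_coord_set <- function(model, chain = NULL, atom = "CA", labels = NULL) {
  stopifnot(inherits(model, "StructureModel"))
  at <- model$atoms
  at <- at[at$role == "polymer" & at$elety == atom, , drop = FALSE]
  if (!is.null(chain)) at <- at[at$chain == chain, , drop = FALSE]
  if (nrow(at) == 0) stop("no matching atoms for coordinate set")
  lab <- if (is.null(labels)) paste(at$chain, at$resno, at$icode, sep = ":")
  else labels
  coord_set(cbind(at$x, at$y, at$z), lab)
}

#' Pair two coordinate sets by label
#'
#' @param a,b \code{CoordSet}s.
#' @return List of the two sets restricted to the label intersection, in
#'   \code{a}'s order; errors when fewer than 3 labels are shared.
#' @export
pair_by_label <- function(a, b) {
  common <- a$labels[a$labels %in% b$labels]
  if (length(common) < 3)
    stop(sprintf("insufficient overlap: only %d common label(s), need >= 3",
                 length(common)))
  ia <- match(common, a$labels)
  ib <- match(common, b$labels)
  list(a = coord_set(a$xyz[ia, , drop = FALSE], common),
       b = coord_set(b$xyz[ib, , drop = FALSE], common))
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the sum of squared
#' deviations of \code{mobile} onto \code{fixed} via SVD of the covariance
#' matrix, with the determinant correction that excludes reflections.
#'
#' @param mobile,fixed Paired \code{CoordSet}s (equal length >= 3).
#' @return A \code{SuperpositionResult}: \code{rotation} (3x3, det +1),
#'   \code{translation} (length 3) such that transformed mobile =
#'   \code{xyz \%*\% t(rotation) + translation}, and the minimized
#'   \code{rmsd} in Angstrom.
#' @export
kabsch_superpose <- function(mobile, fixed) {
  P <- mobile$xyz; Q <- fixed$xyz
  stopifnot(nrow(P) == nrow(Q), nrow(P) >= 3)
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- crossprod(Pc, Qc)
  sv <- svd(H)
  if (sv$d[2] <= 1e-10 * max(sv$d[1], 1e-12))
    stop("degenerate geometry: points are (near-)collinear, rotation ill-conditioned")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rot <- Pc %*% t(R)
  rmsd <- sqrt(mean(rowSums((rot - Qc)^2)))
  structure(list(rotation = R, translation = as.numeric(cq - R %*% cp),
                 rmsd = rmsd), class = "SuperpositionResult")
}

apply_superposition <- function(xyz, sp) {
  sweep(xyz %*% t(sp$rotation), 2, sp$translation, `+`)
}

#' RMSD after optimal superposition
#' @param model,ref Paired \code{CoordSet}s.
#' @return RMSD in Angstrom.
#' @export
superposed_rmsd <- function(model, ref) kabsch_superpose(model, ref)$rmsd

tm_d0 <- function(L) {
  if (L <= 15) return(0.5)
  max(0.5, 1.24 * (L - 15)^(1/3) - 1.8)
}

# seed windows for the iterative superposition search: exhaustive (every
# length, every start) on small problems; a fixed ladder of window lengths
# with coarser strides as the chain grows
seed_windows <- function(L) {
  lens <- if (L <= 48) 3:L
  else unique(pmax(3L, c(L, as.integer(floor(L / 2)),
                         as.integer(floor(L / 4)), 7L, 5L, 3L)))
  out <- list()
  for (len in lens) {
    if (len > L) next
    stride <- if (L <= 80) 1L else max(1L, as.integer(floor(len / 2)))
    for (s in seq(1L, L - len + 1L, by = stride))
      out[[length(out) + 1L]] <- s:(s + len - 1L)
  }
  out
}

# fit on subset, return residual distances of all points (NULL on a
# degenerate subset); internal fast path shared by the score searches
fit_distances <- function(P, Q, sel) {
  Ps <- P[sel, , drop = FALSE]; Qs <- Q[sel, , drop = FALSE]
  cp <- colMeans(Ps); cq <- colMeans(Qs)
  H <- crossprod(Ps, Qs) - length(sel) * tcrossprod(cp, cq)
  sv <- svd(H)
  if (sv$d[2] <= 1e-10 * max(sv$d[1], 1e-12)) return(NULL)
  R <- sv$v %*% diag(c(1, 1, sign(det(sv$v %*% t(sv$u))))) %*% t(sv$u)
  moved <- sweep((P %*% t(R)), 2, as.numeric(cq - R %*% cp), `+`)
  sqrt(rowSums((moved - Q)^2))
}

# generic seeded + iteratively refined superposition search: from each seed
# window, superpose, re-select residues by select_fn on the distances,
# re-superpose on the selection until stable; best score_fn value over all
# visited superpositions is returned
search_superpositions <- function(mobile, fixed, select_fn, score_fn,
                                  max_iter = 20L) {
  P <- mobile$xyz; Q <- fixed$xyz
  best <- -Inf
  for (win in seed_windows(nrow(P))) {
    sel <- win
    prev <- integer(0)
    for (it in seq_len(max_iter)) {
      d <- fit_distances(P, Q, sel)
      if (is.null(d)) break
      s <- score_fn(d)
      if (s > best) best <- s
      nxt <- select_fn(d)
      if (length(nxt) < 3) nxt <- order(d)[1:3]
      if (identical(nxt, prev) || identical(nxt, sel)) break
      prev <- sel
      sel <- nxt
    }
  }
  best
}

#' TM-score of a model against a reference
#'
#' \eqn{TM = \max (1/L) \sum_i 1/(1 + (d_i/d_0)^2)} with the standard
#' length-dependent \eqn{d_0} (floored at 0.5 A), normalized by the
#' reference length and maximized over superpositions found by a
#' fragment-seeded, iteratively refined search (an approximation of the
#' reference implementation's search, checked against an exhaustive-window
#' oracle in the tests).
#'
#' @param model,ref \code{CoordSet}s; paired by label internally.
#' @return TM-score in (0, 1].
#' @export
tm_score <- function(model, ref) {
  p <- pair_by_label(model, ref)
  L <- nrow(p$b$xyz)
  d0 <- tm_d0(L)
  score <- function(d) sum(1 / (1 + (d / d0)^2)) / L
  cut <- max(d0, 1.5)
  search_superpositions(p$a, p$b,
                        select_fn = function(d) which(d < cut),
                        score_fn = score)
}

#' GDT-HA score of a model against a reference
#'
#' Mean over the thresholds 0.5, 1, 2 and 4 Angstrom of the maximal
#' percentage of residue pairs fitting under that threshold across the
#' searched superpositions.
#'
#' @param model,ref \code{CoordSet}s; paired by label internally.
#' @return Score in [0, 100].
#' @export
gdt_ha <- function(model, ref) {
  p <- pair_by_label(model, ref)
  L <- nrow(p$b$xyz)
  per <- vapply(c(0.5, 1, 2, 4), function(thr) {
    search_superpositions(p$a, p$b,
                          select_fn = function(d) which(d < thr),
                          score_fn = function(d) 100 * sum(d <= thr) / L)
  }, 0)
  mean(per)
}

#' lDDT score of a model against a reference
#'
#' Superposition-free local score: over all reference point pairs from
#' different residues within the inclusion radius, the fraction of pairwise
#' distances preserved in the model within each of the tolerance thresholds,
#' averaged over the thresholds. With \code{CoordSet} input each point is
#' one residue (CA mode); with \code{StructureModel} input all heavy atoms
#' are used and pairs within the same residue are excluded.
#'
#' @param model,ref Two \code{CoordSet}s or two \code{StructureModel}s.
#' @param inclusion_radius Reference distance cutoff in Angstrom.
#' @param thresholds Tolerance thresholds in Angstrom.
#' @return Score in [0, 1].
#' @export
lddt <- function(model, ref, inclusion_radius = 15,
                 thresholds = c(0.5, 1, 2, 4)) {
  if (inherits(model, "StructureModel")) {
    ma <- heavy_atom_set(model); ra <- heavy_atom_set(ref)
    common <- intersect(ma$key, ra$key)
    im <- match(common, ma$key); ir <- match(common, ra$key)
    mx <- ma$xyz[im, , drop = FALSE]; rx <- ra$xyz[ir, , drop = FALSE]
    res <- ma$res[im]
  } else {
    p <- pair_by_label(model, ref)
    mx <- p$a$xyz; rx <- p$b$xyz
    res <- p$b$labels
  }
  dr <- as.matrix(stats::dist(rx))
  dm <- as.matrix(stats::dist(mx))
  n <- nrow(dr)
  keep <- upper.tri(dr) & dr < inclusion_radius &
    outer(res, res, `!=`)
  if (!any(keep)) stop("lddt: no qualifying reference pairs within the inclusion radius")
  diffs <- abs(dm[keep] - dr[keep])
  mean(vapply(thresholds, function(t) mean(diffs <= t), 0))
}

heavy_atom_set <- function(model) {
  at <- model$atoms
  at <- at[at$role == "polymer" & !grepl("^H", at$elety), , drop = FALSE]
  res <- paste(at$chain, at$resno, at$icode, sep = ":")
  list(key = paste(res, at$elety, sep = "|"), res = res,
       xyz = cbind(at$x, at$y, at$z))
}

#' RMSD difference between model and template accuracy
#'
#' Subtracts the template-vs-target RMSD from the model-vs-target RMSD; a
#' negative value means the model sits closer to the target than its
#' template did (useful when template and target were caught in different
#' conformations).
#'
#' @param model_vs_target,template_vs_target RMSD values in Angstrom (>= 0).
#' @return Difference in Angstrom (may be negative).
#' @export
rmsd_diff <- function(model_vs_target, template_vs_target) {
  stopifnot(model_vs_target >= 0, template_vs_target >= 0)
  model_vs_target - template_vs_target
}

#' Trim a model set to its longest common segment
#'
#' Restricts every model to the longest contiguous run (in the first
#' model's label order) of labels present in all models, so per-set scores
#' are computed over identical residues. Ties break to the earliest start.
#'
#' @param models List of >= 2 \code{CoordSet}s.
#' @return List of trimmed \code{CoordSet}s.
#' @export
longest_common_segment <- function(models) {
  stopifnot(length(models) >= 2)
  labs <- models[[1]]$labels
  present <- rep(TRUE, length(labs))
  for (m in models[-1]) present <- present & labs %in% m$labels
  if (!any(present)) stop("longest_common_segment: no labels common to all models")
  r <- rle(present)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  span <- labs[starts[best]:ends[best]]
  lapply(models, function(m) {
    idx <- match(span, m$labels)
    coord_set(m$xyz[idx, , drop = FALSE], span)
  })
}

#' Full score set for one model-reference pair
#'
#' @param model,ref \code{CoordSet}s.
#' @param template_vs_target Optional template-target RMSD enabling
#'   \code{rmsd_diff}.
#' @return One-row data.frame: rmsd, tm, gdt_ha, lddt (and rmsd_diff).
#' @export
score_set <- function(model, ref, template_vs_target = NULL) {
  p <- pair_by_label(model, ref)
  r <- kabsch_superpose(p$a, p$b)$rmsd
  out <- data.frame(rmsd = r, tm = tm_score(model, ref),
                    gdt_ha = gdt_ha(model, ref), lddt = lddt(model, ref))
  if (!is.null(template_vs_target))
    out$rmsd_diff <- rmsd_diff(r, template_vs_target)
  out
}
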