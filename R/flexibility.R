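# Rigid-body superposition (Kabsch, SVD-based, reflections excluded) and
# per-residue RMSF anchored on the central chain of each pentamer, mirroring
# how flexibility is profiled in cross-beta filament trajectories: each frame
# is aligned on the Calpha atoms of chain 3a (for protofilament a chains) or
# 3b (for b chains), then fluctuations are measured per chain about the
# per-atom mean position.

#' Least-squares rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation `R` and translation `t` minimising
#' `sum |R x_i + t - y_i|^2` over the selected atoms.
#'
#' @param mobile,reference Numeric n x 3 coordinate matrices (nm).
#' @return List with `rotation` (3 x 3), `translation` (length 3), and
#'   `rmsd` (nm) over the fitted points. Apply as `x %*% t(R) + t`.
#' @export
superpose <- function(mobile, reference) {
  stopifnot(is.matrix(mobile), is.matrix(reference),
            ncol(mobile) == 3, ncol(reference) == 3,
            nrow(mobile) == nrow(reference))
  if (nrow(mobile) < 3) stop("need at least 3 atoms to superpose")
  mc <- colMeans(mobile); rc <- colMeans(reference)
  X <- sweep(mobile, 2, mc); Y <- sweep(reference, 2, rc)
  sv <- svd(crossprod(X, Y))   # t(X) %*% Y
  if (sv$d[2] < 1e-12) stop("degenerate (collinear) atom selection")
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t_vec <- rc - as.numeric(R %*% mc)
  fitted <- mobile %*% t(R) + matrix(t_vec, nrow(mobile), 3, byrow = TRUE)
  list(rotation = R, translation = t_vec,
       rmsd = sqrt(mean(rowSums((fitted - reference)^2))))
}

#' Apply a superposition transform to coordinates
#' @param coords n x 3 matrix.
#' @param fit Result of [superpose()].
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(coords, fit) {
  coords %*% t(fit$rotation) +
    matrix(fit$translation, nrow(coords), 3, byrow = TRUE)
}

#' Per-residue RMSF anchored on the central chains
#'
#' Each frame is superposed onto the first frame using the Calpha atoms of
#' the anchor chain of its protofilament (stack index 3, i.e. chain 3a for
#' protofilament-a chains and 3b for b). Fluctuations are then computed per
#' chain on Calpha atoms about the aligned per-atom mean position:
#' `RMSF_i = sqrt(mean_frames |r_i - <r_i>|^2)`.
#'
#' @param traj A `fibril_trajectory` with at least 2 frames.
#' @param map An `assembly_map`.
#' @return An `rmsf_profile`: data.frame `chain`, `label`, `resid`,
#'   `rmsf_nm`.
#' @export
rmsf <- function(traj, map) {
  n_frames <- dim(traj$coords)[1]
  if (n_frames < 2) stop("RMSF needs at least 2 frames")
  topo <- traj$topology
  out <- list()
  for (proto in unique(map$protofilament_of)) {
    chains_p <- protofilament_chains(map, proto)
    anchor <- map$central_chains[map$protofilament_of[map$central_chains] == proto]
    anchor_rows <- ca_indices(topo, anchor)
    ref <- traj$coords[1, anchor_rows, , drop = FALSE][1, , ]
    chain_rows <- lapply(chains_p, function(ch) ca_indices(topo, ch))
    aligned <- lapply(chain_rows, function(rows)
      array(0, dim = c(n_frames, length(rows), 3)))
    for (f in seq_len(n_frames)) {
      fit <- superpose(traj$coords[f, anchor_rows, , drop = FALSE][1, , ], ref)
      for (k in seq_along(chains_p)) {
        aligned[[k]][f, , ] <-
          apply_transform(traj$coords[f, chain_rows[[k]], , drop = FALSE][1, , ], fit)
      }
    }
    for (k in seq_along(chains_p)) {
      arr <- aligned[[k]]
      mean_pos <- apply(arr, c(2, 3), mean)
      dev2 <- sweep(arr, c(2, 3), mean_pos)^2
      msf <- apply(dev2, 2, sum) / n_frames   # sum over xyz, mean over frames
      resid <- topo$atoms$resid[chain_rows[[k]]]
      out[[paste(proto, k)]] <- data.frame(
        chain = chains_p[k], label = unname(map$label_of[chains_p[k]]),
        resid = resid, rmsf_nm = sqrt(msf), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("rmsf_profile", class(res))
  res
}
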