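# Kabsch-Sander secondary-structure assignment, reduced to three states
# {E, H, C}. Only ladder-forming extended bridges count as E (isolated
# bridges, turns, 3/10 and pi helices all collapse to C); this is the
# "beta-strand content" tracked across trajectories.

KS_COUPLING <- 0.084 * 332   # kcal/mol * Angstrom, fixed by the method
KS_CUTOFF <- -0.5            # kcal/mol; bond iff E < cutoff

#' Kabsch-Sander backbone hydrogen-bond energy
#'
#' Electrostatic energy of a putative C=O...H-N hydrogen bond between an
#' acceptor carbonyl (O, C) and a donor amide (N, H),
#' `E = 0.084 * 332 * (1/rON + 1/rCH - 1/rOH - 1/rCN)` kcal/mol with
#' distances in Angstrom. A hydrogen bond is declared iff `E < -0.5`.
#'
#' @param O,C,N,H Numeric length-3 coordinates in nm.
#' @return Energy in kcal/mol.
#' @export
hbond_energy <- function(O, C, N, H) {
  pts <- rbind(O, C, N, H)
  if (min(dist(pts)) < 0.05) {
    stop("degenerate hydrogen-bond geometry: interatomic distance below 0.05 nm")
  }
  rON <- sqrt(sum((O - N)^2)) * 10
  rCH <- sqrt(sum((C - H)^2)) * 10
  rOH <- sqrt(sum((O - H)^2)) * 10
  rCN <- sqrt(sum((C - N)^2)) * 10
  KS_COUPLING * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
}

# Split a structure into a per-residue backbone table. Returns a list with
# matrices N, CA, C, O, H (NA rows where missing), logicals has_bb / has_h,
# chain/resid vectors, and prev/nxt neighbour indices (NA at chain breaks).
backbone_table <- function(structure) {
  a <- structure$atoms
  key <- paste(a$chain, a$resid, sep = "\r")
  ukey <- unique(key)
  n <- length(ukey)
  first <- match(ukey, key)
  chain <- a$chain[first]
  resid <- a$resid[first]
  resname <- a$resname[first]
  pick <- function(nm) {
    m <- matrix(NA_real_, n, 3)
    sel <- which(a$name == nm)
    idx <- match(paste(a$chain[sel], a$resid[sel], sep = "\r"), ukey)
    m[idx, ] <- as.matrix(a[sel, c("x", "y", "z")])
    m
  }
  N <- pick("N"); CA <- pick("CA"); C <- pick("C"); O <- pick("O"); H <- pick("H")
  prv <- c(NA_integer_, seq_len(n - 1))
  nxt <- c(seq_len(n)[-1], NA_integer_)
  brk <- which(chain[-1] != chain[-n] | resid[-1] != resid[-n] + 1L)
  prv[brk + 1L] <- NA_integer_
  nxt[brk] <- NA_integer_
  has_bb <- rowSums(is.na(cbind(N[, 1], CA[, 1], C[, 1], O[, 1]))) == 0
  # reconstruct missing amide H: 1.01 A from N, opposite the bisector of
  # N->C(i-1) and N->CA (standard DSSP practice); no H on chain-initial
  # residues or prolines (cannot donate)
  has_h <- !is.na(H[, 1])
  need <- which(!has_h & has_bb & !is.na(prv) & resname != "PRO")
  if (length(need) > 0) {
    p <- prv[need]
    v1 <- C[p, , drop = FALSE] - N[need, , drop = FALSE]
    v2 <- CA[need, , drop = FALSE] - N[need, , drop = FALSE]
    v1 <- v1 / sqrt(rowSums(v1^2))
    v2 <- v2 / sqrt(rowSums(v2^2))
    bis <- v1 + v2
    nb <- sqrt(rowSums(bis^2))
    ok <- nb > 1e-8 & !is.na(nb)
    hpos <- N[need, , drop = FALSE] - 0.101 * bis / nb
    H[need[ok], ] <- hpos[ok, , drop = FALSE]
    has_h[need[ok]] <- TRUE
  }
  has_h <- has_h & resname != "PRO"
  list(n = n, chain = chain, resid = resid, resname = resname,
       N = N, CA = CA, C = C, O = O, H = H,
       has_bb = has_bb, has_h = has_h, prv = prv, nxt = nxt)
}

# Hydrogen-bond adjacency: hb[i, j] TRUE iff CO of residue i accepts from NH
# of residue j. Candidate pairs prefiltered by CA-CA distance < 0.9 nm.
ks_hbond_matrix <- function(bb) {
  n <- bb$n
  acc <- which(bb$has_bb)
  don <- which(bb$has_bb & bb$has_h)
  if (length(acc) == 0 || length(don) == 0) {
    return(Matrix_false(n))
  }
  CA <- bb$CA
  d2 <- outer(rowSums(CA[acc, , drop = FALSE]^2), rowSums(CA[don, , drop = FALSE]^2), "+") -
    2 * CA[acc, , drop = FALSE] %*% t(CA[don, , drop = FALSE])
  cand <- which(d2 < 0.81 & outer(acc, don, "!=") , arr.ind = TRUE)
  hb <- Matrix_false(n)
  if (nrow(cand) == 0) return(hb)
  i <- acc[cand[, 1]]; j <- don[cand[, 2]]
  dist <- function(A, B) sqrt(rowSums((A - B)^2)) * 10
  rON <- dist(bb$O[i, , drop = FALSE], bb$N[j, , drop = FALSE])
  rCH <- dist(bb$C[i, , drop = FALSE], bb$H[j, , drop = FALSE])
  rOH <- dist(bb$O[i, , drop = FALSE], bb$H[j, , drop = FALSE])
  rCN <- dist(bb$C[i, , drop = FALSE], bb$N[j, , drop = FALSE])
  e <- KS_COUPLING * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
  # clamp pathological overlaps to "no bond" rather than erroring per frame
  e[pmin(rON, rCH, rOH, rCN) < 0.5] <- 0
  bond <- e < KS_CUTOFF
  hb[cbind(i[bond], j[bond])] <- TRUE
  hb
}

Matrix_false <- function(n) matrix(FALSE, n, n)

# Kabsch-Sander bridge + ladder + helix logic on a backbone table
ks_assign <- function(bb, count_bridges = FALSE) {
  n <- bb$n
  hb <- ks_hbond_matrix(bb)
  prv <- bb$prv; nxt <- bb$nxt
  HB <- function(i, j) {
    ok <- !is.na(i) & !is.na(j)
    out <- logical(length(ok))
    out[ok] <- hb[cbind(i[ok], j[ok])]
    out
  }
  # bridges between all candidate pairs (restrict to pairs with any hbond
  # involvement in a neighbourhood to keep it sparse)
  cand <- which(hb | t(hb), arr.ind = TRUE)
  pairs <- unique(rbind(
    cand,
    cbind(pmax(cand[, 1] - 1L, 1L), cand[, 2]),
    cbind(pmin(cand[, 1] + 1L, n), cand[, 2]),
    cbind(cand[, 1], pmax(cand[, 2] - 1L, 1L)),
    cbind(cand[, 1], pmin(cand[, 2] + 1L, n))
  ))
  pairs <- pairs[pairs[, 1] < pairs[, 2], , drop = FALSE]
  sep_ok <- abs(pairs[, 1] - pairs[, 2]) > 2 |
    bb$chain[pairs[, 1]] != bb$chain[pairs[, 2]]
  pairs <- pairs[sep_ok, , drop = FALSE]
  bridge_par <- matrix(FALSE, 0, 2); bridge_anti <- matrix(FALSE, 0, 2)
  if (nrow(pairs) > 0) {
    i <- pairs[, 1]; j <- pairs[, 2]
    par <- (HB(prv[i], j) & HB(j, nxt[i])) | (HB(prv[j], i) & HB(i, nxt[j]))
    anti <- (HB(i, j) & HB(j, i)) | (HB(prv[i], nxt[j]) & HB(prv[j], nxt[i]))
    bridge_par <- pairs[par, , drop = FALSE]
    bridge_anti <- pairs[anti, , drop = FALSE]
  }
  # ladders: a bridge is ladder-forming (code E) if a bridge of the same type
  # exists between sequence neighbours on both strands
  in_ladder <- function(br, dir2) {
    if (nrow(br) == 0) return(integer(0))
    key <- paste(br[, 1], br[, 2])
    ext1 <- paste(br[, 1] + 1L, br[, 2] + dir2) %in% key
    ext0 <- paste(br[, 1] - 1L, br[, 2] - dir2) %in% key
    keep <- ext1 | ext0
    unique(as.integer(br[keep, , drop = FALSE]))
  }
  e_res <- if (count_bridges) {
    unique(c(as.integer(bridge_par), as.integer(bridge_anti)))
  } else {
    unique(c(in_ladder(bridge_par, +1L), in_ladder(bridge_anti, -1L)))
  }
  # alpha helix: two consecutive i -> i+4 turns give H at i..i+3
  i4 <- function(i, k) {       # index i+k within the same chain, else NA
    out <- i
    for (s in seq_len(k)) out <- ifelse(is.na(out), NA_integer_, nxt[out])
    out
  }
  idx <- seq_len(n)
  turn4 <- HB(idx, i4(idx, 4L))          # turn starting at i
  starts <- which(turn4 & c(FALSE, turn4[-n]))  # turn at i-1 and i
  h_res <- integer(0)
  for (s in starts) {
    r <- i4(s, 3L)
    if (!is.na(r)) h_res <- c(h_res, s:(s + 3L))
  }
  codes <- rep("C", n)
  codes[e_res] <- "E"
  codes[unique(h_res)] <- "H"   # helix takes priority, as in DSSP
  codes[!bb$has_bb] <- "C"
  codes
}

#' Assign three-state secondary structure to one structure
#'
#' Kabsch-Sander assignment reduced to `{E, H, C}`: `E` for residues in
#' ladder-forming beta bridges (parallel or antiparallel), `H` for alpha
#' helix (two consecutive i -> i+4 hydrogen-bond turns), `C` otherwise.
#' Missing amide hydrogens are reconstructed in the peptide plane; residues
#' with missing backbone atoms are assigned `C` with a warning.
#'
#' @param structure A `fibril_structure` with backbone atoms N, CA, C, O
#'   (H optional).
#' @param count_bridges If `TRUE`, isolated beta bridges (DSSP code B) also
#'   count as `E`; the default counts ladder-forming bridges only.
#' @return data.frame with columns `chain`, `resid`, `code`.
#' @export
assign_ss <- function(structure, count_bridges = FALSE) {
  bb <- backbone_table(structure)
  if (any(!bb$has_bb)) {
    warning(sum(!bb$has_bb), " residue(s) missing backbone atoms; assigned C")
  }
  data.frame(chain = bb$chain, resid = bb$resid,
             code = ks_assign(bb, count_bridges), stringsAsFactors = FALSE)
}

#' Beta-strand content along a trajectory
#'
#' Per frame, the fraction of selected residues assigned code `E`.
#'
#' @param traj A `fibril_trajectory`.
#' @param chains Optional chain subset.
#' @param residues Optional residue-number subset (tau numbering).
#' @param count_bridges Count isolated bridges as beta (see [assign_ss()]).
#' @return data.frame with columns `time_ns` and `beta_fraction`.
#' @export
beta_fraction <- function(traj, chains = NULL, residues = NULL,
                          count_bridges = FALSE) {
  n_frames <- dim(traj$coords)[1]
  out <- numeric(n_frames)
  for (f in seq_len(n_frames)) {
    ss <- assign_ss(get_frame(traj, f), count_bridges)
    sel <- rep(TRUE, nrow(ss))
    if (!is.null(chains)) sel <- sel & ss$chain %in% chains
    if (!is.null(residues)) sel <- sel & ss$resid %in% residues
    if (!any(sel)) stop("empty residue selection")
    out[f] <- mean(ss$code[sel] == "E")
  }
  data.frame(time_ns = traj$times, beta_fraction = out)
}

#' Aggregate replicate time series into mean and standard deviation
#'
#' @param series_list List of data.frames sharing a time column and one value
#'   column (e.g. outputs of [beta_fraction()] for independent runs).
#' @param value Name of the value column (default: second column of the first
#'   element).
#' @return data.frame with `time_ns`, `mean`, `sd`, `n_runs`.
#' @export
aggregate_series <- function(series_list, value = NULL) {
  stopifnot(length(series_list) >= 1)
  if (is.null(value)) value <- names(series_list[[1]])[2]
  t0 <- series_list[[1]]$time_ns
  mat <- vapply(series_list, function(s) {
    if (!isTRUE(all.equal(s$time_ns, t0))) stop("series have different time grids")
    s[[value]]
  }, numeric(length(t0)))
  mat <- matrix(mat, nrow = length(t0))
  data.frame(time_ns = t0,
             mean = rowMeans(mat),
             sd = apply(mat, 1, sd),
             n_runs = length(series_list))
}
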