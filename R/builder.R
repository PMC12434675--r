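# Idealized cross-beta decamer builder. Each chain is a C-shaped, 77-residue
# backbone trace in its layer plane: two straight strand arms joined by a
# semicircular turn (residues 340-350). In strand segments the carbonyls
# alternate along +/- z (pleat), so that in-register stacking at the given
# rise produces parallel-sheet hydrogen bonds that the Kabsch-Sander
# criterion recognizes; in the turn the carbonyls lie in the layer plane and
# form no interlayer bonds. Protofilament b is the C2 rotation of a about
# the fibril (z) axis. Gaussian bulges on the outer face of arm 1 localize
# the interprotofilament contacts: one bulge at residues ~331-338 carries the
# symmetric PHF interface, two smaller bulges at ~315 / ~322.5 carry the
# asymmetric SF interface (313-317 of one protofilament against 321-324 of
# the other, via a half-period stagger of the anti-aligned arms).

AA3 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE", G = "GLY",
         H = "HIS", I = "ILE", K = "LYS", L = "LEU", M = "MET", N = "ASN",
         P = "PRO", Q = "GLN", R = "ARG", S = "SER", T = "THR", V = "VAL",
         W = "TRP", Y = "TYR")

#' Residue-role table of the builder
#' @param spec A `peptide_spec` (default [tau_core_spec()]).
#' @return data.frame `resid`, `role` (`"strand"` or `"turn"`).
#' @export
builder_roles <- function(spec = tau_core_spec()) {
  turn <- segment_residues(spec, "turn")
  data.frame(resid = spec$residue_numbers,
             role = ifelse(spec$residue_numbers %in% turn, "turn", "strand"),
             stringsAsFactors = FALSE)
}

# Outer-face bulge profile (nm of +y displacement) by chain position index.
# One bulge under residue ~334.5 (index 31.5) carries the symmetric PHF
# interface; two at ~315 / ~322.5 (indices 12 / 19.5) carry the asymmetric
# SF interface. All three are part of the single chain shape.
builder_bump <- function(idx) {
  0.28 * exp(-((idx - 31.5) / 4)^2) +
    0.20 * (exp(-((idx - 12) / 2.5)^2) + exp(-((idx - 19.5) / 2.5)^2))
}

# Calpha path of one chain in its layer plane (x, y), nm
builder_ca_path <- function(n_res = 77L, spacing = 0.38) {
  r_turn <- spacing * 5 / pi             # 180 deg over indices 39..44
  xc <- 38 * spacing                     # x of index 39 (turn entry)
  x <- numeric(n_res); y <- numeric(n_res)
  for (i in seq_len(n_res)) {
    if (i <= 39L) {                       # upper arm (+x), incl. turn entry
      x[i] <- (i - 1L) * spacing
      y[i] <- 0
    } else if (i <= 44L) {                # semicircle, tangent-continuous
      th <- (i - 39L) * pi / 5
      x[i] <- xc + r_turn * sin(th)
      y[i] <- -r_turn * (1 - cos(th))
    } else {                              # lower arm (-x)
      x[i] <- xc - (i - 44L) * spacing
      y[i] <- -2 * r_turn
    }
  }
  # outer-face bulges (interface carriers) on the upper arm only
  arm1 <- seq_len(39L)
  y[arm1] <- y[arm1] + builder_bump(arm1)
  cbind(x = x, y = y)
}

# default protofilament-b placements; derived from the bulge geometry so the
# designed minimum Calpha approach sits inside the contact cutoffs
BUILDER_GAPS <- c(phf = 1.10, sf = 1.33)

#' Build an idealized cross-beta tau decamer
#'
#' @param topology `"phf"` (symmetric interface at ~332-336) or `"sf"`
#'   (asymmetric interface, 313-317 against 321-324).
#' @param n_layers Chains per protofilament (default 5).
#' @param rise Layer rise along the fibril axis in nm (default 0.475, the
#'   canonical cross-beta value).
#' @param twist_deg Twist per layer about the fibril axis in degrees
#'   (default 0).
#' @param gap Interprotofilament placement gap in nm; default depends on
#'   `topology` (tuned so the PHF interface is larger than the SF one).
#' @param spec Peptide spec (default [tau_core_spec()]).
#' @param n_protofilaments 2 (decamer, default) or 1 (single pentamer).
#' @param spacing Calpha spacing along the chain path (nm, default 0.38).
#' @return A `fibril_structure` with backbone atoms N, CA, C, O, H
#'   (5 atoms x 77 residues per chain); chains `A..E` are protofilament a
#'   (stack 1..5 bottom to top), `F..J` protofilament b.
#' @export
build_fibril <- function(topology = c("phf", "sf"), n_layers = 5L,
                         rise = 0.475, twist_deg = 0, gap = NULL,
                         spec = tau_core_spec(), n_protofilaments = 2L,
                         spacing = 0.38) {
  topology <- match.arg(topology)
  stopifnot(rise > 0, n_layers >= 2)
  if (is.null(gap)) gap <- BUILDER_GAPS[[topology]]
  n_res <- length(spec$residue_numbers)
  roles <- builder_roles(spec)
  path_a <- builder_ca_path(n_res, spacing)
  # protofilament b: C2 rotation about the z axis through the interface
  # midline. For phf the C2 axis sits over the large bulge (index 31.5); for
  # sf it sits at the stagger midpoint (index 15.75) so bulge 315 of one
  # protofilament faces bulge 322.5 of the other.
  c2_idx <- if (topology == "phf") 31.5 else 15.75
  qx <- (c2_idx - 1) * spacing
  path_b <- cbind(x = 2 * qx - path_a[, "x"], y = gap - path_a[, "y"])
  chains_xy <- c(list(path_a), if (n_protofilaments == 2L) list(path_b))
  chain_ids <- if (n_protofilaments == 2L) {
    c(LETTERS[1:n_layers], LETTERS[5 + (1:n_layers)])
  } else LETTERS[1:n_layers]
  # fibril axis for the per-layer twist: centroid of all layer-1 Calphas
  axis_xy <- colMeans(do.call(rbind, chains_xy))
  seq1 <- strsplit(spec$sequence, "")[[1]]
  atoms_list <- list()
  for (p in seq_along(chains_xy)) {
    for (k in seq_len(n_layers)) {
      theta <- (k - 1) * twist_deg * pi / 180
      R2 <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
      xy <- sweep(chains_xy[[p]], 2, axis_xy)
      xy <- xy %*% t(R2)
      xy <- sweep(xy, 2, axis_xy, FUN = "+")
      bb <- builder_backbone(xy, z0 = (k - 1) * rise, roles$role)
      n_at <- nrow(bb)
      atoms_list[[length(atoms_list) + 1L]] <- data.frame(
        name = bb$name,
        resname = AA3[seq1[bb$ires]],
        chain = chain_ids[(p - 1L) * n_layers + k],
        resid = spec$residue_numbers[bb$ires],
        x = bb$x, y = bb$y, z = bb$z,
        element = substr(bb$name, 1, 1),
        stringsAsFactors = FALSE)
    }
  }
  atoms <- do.call(rbind, atoms_list)
  rownames(atoms) <- NULL
  s <- new_structure(atoms, title = sprintf("idealized %s decamer (synthetic)",
                                            toupper(topology)))
  check_clashes(s)
  s
}

# backbone atoms for one chain layer given the Calpha path (n x 2) and the
# layer z. Strand residues: pleated carbonyls along +/- z. Turn residues:
# carbonyls in-plane (no interlayer hydrogen bonds).
builder_backbone <- function(xy, z0, role) {
  n <- nrow(xy)
  p <- cbind(xy, z0)
  u <- rbind(p[-1, ] - p[-n, ], p[n, ] - p[n - 1, ])
  u <- u / sqrt(rowSums(u^2))
  zhat <- c(0, 0, 1)
  dir <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    if (role[i] == "strand") {
      dir[i, ] <- zhat * ifelse(i %% 2 == 0, 1, -1)
    } else {
      w <- c(-u[i, 2], u[i, 1], 0)       # in-plane normal
      dir[i, ] <- w / sqrt(sum(w^2))
    }
  }
  Cp <- p + 0.14 * u + 0.05 * dir        # carbonyl carbon
  O <- Cp + 0.123 * dir
  Np <- matrix(0, n, 3)                  # amide nitrogen of residue i
  Hp <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    j <- max(i - 1L, 1L)                 # peptide plane shared with i-1
    Np[i, ] <- p[i, ] - 0.12 * u[j, ] + 0.05 * dir[j, ]
    Hp[i, ] <- Np[i, ] - 0.101 * dir[j, ]
  }
  out <- data.frame(
    ires = rep(seq_len(n), each = 5L),
    name = rep(c("N", "CA", "C", "O", "H"), n),
    x = 0, y = 0, z = 0)
  coords <- matrix(0, 5L * n, 3)
  for (i in seq_len(n)) {
    coords[(i - 1L) * 5L + 1:5, ] <- rbind(Np[i, ], p[i, ], Cp[i, ], O[i, ], Hp[i, ])
  }
  out$x <- coords[, 1]; out$y <- coords[, 2]; out$z <- coords[, 3]
  out
}

check_clashes <- function(structure, min_dist = 0.15) {
  a <- structure$atoms
  # check across chains only (intra-chain bonded distances are < min_dist by
  # construction of the peptide unit)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  ch <- a$chain
  for (c1 in unique(ch)) {
    i <- which(ch == c1); j <- which(ch != c1 & ch > c1)
    if (length(j) == 0) next
    # block-wise min distance
    d2min <- Inf
    for (blk in split(i, ceiling(seq_along(i) / 500))) {
      d2 <- outer(rowSums(xyz[blk, , drop = FALSE]^2), rowSums(xyz[j, , drop = FALSE]^2), "+") -
        2 * xyz[blk, , drop = FALSE] %*% t(xyz[j, , drop = FALSE])
      d2min <- min(d2min, min(d2))
    }
    if (d2min < min_dist^2) {
      stop(sprintf("steric collision: interchain distance %.3f nm below %.2f nm",
                   sqrt(max(d2min, 0)), min_dist))
    }
  }
  invisible(structure)
}

#' Generate synthetic beta-content decay traces
#'
#' Draws `n_runs` replicate series `y(t) = model(t) + N(0, sigma)` clipped to
#' `[0, 1]`, emulating per-run beta-strand content decays.
#'
#' @param model Decay model id (`"m1"`..`"m4"`).
#' @param par Named true parameters (subset of A, B, C, D per model).
#' @param sigma Gaussian noise standard deviation.
#' @param n_runs,n_points Number of replicate series and points per series.
#' @param t_max Time range (series sampled on `seq(0, t_max, length.out =
#'   n_points)`).
#' @param seed RNG seed (reproducible).
#' @return List of data.frames (`time_ns`, `beta_fraction`, `run_id`).
#' @export
generate_decay_traces <- function(model = "m3",
                                  par = c(A = 0.6, B = 0.5, D = 5.0),
                                  sigma = 0.02, n_runs = 10L, n_points = 100L,
                                  t_max = 10, seed = 1L) {
  stopifnot(sigma >= 0, n_points >= 2)
  tc <- par[names(par) %in% c("B", "D")]
  stopifnot(all(tc > 0))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  t <- seq(0, t_max, length.out = n_points)
  base <- decay_value(model, as.list(par), t)
  lapply(seq_len(n_runs), function(r) {
    y <- base + rnorm(n_points, 0, sigma)
    data.frame(time_ns = t, beta_fraction = pmin(1, pmax(0, y)), run_id = r)
  })
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Kinematic perturbation of a structure into a synthetic trajectory
#'
#' Applies a schedule of degradation-mimicking events to a starting
#' structure: independent Gaussian jitter on terminal segments, enhanced
#' jitter on the turn (340-350), and a rigid separation of protofilament b
#' from frame `separation_frame` onward. Purely kinematic; no dynamics.
#'
#' @param structure Starting `fibril_structure`.
#' @param map An `assembly_map` (needed for separation; may be `NULL`).
#' @param n_frames Number of frames.
#' @param dt_ns Frame spacing in ns.
#' @param terminus_sigma Per-coordinate jitter sd (nm) on the first/last
#'   `n_terminus` residues of each chain (0 disables).
#' @param n_terminus Number of residues per terminus (default 5).
#' @param turn_sigma Per-coordinate jitter sd (nm) on residues 340-350.
#' @param turn_residues Residue numbers of the turn.
#' @param separation_frame Frame index from which protofilament b moves away
#'   (`NA` disables).
#' @param separation_velocity Rigid displacement per frame (nm) of
#'   protofilament b along +y.
#' @param seed RNG seed.
#' @return A `fibril_trajectory`.
#' @export
perturb_trajectory <- function(structure, map = NULL, n_frames = 20L,
                               dt_ns = 1, terminus_sigma = 0, n_terminus = 5L,
                               turn_sigma = 0, turn_residues = 340:350,
                               separation_frame = NA, separation_velocity = 0.5,
                               seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  a <- structure$atoms
  n_at <- nrow(a)
  base <- as.matrix(a[, c("x", "y", "z")])
  jitter_rows <- integer(0)
  sig <- numeric(0)
  if (terminus_sigma > 0) {
    for (ch in unique(a$chain)) {
      res <- sort(unique(a$resid[a$chain == ch]))
      term <- c(utils::head(res, n_terminus), utils::tail(res, n_terminus))
      rows <- which(a$chain == ch & a$resid %in% term)
      jitter_rows <- c(jitter_rows, rows)
      sig <- c(sig, rep(terminus_sigma, length(rows)))
    }
  }
  if (turn_sigma > 0) {
    rows <- which(a$resid %in% turn_residues)
    jitter_rows <- c(jitter_rows, rows)
    sig <- c(sig, rep(turn_sigma, length(rows)))
  }
  b_rows <- if (!is.null(map) && !is.na(separation_frame)) {
    which(a$chain %in% protofilament_chains(map, "b"))
  } else integer(0)
  coords <- array(0, dim = c(n_frames, n_at, 3))
  for (f in seq_len(n_frames)) {
    fr <- base
    if (length(jitter_rows) > 0 && f > 1) {
      fr[jitter_rows, ] <- fr[jitter_rows, ] +
        matrix(rnorm(3 * length(jitter_rows), 0, sig), ncol = 3)
    }
    if (length(b_rows) > 0 && f >= separation_frame) {
      fr[b_rows, 2] <- fr[b_rows, 2] + separation_velocity * (f - separation_frame + 1)
    }
    coords[f, , ] <- fr
  }
  make_trajectory(structure, coords, dt_ns * (seq_len(n_frames) - 1))
}
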