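# Independent oracles used by the test suite. These deliberately share no
# code with the package implementation: a quaternion (Horn) superposition, a
# second Kabsch-Sander implementation written from the method definition, a
# brute-force contact enumerator, and a NeRF internal-coordinate peptide
# builder for ideal helix/strand fixtures.

# ---- quaternion-based rigid superposition (Horn 1987) -----------------------
oracle_superpose <- function(mobile, reference) {
  mc <- colMeans(mobile); rc <- colMeans(reference)
  X <- sweep(mobile, 2, mc); Y <- sweep(reference, 2, rc)
  S <- crossprod(X, Y)
  N <- matrix(0, 4, 4)
  N[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  N[1, 2] <- N[2, 1] <- S[2, 3] - S[3, 2]
  N[1, 3] <- N[3, 1] <- S[3, 1] - S[1, 3]
  N[1, 4] <- N[4, 1] <- S[1, 2] - S[2, 1]
  N[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  N[2, 3] <- N[3, 2] <- S[1, 2] + S[2, 1]
  N[2, 4] <- N[4, 2] <- S[1, 3] + S[3, 1]
  N[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  N[3, 4] <- N[4, 3] <- S[2, 3] + S[3, 2]
  N[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), w^2 - x^2 - y^2 + z^2
  ), 3, 3, byrow = TRUE)
  t_vec <- rc - as.numeric(R %*% mc)
  fitted <- mobile %*% t(R) + matrix(t_vec, nrow(mobile), 3, byrow = TRUE)
  list(rotation = R, translation = t_vec,
       rmsd = sqrt(mean(rowSums((fitted - reference)^2))))
}

# ---- independent Kabsch-Sander assignment -----------------------------------
# Straightforward nested-loop implementation from the method definition.
# Input: a fibril_structure. Output: character codes per residue (E/H/C),
# in the same order as unique (chain, resid).
oracle_dssp <- function(structure) {
  a <- structure$atoms
  key <- unique(a[, c("chain", "resid")])
  n <- nrow(key)
  getat <- function(i, nm) {
    r <- a[a$chain == key$chain[i] & a$resid == key$resid[i] & a$name == nm, ]
    if (nrow(r) == 0) return(NULL)
    as.numeric(r[1, c("x", "y", "z")])
  }
  Ns <- lapply(1:n, getat, nm = "N"); CAs <- lapply(1:n, getat, nm = "CA")
  Cs <- lapply(1:n, getat, nm = "C"); Os <- lapply(1:n, getat, nm = "O")
  Hs <- lapply(1:n, getat, nm = "H")
  resname <- vapply(1:n, function(i)
    a$resname[a$chain == key$chain[i] & a$resid == key$resid[i]][1], "")
  bonded_prev <- function(i) {
    i > 1 && key$chain[i] == key$chain[i - 1] && key$resid[i] == key$resid[i - 1] + 1
  }
  # reconstruct H where absent (same geometric rule, independent code)
  for (i in 1:n) {
    if (is.null(Hs[[i]]) && bonded_prev(i) && resname[i] != "PRO" &&
        !is.null(Ns[[i]]) && !is.null(CAs[[i]]) && !is.null(Cs[[i - 1]])) {
      v1 <- Cs[[i - 1]] - Ns[[i]]; v1 <- v1 / sqrt(sum(v1^2))
      v2 <- CAs[[i]] - Ns[[i]]; v2 <- v2 / sqrt(sum(v2^2))
      b <- v1 + v2
      if (sqrt(sum(b^2)) > 1e-8) Hs[[i]] <- Ns[[i]] - 0.101 * b / sqrt(sum(b^2))
    }
  }
  hbond <- matrix(FALSE, n, n)   # hbond[i,j]: CO of i accepts NH of j
  for (i in 1:n) {
    if (is.null(Cs[[i]]) || is.null(Os[[i]])) next
    for (j in 1:n) {
      if (i == j) next
      if (is.null(Ns[[j]]) || is.null(Hs[[j]]) || resname[j] == "PRO") next
      if (sum((CAs[[i]] - CAs[[j]])^2) > 0.81) next
      rON <- sqrt(sum((Os[[i]] - Ns[[j]])^2)) * 10
      rCH <- sqrt(sum((Cs[[i]] - Hs[[j]])^2)) * 10
      rOH <- sqrt(sum((Os[[i]] - Hs[[j]])^2)) * 10
      rCN <- sqrt(sum((Cs[[i]] - Ns[[j]])^2)) * 10
      e <- 0.084 * 332 * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
      hbond[i, j] <- e < -0.5
    }
  }
  hb <- function(i, j) {
    !is.na(i) && !is.na(j) && i >= 1 && j >= 1 && i <= n && j <= n && hbond[i, j]
  }
  prv <- function(i) if (bonded_prev(i)) i - 1L else NA_integer_
  nxt <- function(i) if (i < n && bonded_prev(i + 1L)) i + 1L else NA_integer_
  par_bridge <- matrix(FALSE, n, n); anti_bridge <- matrix(FALSE, n, n)
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    close_seq <- key$chain[i] == key$chain[j] && abs(key$resid[i] - key$resid[j]) <= 2
    if (close_seq) next
    if ((hb(prv(i), j) && hb(j, nxt(i))) || (hb(prv(j), i) && hb(i, nxt(j)))) {
      par_bridge[i, j] <- TRUE
    }
    if ((hb(i, j) && hb(j, i)) || (hb(prv(i), nxt(j)) && hb(prv(j), nxt(i)))) {
      anti_bridge[i, j] <- TRUE
    }
  }
  codes <- rep("C", n)
  for (i in 1:n) for (j in 1:n) {
    if (par_bridge[i, j] &&
        ((!is.na(nxt(i)) && !is.na(nxt(j)) && par_bridge[nxt(i), nxt(j)]) ||
         (!is.na(prv(i)) && !is.na(prv(j)) && par_bridge[prv(i), prv(j)]))) {
      codes[i] <- "E"
    }
    if (anti_bridge[i, j] &&
        ((!is.na(nxt(i)) && !is.na(prv(j)) && anti_bridge[nxt(i), prv(j)]) ||
         (!is.na(prv(i)) && !is.na(nxt(j)) && anti_bridge[prv(i), nxt(j)]))) {
      codes[i] <- "E"
    }
  }
  turn4 <- rep(FALSE, n)
  for (i in 1:n) {
    j <- i
    ok <- TRUE
    for (s in 1:4) { j <- nxt(j); if (is.na(j)) { ok <- FALSE; break } }
    turn4[i] <- ok && hb(i, j)
  }
  for (i in 2:n) {
    if (turn4[i] && turn4[i - 1]) {
      j <- i
      for (s in 0:3) { if (!is.na(j)) { codes[j] <- "H"; j <- nxt(j) } }
    }
  }
  codes
}

# ---- brute-force contact enumeration and survival ---------------------------
oracle_contact_fraction <- function(traj, map) {
  # returns per-frame fractions per class, by direct double loops
  s0 <- get_frame(traj, 1)
  at <- s0$atoms[s0$atoms$name == "CA", ]
  n <- nrow(at)
  cutoffs <- c(intrapeptide = 1.25, interpeptide = 0.8, interprotofilament = 1.0)
  ref <- list()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- sqrt(sum((as.numeric(at[i, c("x", "y", "z")]) -
                     as.numeric(at[j, c("x", "y", "z")]))^2))
    same <- at$chain[i] == at$chain[j]
    if (same && abs(at$resid[i] - at$resid[j]) > 3 && d < cutoffs[1]) {
      ref[[length(ref) + 1]] <- c(i, j, 1)
    }
    if (!same && d < cutoffs[2]) ref[[length(ref) + 1]] <- c(i, j, 2)
    if (!is.null(map) && !same &&
        map$protofilament_of[at$chain[i]] != map$protofilament_of[at$chain[j]] &&
        d < cutoffs[3]) {
      ref[[length(ref) + 1]] <- c(i, j, 3)
    }
  }
  ref <- do.call(rbind, ref)
  ca_rows <- which(traj$topology$atoms$name == "CA")
  out <- list()
  for (f in seq_len(dim(traj$coords)[1])) {
    xyz <- traj$coords[f, ca_rows, , drop = FALSE][1, , ]
    for (cl in 1:3) {
      sub <- ref[ref[, 3] == cl, , drop = FALSE]
      if (nrow(sub) == 0) next
      alive <- vapply(seq_len(nrow(sub)), function(r) {
        sqrt(sum((xyz[sub[r, 1], ] - xyz[sub[r, 2], ])^2)) < cutoffs[cl]
      }, logical(1))
      out[[length(out) + 1]] <- data.frame(
        frame = f, class = names(cutoffs)[cl], fraction = mean(alive))
    }
  }
  do.call(rbind, out)
}

# ---- NeRF internal-coordinate peptide builder -------------------------------
# Places atom d given positions a, b, c and (bond length c-d, angle b-c-d in
# degrees, torsion a-b-c-d in degrees).
nerf_place <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180; tor <- torsion * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  nv <- pracma_cross(ab, bc); nv <- nv / sqrt(sum(nv^2))
  m <- pracma_cross(nv, bc)
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor), bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * nv
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3], u[1] * v[2] - u[2] * v[1])
}

# Ideal polypeptide backbone (N, CA, C, O) with constant phi/psi, in nm.
# omega fixed at 180. Returns a fibril_structure.
build_ideal_peptide <- function(n_res, phi, psi, chain = "A", resid0 = 1L) {
  b_NCa <- 0.1458; b_CaC <- 0.1525; b_CN <- 0.1329; b_CO <- 0.1231
  a_NCaC <- 111.2; a_CaCN <- 116.2; a_CNCa <- 121.7; a_CaCO <- 120.8
  N <- CA <- C <- O <- matrix(0, n_res, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(b_NCa, 0, 0)
  C[1, ] <- nerf_place(c(-0.1, 0.1, 0), N[1, ], CA[1, ], b_CaC, a_NCaC, -60)
  for (i in 2:n_res) {
    # psi(i-1): N(i-1)-CA(i-1)-C(i-1)-N(i); omega = 180; phi(i): C(i-1)-N(i)-CA(i)-C(i)
    N[i, ] <- nerf_place(N[i - 1, ], CA[i - 1, ], C[i - 1, ], b_CN, a_CaCN, psi)
    CA[i, ] <- nerf_place(CA[i - 1, ], C[i - 1, ], N[i, ], b_NCa, a_CNCa, 180)
    C[i, ] <- nerf_place(C[i - 1, ], N[i, ], CA[i, ], b_CaC, a_NCaC, phi)
  }
  for (i in 1:n_res) {
    O[i, ] <- nerf_place(N[i, ], CA[i, ], C[i, ], b_CO, a_CaCO, psi + 180)
  }
  rows <- list()
  for (i in 1:n_res) {
    xyz <- rbind(N[i, ], CA[i, ], C[i, ], O[i, ])
    rows[[i]] <- data.frame(name = c("N", "CA", "C", "O"), resname = "ALA",
                            chain = chain, resid = resid0 + i - 1L,
                            x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                            element = c("N", "C", "C", "O"),
                            stringsAsFactors = FALSE)
  }
  taufield:::new_structure(do.call(rbind, rows),
                           title = sprintf("ideal phi=%g psi=%g", phi, psi))
}

# independent dihedral: angle between plane normals, sign by triple product
oracle_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- pracma_cross(b1, b2); n2 <- pracma_cross(b2, b3)
  cosang <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  if (sum(pracma_cross(n1, n2) * b2) < 0) ang <- -ang
  ang
}
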