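# Coarse-grained charged elastic-network model under an oscillating external
# electric field, integrated by overdamped Langevin (Brownian) dynamics.
# One bead per residue at the Calpha position; formal side-chain charges
# (K/R +1, D/E -1); harmonic springs between beads within a cutoff, with a
# separately configurable (typically weaker) stiffness across the
# protofilament interface. Units: kJ/mol, nm, ps, elementary charge, K.

KB_KJMOL <- 0.0083144621        # Boltzmann constant, kJ/(mol K)
EVNM_TO_KJMOLNM <- 96.485       # 1 e V/nm in kJ/(mol nm) (Faraday/1000)

#' Oscillating-field specification
#'
#' @param E0 Field strength in mV/nm (>= 0).
#' @param freq_GHz Oscillation frequency in GHz (0 = static field).
#' @param axis Field direction (3-vector, normalized internally).
#' @return A `field_spec` list.
#' @export
field_spec <- function(E0, freq_GHz, axis = c(0, 1, 0)) {
  stopifnot(E0 >= 0, freq_GHz >= 0, length(axis) == 3)
  nrm <- sqrt(sum(axis^2))
  if (nrm == 0) stop("field axis must be nonzero")
  structure(list(E0 = E0, freq_GHz = freq_GHz, axis = axis / nrm),
            class = "field_spec")
}

#' Field vector at a time point
#'
#' `E(t) = E0 cos(2 pi nu t) axis` (continuous oscillation, no pulse
#' envelope).
#'
#' @param t_ps Time in ps (>= 0).
#' @param spec A `field_spec`.
#' @return Field vector in mV/nm.
#' @export
field_at <- function(t_ps, spec) {
  stopifnot(inherits(spec, "field_spec"), t_ps >= 0)
  omega <- 2 * pi * spec$freq_GHz * 1e-3   # rad/ps
  spec$E0 * cos(omega * t_ps) * spec$axis
}

#' Force on a charge in an external field
#'
#' `F = q E`, converting e * mV/nm to kJ/(mol nm) via the Faraday constant
#' (1 e V/nm = 96.485 kJ/(mol nm)).
#'
#' @param charge Charge in elementary units.
#' @param field_mV_nm Field (vector or scalar) in mV/nm.
#' @return Force in kJ/(mol nm).
#' @export
field_force <- function(charge, field_mV_nm) {
  charge * field_mV_nm * 1e-3 * EVNM_TO_KJMOLNM
}

three_to_one <- function(resname) {
  m <- setNames(names(AA3), AA3)
  out <- m[resname]
  if (anyNA(out)) stop("unknown residue name(s): ",
                       paste(unique(resname[is.na(out)]), collapse = ", "))
  out
}

#' Build a charged elastic-network system from a structure
#'
#' Beads sit on Calpha atoms and carry the formal side-chain charge of their
#' residue. Springs connect bead pairs within `cutoff`, at rest at their
#' starting distance; springs crossing the protofilament interface get
#' stiffness `k_inter` (weaker by default, making field- or thermally-driven
#' protofilament separation reachable).
#'
#' @param structure A `fibril_structure`.
#' @param map Optional `assembly_map` (enables the interface spring class).
#' @param cutoff Spring cutoff in nm (default 1.2).
#' @param k Intra/interchain spring stiffness, kJ/(mol nm^2) (default 100).
#' @param k_inter Interprotofilament spring stiffness (default 10).
#' @param gamma Friction, kJ mol^-1 ps nm^-2 (default 2000; sets the
#'   corner frequency k/(2 pi gamma) between the responsive and
#'   non-responsive field regimes).
#' @param temperature Kelvin (default 300).
#' @return An `enm_system`.
#' @export
build_enm <- function(structure, map = NULL, cutoff = 1.2, k = 100,
                      k_inter = 10, gamma = 2000, temperature = 300) {
  stopifnot(k > 0, k_inter > 0, gamma > 0)
  ca <- ca_table(structure)
  xyz <- as.matrix(ca[, c("x", "y", "z")])
  n <- nrow(xyz)
  aa1 <- three_to_one(structure$atoms$resname[structure$atoms$name == "CA"])
  charges <- assign_charges(paste(aa1, collapse = ""))
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * tcrossprod(xyz)
  d2[d2 < 0] <- 0
  pairs <- which(upper.tri(d2) & d2 < cutoff^2, arr.ind = TRUE)
  kk <- rep(k, nrow(pairs))
  if (!is.null(map)) {
    proto <- map$protofilament_of[ca$chain]
    inter <- proto[pairs[, 1]] != proto[pairs[, 2]]
    kk[inter] <- k_inter
  }
  structure(list(
    coords = xyz, chain = ca$chain, resid = ca$resid, charge = charges,
    springs = data.frame(i = pairs[, 1], j = pairs[, 2], k = kk,
                         r0 = sqrt(d2[pairs])),
    anchor_k = rep(0, n), anchor_pos = xyz,
    gamma = gamma, temperature = temperature
  ), class = "enm_system")
}

#' Minimal hand-built ENM system (for analytic checks)
#'
#' @param coords n x 3 bead coordinates (nm).
#' @param charge Length-n charges (e).
#' @param springs data.frame `i`, `j`, `k`, `r0` (may have zero rows).
#' @param anchor_k Per-bead harmonic anchor stiffness to the initial
#'   position (0 = free).
#' @param gamma,temperature As in [build_enm()].
#' @return An `enm_system`.
#' @export
enm_system <- function(coords, charge = rep(0, nrow(coords)),
                       springs = data.frame(i = integer(0), j = integer(0),
                                            k = numeric(0), r0 = numeric(0)),
                       anchor_k = rep(0, nrow(coords)),
                       gamma = 50, temperature = 300) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  structure(list(coords = coords, chain = rep("A", nrow(coords)),
                 resid = seq_len(nrow(coords)), charge = charge,
                 springs = springs, anchor_k = anchor_k, anchor_pos = coords,
                 gamma = gamma, temperature = temperature),
            class = "enm_system")
}

#' @export
print.enm_system <- function(x, ...) {
  cat("enm_system:", nrow(x$coords), "beads,", nrow(x$springs), "springs,",
      sum(x$charge != 0), "charged; gamma =", x$gamma,
      "T =", x$temperature, "K\n")
  invisible(x)
}

#' Simulate a charged elastic network under an oscillating field
#'
#' Overdamped Langevin update: position increment
#' `(dt/gamma) (F_spring + qE(t)) + sqrt(2 kBT dt / gamma) * eta`.
#' Reproducible via `set.seed` (noise comes from R's RNG). Aborts with a
#' diagnostic if any per-step displacement exceeds 0.5 nm.
#'
#' @param system An `enm_system`.
#' @param field A `field_spec` (or `NULL` for no field).
#' @param dt Time step in ps; must satisfy `dt * k_max / gamma < 0.1`.
#' @param n_steps Number of steps.
#' @param stride Save every `stride`-th frame (plus the initial one).
#' @param seed Optional seed (`set.seed(seed)` before integrating).
#' @return A `fibril_trajectory` of Calpha pseudo-atoms (times in ns).
#' @export
simulate_enm <- function(system, field = NULL, dt = 1, n_steps = 1000L,
                         stride = 10L, seed = NULL) {
  stopifnot(inherits(system, "enm_system"))
  kmax <- max(c(system$springs$k, system$anchor_k, 0))
  if (kmax > 0 && dt * kmax / system$gamma >= 0.1) {
    stop("unstable time step: dt * k / gamma = ",
         signif(dt * kmax / system$gamma, 3), " >= 0.1")
  }
  if (is.null(field)) field <- field_spec(0, 0)
  famp <- field_force(1, field$E0)         # kJ/(mol nm) per unit charge
  omega <- 2 * pi * field$freq_GHz * 1e-3  # rad/ps
  kBT <- KB_KJMOL * system$temperature
  if (!is.null(seed)) set.seed(seed)
  arr <- simulate_enm_cpp(system$coords,
                          as.integer(system$springs$i - 1L),
                          as.integer(system$springs$j - 1L),
                          as.numeric(system$springs$k),
                          as.numeric(system$springs$r0),
                          as.numeric(system$anchor_k), system$anchor_pos,
                          as.numeric(system$charge),
                          famp, field$axis, omega, system$gamma, kBT,
                          dt, as.integer(n_steps), as.integer(stride))
  n_frames <- dim(arr)[1]
  atoms <- data.frame(
    name = "CA",
    resname = "GLY",
    chain = system$chain,
    resid = system$resid,
    x = system$coords[, 1], y = system$coords[, 2], z = system$coords[, 3],
    element = "C", stringsAsFactors = FALSE)
  topo <- new_structure(atoms, title = "enm beads")
  times_ns <- dt * stride * (seq_len(n_frames) - 1) * 1e-3
  make_trajectory(topo, arr, times_ns)
}

#' Closed-form and simulated response amplitude of a driven bead
#'
#' For a single charged bead in a harmonic well `k` under
#' `E(t) = E0 cos(2 pi nu t)`, the steady-state oscillation amplitude is
#' `q E0 / sqrt(k^2 + (2 pi nu gamma)^2)` (overdamped linear response).
#' Optionally also estimates the amplitude from a noiseless simulation by
#' projecting the trajectory onto the drive frequency.
#'
#' @param k Well stiffness, kJ/(mol nm^2).
#' @param gamma Friction, kJ mol^-1 ps nm^-2.
#' @param charge Charge (e).
#' @param field A `field_spec`.
#' @param simulate If `TRUE`, also run a noiseless simulation.
#' @param n_periods,dt Simulation length (drive periods) and time step (ps).
#' @return List with `analytic` (nm) and, if simulated, `simulated` (nm).
#' @export
response_amplitude <- function(k, gamma, charge, field, simulate = FALSE,
                               n_periods = 5, dt = 0.5) {
  omega <- 2 * pi * field$freq_GHz * 1e-3
  fq <- field_force(charge, field$E0)
  analytic <- abs(fq) / sqrt(k^2 + (omega * gamma)^2)
  out <- list(analytic = analytic)
  if (simulate) {
    if (omega == 0) stop("simulated amplitude needs a nonzero frequency")
    period <- 2 * pi / omega
    sys <- enm_system(matrix(0, 1, 3), charge = charge, anchor_k = k,
                      gamma = gamma, temperature = 0)
    relax <- 5 * gamma / k                    # transient decay time
    n_relax <- ceiling(relax / dt)
    n_meas <- ceiling(n_periods * period / dt)
    traj <- simulate_enm(sys, field, dt = dt, n_steps = n_relax + n_meas,
                         stride = 1L)
    # project measurement window onto e^{-i omega t}
    idx <- (n_relax + 1):(n_relax + n_meas)
    tt <- (idx - 1) * dt
    xx <- traj$coords[idx + 1, 1, ] %*% field$axis
    amp <- 2 * sqrt(mean(xx * cos(omega * tt))^2 + mean(xx * sin(omega * tt))^2)
    out$simulated <- as.numeric(amp)
  }
  out
}
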