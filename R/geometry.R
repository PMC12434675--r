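# Sheet-twist dihedral, Shrake-Rupley solvent-accessible surface area, and
# protofilament interface area by SASA subtraction.

#' Signed dihedral angle over four points
#'
#' IUPAC convention: right-handed, trans = 180 degrees; range (-180, 180].
#'
#' @param p1,p2,p3,p4 Numeric length-3 coordinates.
#' @return Angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  # sin term: (n1 x n2) . b2_unit; cos term: n1 . n2 (IUPAC sign convention)
  n1xn2 <- c(n1[2] * n2[3] - n1[3] * n2[2],
             n1[3] * n2[1] - n1[1] * n2[3],
             n1[1] * n2[2] - n1[2] * n2[1])
  ang <- atan2(sum(n1xn2 * b2) / sqrt(sum(b2^2)), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Beta-sheet twist between adjacent peptides
#'
#' The dihedral angle over the Calpha atoms (306 of chain 1a, 310 of chain
#' 1a, 310 of chain 2a, 306 of chain 2a) quantifying the twist of the sheet
#' between the first two layers of protofilament a.
#'
#' @param structure A `fibril_structure`.
#' @param map An `assembly_map`.
#' @param residues Two residue numbers delimiting the probe strand
#'   (default `c(306, 310)`).
#' @return Signed dihedral in degrees.
#' @export
sheet_twist <- function(structure, map, residues = c(306L, 310L)) {
  ch1 <- map$chain_ids[map$label_of == "1a"]
  ch2 <- map$chain_ids[map$label_of == "2a"]
  a <- structure$atoms
  grab <- function(ch, res) {
    row <- a[a$chain == ch & a$resid == res & a$name == "CA", c("x", "y", "z")]
    if (nrow(row) != 1) stop("missing Calpha for chain ", ch, " residue ", res)
    as.numeric(row)
  }
  dihedral_angle(grab(ch1, residues[1]), grab(ch1, residues[2]),
                 grab(ch2, residues[2]), grab(ch2, residues[1]))
}

#' Sheet-twist time series over a trajectory
#' @param traj A `fibril_trajectory`.
#' @param map An `assembly_map`.
#' @param residues Passed to [sheet_twist()].
#' @return data.frame `time_ns`, `twist_deg`.
#' @export
twist_series <- function(traj, map, residues = c(306L, 310L)) {
  n <- dim(traj$coords)[1]
  tw <- vapply(seq_len(n),
               function(f) sheet_twist(get_frame(traj, f), map, residues),
               numeric(1))
  data.frame(time_ns = traj$times, twist_deg = tw)
}

# heavy-atom van der Waals radii (Angstrom), element-keyed; hydrogens are
# excluded from SASA by default (cryo-EM models are heavy-atom)
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20)

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Sphere-sampling SASA with a probe of 1.4 Angstrom by default. Hydrogens
#' are excluded unless `include_h = TRUE`. Note the probe is specified in nm
#' (internal unit) but areas are returned in Angstrom^2, the field's
#' customary unit for interface areas.
#'
#' @param structure A `fibril_structure`.
#' @param probe Probe radius in nm (default 0.14).
#' @param n_points Quadrature points per atom (default 960; single-sphere
#'   error < 0.5 percent).
#' @param include_h Include hydrogen atoms (default `FALSE`).
#' @return List with `total` (Angstrom^2) and `per_atom` (vector, one entry
#'   per retained atom, named by atom table row).
#' @export
sasa <- function(structure, probe = 0.14, n_points = 960L, include_h = FALSE) {
  a <- structure$atoms
  if (!include_h) a <- a[a$element != "H", ]
  if (nrow(a) == 0) stop("no atoms left for SASA")
  r <- VDW_RADII[a$element]
  if (anyNA(r)) {
    bad <- unique(a$element[is.na(r)])
    stop("no van der Waals radius for element(s): ", paste(bad, collapse = ", "))
  }
  xyz <- as.matrix(a[, c("x", "y", "z")]) * 10  # nm -> Angstrom
  per <- sasa_cpp(xyz, unname(r), probe * 10, as.integer(n_points))
  list(total = sum(per), per_atom = per)
}

#' Protofilament interface area by SASA subtraction
#'
#' `sasa(pentamer a) + sasa(pentamer b) - sasa(decamer)`. Note this is twice
#' the conventional per-side buried area; the convention (sum-minus-complex)
#' is kept deliberately.
#'
#' @param structure A `fibril_structure` of the decamer.
#' @param map An `assembly_map` partitioning the chains into protofilaments
#'   `a` and `b`.
#' @param ... Passed to [sasa()].
#' @return List with `interface_area`, `sasa_decamer`, `sasa_pentamer_a`,
#'   `sasa_pentamer_b` (all Angstrom^2).
#' @export
interface_area <- function(structure, map, ...) {
  protos <- unique(map$protofilament_of)
  if (length(protos) != 2) stop("interface area needs two protofilaments")
  sub_structure <- function(chains) {
    new_structure(structure$atoms[structure$atoms$chain %in% chains, ],
                  title = structure$title)
  }
  s_ab <- sasa(structure, ...)$total
  s_a <- sasa(sub_structure(protofilament_chains(map, "a")), ...)$total
  s_b <- sasa(sub_structure(protofilament_chains(map, "b")), ...)$total
  list(interface_area = s_a + s_b - s_ab,
       sasa_decamer = s_ab, sasa_pentamer_a = s_a, sasa_pentamer_b = s_b)
}
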