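#' @useDynLib taufield, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optim rnorm runif sd setNames var median pt aggregate dist
#' @importFrom utils read.csv write.csv modifyList
"_PACKAGE"

# Fibrillar core of tau (residues 304-380, 2N4R numbering). The 77-residue
# peptide forms a C-shaped layer; five layers stack into a protofilament and
# two protofilaments into the decameric filament core. Validated by tests
# against the segment invariants (306..311 VQIVYK, 340..350 KSEKLDFKDRV,
# 350..362 VQSKIGSLDNITH).
TAU_CORE_SEQUENCE <- paste0(
  "GS",                                # 304-305 (end of repeat R2)
  "VQIVYKPVDLSKVTSKCGSLGNIHHKPGGGQ",   # 306-336 (repeat R3)
  "VEVKSEKLDFKDRVQSKIGSLDNITHVPGGGN",  # 337-368 (repeat R4)
  "KKIETHKLTFRE"                       # 369-380 (start of R')
)

#' Tau fibrillar core peptide specification
#'
#' Returns the specification of the 77-residue tau core peptide (residues
#' G304-E380 in tau numbering) that forms each chain of the PHF/SF filament
#' core, together with the named segments used throughout the package:
#' the amyloidogenic hexapeptide `PHF6` (306-VQIVYK-311), the polymorphic
#' amyloid motif `PAM4` (350-VQSKIGSLDNITH-362) and the charged `turn`
#' segment (340-KSEKLDFKDRV-350) at the apex of the C-shape.
#'
#' @param sequence Optional replacement one-letter sequence (for non-tau use).
#' @param first_residue_number Tau-numbering of the first residue (default 304).
#' @param segments Named list of `c(first, last)` residue-number ranges.
#' @return An object of class `peptide_spec` with elements `sequence`,
#'   `first_residue_number`, `residue_numbers` and `segments`.
#' @examples
#' spec <- tau_core_spec()
#' nchar(spec$sequence)              # 77
#' segment_residues(spec, "PHF6")    # 306..311
#' @export
tau_core_spec <- function(sequence = NULL, first_residue_number = 304L,
                          segments = NULL) {
  if (is.null(sequence)) sequence <- TAU_CORE_SEQUENCE
  if (is.null(segments)) {
    segments <- list(PHF6 = c(306L, 311L), PAM4 = c(350L, 362L),
                     turn = c(340L, 350L))
  }
  n <- nchar(sequence)
  structure(list(
    sequence = sequence,
    first_residue_number = as.integer(first_residue_number),
    residue_numbers = seq.int(first_residue_number, length.out = n),
    segments = segments
  ), class = "peptide_spec")
}

#' Residue numbers of a named segment
#'
#' @param spec A `peptide_spec` from [tau_core_spec()].
#' @param name Registered segment name (e.g. `"PHF6"`, `"PAM4"`, `"turn"`).
#' @return Integer vector of residue numbers (inclusive range).
#' @export
segment_residues <- function(spec, name) {
  stopifnot(inherits(spec, "peptide_spec"))
  if (!name %in% names(spec$segments)) {
    stop("unknown segment '", name, "'; registered: ",
         paste(names(spec$segments), collapse = ", "))
  }
  rng <- spec$segments[[name]]
  seq.int(rng[1], rng[2])
}

#' Extract the one-letter subsequence for a residue-number range
#' @param spec A `peptide_spec`.
#' @param residues Integer vector of residue numbers (tau numbering).
#' @return Character scalar.
#' @export
subsequence <- function(spec, residues) {
  idx <- match(residues, spec$residue_numbers)
  if (anyNA(idx)) stop("residue numbers outside the peptide range")
  paste(strsplit(spec$sequence, "")[[1]][idx], collapse = "")
}

#' Assign formal side-chain charges to a sequence
#'
#' Lysine and arginine are assigned +1, aspartate and glutamate -1, all other
#' standard residues (including histidine, taken neutral at pH 7) 0.
#' Termini are not charged (the simulated peptides are capped).
#'
#' @param sequence One-letter amino-acid string (20 standard codes).
#' @return Integer vector of the same length with values in `{-1, 0, +1}`.
#' @examples
#' assign_charges("KSEKLDFKDRV")  # 4 x +1, 3 x -1
#' @export
assign_charges <- function(sequence) {
  aa <- strsplit(sequence, "")[[1]]
  valid <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  bad <- which(!aa %in% valid)
  if (length(bad) > 0) {
    stop("unknown residue code '", aa[bad[1]], "' at position ", bad[1])
  }
  ifelse(aa %in% c("K", "R"), 1L, ifelse(aa %in% c("D", "E"), -1L, 0L))
}

#' Chain-to-protofilament bookkeeping for the decameric assembly
#'
#' Maps the chains of a filament structure onto the two pentameric
#' protofilaments `a` and `b` with stack indices 1..5 along the fibril axis,
#' identifying the central chains (stack index 3) used as RMSF alignment
#' anchors.
#'
#' @param structure A `fibril_structure` (see [read_structure()]).
#' @param chain_order Optional character vector giving the chain ids in the
#'   order 1a..5a, 1b..5b. Default: chains in file order, stack index assigned
#'   by position along the mean fibril (z) axis within each protofilament.
#' @param single_protofilament If `TRUE`, accept a 5-chain structure as one
#'   protofilament `a`.
#' @return An `assembly_map` with fields `chain_ids`, `protofilament_of`,
#'   `stack_index_of`, `central_chains`, and `label_of` (chain -> "3a" style).
#' @export
build_assembly_map <- function(structure, chain_order = NULL,
                               single_protofilament = FALSE) {
  atoms <- structure$atoms
  chains <- unique(atoms$chain)
  n_per <- 5L
  if (single_protofilament) {
    if (length(chains) != 5L) stop("single-protofilament mode needs 5 chains, got ",
                                   length(chains))
    protos <- rep("a", 5L)
  } else {
    if (length(chains) != 10L) stop("expected 10 chains, got ", length(chains),
                                    " (use single_protofilament = TRUE for 5)")
    protos <- rep(c("a", "b"), each = 5L)
  }
  nres <- vapply(chains, function(ch) {
    length(unique(atoms$resid[atoms$chain == ch]))
  }, integer(1))
  if (length(unique(nres)) != 1L) stop("chains differ in residue count")
  if (is.null(chain_order)) {
    # order within each protofilament by mean z (fibril axis) of the chain
    grp <- split(chains, protos[match(chains, chains)])
    ord <- character(0)
    for (g in seq_along(unique(protos))) {
      p <- unique(protos)[g]
      idx <- which(protos == p)
      ch_p <- chains[idx]
      mz <- vapply(ch_p, function(ch) mean(atoms$z[atoms$chain == ch]), numeric(1))
      ord <- c(ord, ch_p[order(mz)])
    }
    chain_order <- ord
  } else {
    if (!setequal(chain_order, chains)) stop("chain_order must list every chain exactly once")
  }
  stack <- rep(seq_len(n_per), length.out = length(chain_order))
  proto <- rep(c("a", "b"), each = n_per)[seq_along(chain_order)]
  label <- paste0(stack, proto)
  central <- chain_order[stack == 3L]
  structure(list(
    chain_ids = chain_order,
    protofilament_of = setNames(proto, chain_order),
    stack_index_of = setNames(stack, chain_order),
    label_of = setNames(label, chain_order),
    central_chains = central
  ), class = "assembly_map")
}

#' @export
print.assembly_map <- function(x, ...) {
  cat("assembly_map:", length(x$chain_ids), "chains;",
      length(unique(x$protofilament_of)), "protofilament(s)\n")
  cat("  labels:", paste(sprintf("%s=%s", x$chain_ids, x$label_of), collapse = " "), "\n")
  cat("  central:", paste(x$central_chains, collapse = ", "), "\n")
  invisible(x)
}

#' Chains belonging to one protofilament
#' @param map An `assembly_map`.
#' @param protofilament `"a"` or `"b"`.
#' @return Character vector of chain ids.
#' @export
protofilament_chains <- function(map, protofilament) {
  map$chain_ids[map$protofilament_of[map$chain_ids] == protofilament]
}
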