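# Reference Calpha contact sets on a starting structure and their survival
# along a trajectory. Three classes, each with its own cutoff:
#   intrapeptide       same chain, |sequence separation| > 3, 1.25 nm
#   interpeptide       different chains,                       0.80 nm
#   interprotofilament different protofilaments,               1.00 nm
# Distances strictly below the cutoff count as "in contact", applied
# identically when building the reference set and when tracking it.

CONTACT_CUTOFFS <- c(intrapeptide = 1.25, interpeptide = 0.8,
                     interprotofilament = 1.0)

# residue-level Calpha table: chain, resid, x, y, z
ca_table <- function(structure) {
  a <- structure$atoms
  ca <- a[a$name == "CA", c("chain", "resid", "x", "y", "z")]
  all_res <- unique(a[, c("chain", "resid")])
  if (nrow(ca) < nrow(all_res)) {
    miss <- all_res[!paste(all_res$chain, all_res$resid) %in%
                      paste(ca$chain, ca$resid), ]
    stop("missing Calpha for residue(s): ",
         paste(paste0(miss$chain, ":", miss$resid)[seq_len(min(5, nrow(miss)))],
               collapse = ", "))
  }
  rownames(ca) <- NULL
  ca
}

#' Reference contact set of a starting structure
#'
#' Enumerates all residue pairs satisfying each contact-class definition on
#' the given structure. A pair on different protofilaments lying within both
#' the interpeptide (0.8 nm) and interprotofilament (1.0 nm) cutoffs appears
#' in both classes.
#'
#' @param structure A `fibril_structure` (typically the first trajectory
#'   frame).
#' @param map An `assembly_map` (needed for the interprotofilament class;
#'   may be `NULL` to skip it).
#' @return A `contact_set`: data.frame with columns `chain_a`, `resid_a`,
#'   `chain_b`, `resid_b`, `class`, `cutoff_nm`, plus attribute `ca_order`.
#' @export
reference_contacts <- function(structure, map = NULL) {
  ca <- ca_table(structure)
  n <- nrow(ca)
  xyz <- as.matrix(ca[, c("x", "y", "z")])
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * tcrossprod(xyz)
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  same_chain <- outer(ca$chain, ca$chain, "==")
  sep <- abs(outer(ca$resid, ca$resid, "-"))
  upper <- upper.tri(d)
  recs <- list()
  pairs_from <- function(mask, class) {
    idx <- which(mask & upper, arr.ind = TRUE)
    if (nrow(idx) == 0) {
      return(data.frame(chain_a = character(0), resid_a = integer(0),
                        chain_b = character(0), resid_b = integer(0),
                        class = character(0), cutoff_nm = numeric(0)))
    }
    data.frame(chain_a = ca$chain[idx[, 1]], resid_a = ca$resid[idx[, 1]],
               chain_b = ca$chain[idx[, 2]], resid_b = ca$resid[idx[, 2]],
               class = class, cutoff_nm = unname(CONTACT_CUTOFFS[class]),
               stringsAsFactors = FALSE)
  }
  recs$intra <- pairs_from(same_chain & sep > 3 & d < CONTACT_CUTOFFS["intrapeptide"],
                           "intrapeptide")
  recs$inter <- pairs_from(!same_chain & d < CONTACT_CUTOFFS["interpeptide"],
                           "interpeptide")
  if (!is.null(map)) {
    proto <- map$protofilament_of[ca$chain]
    diff_proto <- outer(proto, proto, "!=")
    recs$protof <- pairs_from(diff_proto & d < CONTACT_CUTOFFS["interprotofilament"],
                              "interprotofilament")
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  attr(out, "ca_order") <- paste(ca$chain, ca$resid)
  class(out) <- c("contact_set", class(out))
  out
}

# map contact records onto row indices of the Calpha table of a structure
contact_indices <- function(refset, ca) {
  key <- paste(ca$chain, ca$resid)
  ia <- match(paste(refset$chain_a, refset$resid_a), key)
  ib <- match(paste(refset$chain_b, refset$resid_b), key)
  if (anyNA(ia) || anyNA(ib)) stop("contact set references residues absent from structure")
  cbind(ia, ib)
}

#' Surviving fraction of reference contacts along a trajectory
#'
#' Per frame and contact class, the fraction of reference pairs whose
#' Calpha distance is still below that pair's class cutoff.
#'
#' @param traj A `fibril_trajectory`.
#' @param refset A `contact_set` from [reference_contacts()] (typically built
#'   on frame 1 of `traj`).
#' @param group_by `"class"` (default) for one series per class, or
#'   `"residue"` for a per-residue x class breakdown (averaging over the
#'   reference pairs involving each residue).
#' @param chains Optional chain filter: keep only reference pairs with at
#'   least one member in `chains`.
#' @param per_residue_stat For `group_by = "residue"`: `"mean"` (default)
#'   averages survival over the pairs involving a residue; `"any"` reports
#'   whether at least one of its reference contacts survives.
#' @return For `group_by = "class"`: data.frame `time_ns`, `class`,
#'   `fraction`. For `"residue"`: data.frame `time_ns`, `chain`, `resid`,
#'   `class`, `fraction`.
#' @export
contact_fraction <- function(traj, refset, group_by = c("class", "residue"),
                             chains = NULL,
                             per_residue_stat = c("mean", "any")) {
  group_by <- match.arg(group_by)
  per_residue_stat <- match.arg(per_residue_stat)
  res_fun <- if (per_residue_stat == "mean") mean else function(x) as.numeric(any(x))
  if (!is.null(chains)) {
    keep <- refset$chain_a %in% chains | refset$chain_b %in% chains
    att <- attr(refset, "ca_order")
    refset <- refset[keep, ]
    attr(refset, "ca_order") <- att
  }
  if (nrow(refset) == 0) stop("empty contact set")
  topo_ca <- ca_table(get_frame(traj, 1))
  idx <- contact_indices(refset, topo_ca)
  ca_rows <- ca_indices(traj$topology)
  n_frames <- dim(traj$coords)[1]
  classes <- unique(refset$class)
  res_list <- list()
  for (f in seq_len(n_frames)) {
    xyz <- traj$coords[f, ca_rows, , drop = FALSE][1, , ]
    dd <- sqrt(rowSums((xyz[idx[, 1], , drop = FALSE] -
                          xyz[idx[, 2], , drop = FALSE])^2))
    alive <- dd < refset$cutoff_nm
    if (group_by == "class") {
      fr <- vapply(classes, function(cl) mean(alive[refset$class == cl]), numeric(1))
      res_list[[f]] <- data.frame(time_ns = traj$times[f], class = classes,
                                  fraction = unname(fr), stringsAsFactors = FALSE)
    } else {
      both <- rbind(
        data.frame(chain = refset$chain_a, resid = refset$resid_a,
                   class = refset$class, alive = alive, stringsAsFactors = FALSE),
        data.frame(chain = refset$chain_b, resid = refset$resid_b,
                   class = refset$class, alive = alive, stringsAsFactors = FALSE))
      agg <- aggregate(alive ~ chain + resid + class, data = both, FUN = res_fun)
      names(agg)[names(agg) == "alive"] <- "fraction"
      agg$time_ns <- traj$times[f]
      res_list[[f]] <- agg[, c("time_ns", "chain", "resid", "class", "fraction")]
    }
  }
  out <- do.call(rbind, res_list)
  rownames(out) <- NULL
  out
}

#' Count reference contacts per class
#' @param refset A `contact_set`.
#' @return Named integer vector.
#' @export
contact_counts <- function(refset) {
  table(factor(refset$class, levels = names(CONTACT_CUTOFFS)))
}
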