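#' Donor/acceptor dictionary for geometric hydrogen-bond detection
#'
#' @param donors data.frame with columns `resid`, `heavy`, `hydrogen`: one
#'   row per donor heavy atom / bonded hydrogen pair, keyed by residue name.
#' @param acceptors data.frame with columns `resid`, `heavy`.
#' @return object of class `hbond_spec`.
#' @seealso [default_hbond_spec()]
#' @export
hbond_spec <- function(donors, acceptors) {
  if (!all(c("resid", "heavy", "hydrogen") %in% names(donors)))
    stop("'donors' needs columns resid, heavy, hydrogen")
  if (!all(c("resid", "heavy") %in% names(acceptors)))
    stop("'acceptors' needs columns resid, heavy")
  structure(list(donors = donors, acceptors = acceptors),
            class = "hbond_spec")
}

#' Default donor/acceptor dictionary
#'
#' Covers the 20 amino acids (backbone N-H donors except proline, backbone
#' carbonyl acceptors, the usual polar side chains) plus the NAP/NAD ligand
#' components (adenine N6 and carboxamide N7 donors; ring nitrogens, ribose,
#' carboxamide and phosphate oxygens as acceptors). Shipped as an editable
#' TSV (`inst/extdata/hbond_chemistry.tsv`); the inventory is a documented
#' package choice, intended for MD-style frames with explicit hydrogens.
#'
#' @param path alternative TSV file in the same format.
#' @return an [hbond_spec()].
#' @export
default_hbond_spec <- function(path = system.file("extdata",
                                                  "hbond_chemistry.tsv",
                                                  package = "cofspec")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  donors <- tab[tab$role == "donor", c("resid", "heavy", "hydrogen")]
  acceptors <- tab[tab$role == "acceptor", c("resid", "heavy")]
  hbond_spec(donors, acceptors)
}

#' Donor-hydrogen-acceptor angle
#'
#' Angle at the hydrogen between the H->donor and H->acceptor vectors, in
#' degrees within \[0, 180\]. Invariant under rigid motions.
#'
#' @param d,h,a numeric length-3 coordinates of donor, hydrogen, acceptor.
#' @return angle in degrees.
#' @export
dha_angle <- function(d, h, a) {
  d <- as.numeric(d); h <- as.numeric(h); a <- as.numeric(a)
  v1 <- d - h
  v2 <- a - h
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 < .Machine$double.eps || n2 < .Machine$double.eps)
    stop("coincident points: angle undefined")
  cosang <- sum(v1 * v2) / (n1 * n2)
  acos(min(1, max(-1, cosang))) * 180 / pi
}

#' Detect geometric hydrogen bonds in one frame
#'
#' A hydrogen bond is every (donor heavy atom, bonded hydrogen, acceptor
#' heavy atom) triple with donor-acceptor distance strictly below `d_max`
#' (default 3.5 angstrom) and donor-hydrogen-acceptor angle strictly above
#' `angle_min` (default 120 degrees). Intra-residue pairs are excluded.
#' Hydrogens must be explicit: a donor heavy atom present in the frame whose
#' listed hydrogen is missing raises an error naming the atom.
#'
#' @param frame a [cof_structure()].
#' @param spec an [hbond_spec()]; defaults to the shipped dictionary.
#' @param d_max donor-acceptor distance cutoff in angstrom (strict <).
#' @param angle_min D-H-A angle cutoff in degrees (strict >).
#' @return data.frame of events: donor/hydrogen/acceptor identities,
#'   `distance`, `angle`, `donor_moiety`, `acceptor_moiety` (each of
#'   `backbone`, `sidechain`, `ligand`).
#' @export
detect_hbonds <- function(frame, spec = default_hbond_spec(), d_max = 3.5,
                          angle_min = 120) {
  stopifnot(inherits(frame, "cof_structure"), inherits(spec, "hbond_spec"))
  a <- frame$atoms
  a$.row <- seq_len(nrow(a))
  a$.reskey <- paste(a$chain, a$resno, sep = ":")

  dn <- merge(a, spec$donors, by.x = c("resid", "elety"),
              by.y = c("resid", "heavy"))
  if (nrow(dn)) {
    hkey <- paste(dn$.reskey, dn$hydrogen)
    akey <- paste(a$.reskey, a$elety)
    hrow <- match(hkey, akey)
    if (anyNA(hrow)) {
      miss <- dn[is.na(hrow), ][1L, ]
      stop("donor ", miss$resid, " ", miss$elety, " (", miss$.reskey,
           ") lacks its hydrogen ", miss$hydrogen,
           "; frames must carry explicit hydrogens")
    }
    dn$hx <- a$x[hrow]; dn$hy <- a$y[hrow]; dn$hz <- a$z[hrow]
    dn$hydrogen_name <- dn$hydrogen
  }
  ac <- merge(a, spec$acceptors, by.x = c("resid", "elety"),
              by.y = c("resid", "heavy"))

  empty <- data.frame(
    donor_chain = character(), donor_resno = integer(),
    donor_resid = character(), donor_atom = character(),
    hydrogen = character(), acceptor_chain = character(),
    acceptor_resno = integer(), acceptor_resid = character(),
    acceptor_atom = character(), distance = numeric(), angle = numeric(),
    donor_moiety = character(), acceptor_moiety = character())
  if (!nrow(dn) || !nrow(ac)) return(empty)

  dmat <- pairwise_distances(atom_xyz(dn), atom_xyz(ac))
  hits <- which(dmat < d_max, arr.ind = TRUE)
  if (!nrow(hits)) return(empty)
  keep <- dn$.reskey[hits[, 1L]] != ac$.reskey[hits[, 2L]]
  hits <- hits[keep, , drop = FALSE]
  if (!nrow(hits)) return(empty)

  ang <- vapply(seq_len(nrow(hits)), function(k) {
    i <- hits[k, 1L]; j <- hits[k, 2L]
    dha_angle(c(dn$x[i], dn$y[i], dn$z[i]),
              c(dn$hx[i], dn$hy[i], dn$hz[i]),
              c(ac$x[j], ac$y[j], ac$z[j]))
  }, 0)
  keep <- ang > angle_min
  hits <- hits[keep, , drop = FALSE]
  ang <- ang[keep]
  if (!nrow(hits)) return(empty)

  i <- hits[, 1L]; j <- hits[, 2L]
  out <- data.frame(
    donor_chain = dn$chain[i], donor_resno = dn$resno[i],
    donor_resid = dn$resid[i], donor_atom = dn$elety[i],
    hydrogen = dn$hydrogen_name[i],
    acceptor_chain = ac$chain[j], acceptor_resno = ac$resno[j],
    acceptor_resid = ac$resid[j], acceptor_atom = ac$elety[j],
    distance = dmat[cbind(i, j)], angle = ang,
    donor_moiety = atom_moiety(dn$type[i], dn$elety[i]),
    acceptor_moiety = atom_moiety(ac$type[j], ac$elety[j]))
  out[order(out$donor_chain, out$donor_resno, out$acceptor_resno,
            out$donor_atom, out$acceptor_atom), , drop = FALSE]
}

# backbone/sidechain/ligand classification of a protein or HETATM atom
atom_moiety <- function(type, elety) {
  ifelse(type == "HETATM", "ligand",
         ifelse(elety %in% c("N", "H", "O", "C", "CA"),
                "backbone", "sidechain"))
}

#' Hydrogen-bond occupancy over a trajectory
#'
#' Applies [detect_hbonds()] to every frame independently (no smoothing) and
#' tabulates, for each (protein residue, moiety, ligand group), the fraction
#' of frames with at least one qualifying protein-ligand bond, plus the
#' per-frame bond count series. Interactions through the backbone (atom
#' names N, H, O, C, CA) and the side chain are counted separately. Ligand
#' atoms can be grouped into named halves (e.g. 2'-phosphate, adenine-ribose,
#' nicotinamide) via `group_map`.
#'
#' @param traj a [cof_trajectory()].
#' @param spec an [hbond_spec()].
#' @param group_map named list mapping group names to ligand atom-name
#'   vectors; atoms not covered fall into group `"other"`. `NULL` puts all
#'   ligand atoms in group `"ligand"`.
#' @param d_max,angle_min geometric criterion, as in [detect_hbonds()].
#' @return object of class `occupancy_table`: data.frame with `chain`,
#'   `resno`, `resid`, `moiety`, `group`, `occupancy`, `n_frames`; the
#'   per-frame count matrix (series x frame) is in attribute `"counts"` and
#'   the raw event table in attribute `"events"`.
#' @export
occupancy <- function(traj, spec = default_hbond_spec(), group_map = NULL,
                      d_max = 3.5, angle_min = 120) {
  stopifnot(inherits(traj, "cof_trajectory"))
  n <- length(traj$frames)
  if (!n) stop("empty trajectory")
  ev_list <- lapply(seq_len(n), function(i) {
    ev <- detect_hbonds(traj$frames[[i]], spec, d_max = d_max,
                        angle_min = angle_min)
    if (nrow(ev)) ev$frame <- i
    ev
  })
  ev <- do.call(rbind, ev_list[vapply(ev_list, nrow, 0L) > 0])

  assign_group <- function(atom) {
    if (is.null(group_map)) return(rep("ligand", length(atom)))
    out <- rep("other", length(atom))
    for (g in names(group_map)) out[atom %in% group_map[[g]]] <- g
    out
  }

  pl <- NULL
  if (!is.null(ev) && nrow(ev)) {
    lig_on_donor <- ev$donor_moiety == "ligand"
    lig_on_acceptor <- ev$acceptor_moiety == "ligand"
    pl <- ev[xor(lig_on_donor, lig_on_acceptor), , drop = FALSE]
    if (nrow(pl)) {
      # ligand-protein bonds: track the protein residue, group by ligand atom
      lig_side_donor <- pl$donor_moiety == "ligand"
      pl$res_chain <- ifelse(lig_side_donor, pl$acceptor_chain, pl$donor_chain)
      pl$res_resno <- ifelse(lig_side_donor, pl$acceptor_resno, pl$donor_resno)
      pl$res_resid <- ifelse(lig_side_donor, pl$acceptor_resid, pl$donor_resid)
      pl$res_moiety <- ifelse(lig_side_donor, pl$acceptor_moiety,
                              pl$donor_moiety)
      pl$group <- assign_group(ifelse(lig_side_donor, pl$donor_atom,
                                      pl$acceptor_atom))
    } else {
      # no ligand in the system: tabulate by donor residue, partner "protein"
      pl <- ev
      pl$res_chain <- pl$donor_chain
      pl$res_resno <- pl$donor_resno
      pl$res_resid <- pl$donor_resid
      pl$res_moiety <- pl$donor_moiety
      pl$group <- "protein"
    }
  }
  if (is.null(pl) || !nrow(pl)) {
    tab <- data.frame(chain = character(), resno = integer(),
                      resid = character(), moiety = character(),
                      group = character(), occupancy = numeric(),
                      n_frames = integer())
    counts <- matrix(0L, 0L, n)
  } else {
    key <- paste(pl$res_chain, pl$res_resno, pl$res_resid, pl$res_moiety,
                 pl$group, sep = "|")
    ukey <- sort(unique(key))
    counts <- matrix(0L, length(ukey), n,
                     dimnames = list(ukey, seq_len(n)))
    tb <- table(factor(key, levels = ukey), factor(pl$frame, levels = 1:n))
    counts[] <- as.integer(tb)
    parts <- do.call(rbind, strsplit(ukey, "|", fixed = TRUE))
    tab <- data.frame(chain = parts[, 1L],
                      resno = as.integer(parts[, 2L]),
                      resid = parts[, 3L], moiety = parts[, 4L],
                      group = parts[, 5L],
                      occupancy = rowMeans(counts > 0),
                      n_frames = n)
  }
  structure(tab, counts = counts,
            events = if (is.null(ev)) NULL else ev,
            class = c("occupancy_table", "data.frame"))
}
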