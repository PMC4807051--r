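#' Molecular structure container
#'
#' A light container around an atom table in PDB column convention:
#' `type` (ATOM/HETATM), `eleno`, `elety` (atom name), `resid` (residue
#' name), `chain`, `resno`, `x`, `y`, `z` (angstrom), `o` (occupancy),
#' `b` (B-factor), `elesy` (element symbol).
#'
#' @param atoms data.frame with at least `type`, `elety`, `resid`, `chain`,
#'   `resno`, `x`, `y`, `z`; missing optional columns are filled.
#' @return object of class `cof_structure`.
#' @export
cof_structure <- function(atoms) {
  need <- c("type", "elety", "resid", "chain", "resno", "x", "y", "z")
  if (!is.data.frame(atoms) || !all(need %in% names(atoms)))
    stop("'atoms' needs columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates")
  if (is.null(atoms$eleno)) atoms$eleno <- seq_len(nrow(atoms))
  if (is.null(atoms$o)) atoms$o <- 1
  if (is.null(atoms$b)) atoms$b <- 0
  if (is.null(atoms$elesy)) atoms$elesy <- guess_element(atoms$elety)
  key <- paste(atoms$chain, atoms$resno, atoms$resid, atoms$elety)
  if (anyDuplicated(key))
    stop("duplicated atom name within a residue: ",
         key[duplicated(key)][1L])
  rownames(atoms) <- NULL
  structure(list(atoms = atoms), class = "cof_structure")
}

#' @export
print.cof_structure <- function(x, ...) {
  a <- x$atoms
  cat("Structure:", nrow(a), "atoms,",
      length(unique(paste(a$chain, a$resno, a$resid))), "residues,",
      "chains:", paste(unique(a$chain), collapse = " "), "\n")
  invisible(x)
}

# element symbol from a PDB atom name (first alphabetic character, with the
# usual caveat that names starting with a digit, e.g. 1HB, are hydrogens)
guess_element <- function(elety) {
  e <- sub("^[0-9']*", "", elety)
  one <- toupper(substr(e, 1L, 1L))
  two <- toupper(substr(e, 1L, 2L))
  ifelse(two %in% c("FE", "ZN", "MG", "MN", "CL", "BR", "NA", "SE"), two, one)
}

atom_xyz <- function(atoms) {
  as.matrix(atoms[, c("x", "y", "z"), drop = FALSE])
}

# all-pairs Euclidean distances between two coordinate matrices (n x 3, m x 3)
pairwise_distances <- function(a, b) {
  a <- matrix(as.numeric(a), ncol = 3)
  b <- matrix(as.numeric(b), ncol = 3)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

#' Read a structure from a PDB file
#'
#' Loads all ATOM/HETATM records of one MODEL (the first, by default) and
#' collapses alternate-location indicators to the highest-occupancy copy.
#' Parsing is delegated to [bio3d::read.pdb()].
#'
#' @param path PDB file.
#' @param model 1-based MODEL index to load.
#' @return a [cof_structure()].
#' @export
read_structure <- function(path, model = 1L) {
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e)
                    stop("cannot parse PDB file '", path, "': ",
                         conditionMessage(e)))
  atoms <- pdb$atom
  nmod <- nrow(pdb$xyz)
  if (model > nmod)
    stop("requested MODEL ", model, " but file has ", nmod)
  xyz <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  atoms$chain[is.na(atoms$chain)] <- " "
  # collapse altloc: keep highest occupancy per (chain, resno, resid, elety)
  if (any(!is.na(atoms$alt))) {
    key <- paste(atoms$chain, atoms$resno, atoms$resid, atoms$elety)
    ord <- order(key, -replace(atoms$o, is.na(atoms$o), 1))
    atoms <- atoms[ord, ][!duplicated(sort(key)), ]
    atoms <- atoms[order(atoms$eleno), ]
  }
  cof_structure(atoms[, c("type", "eleno", "elety", "resid", "chain",
                          "resno", "x", "y", "z", "o", "b", "elesy")])
}

#' Write a structure (or trajectory frames) to a PDB file
#'
#' Delegates to [bio3d::write.pdb()]; B-factors land in columns 61-66 with
#' two decimals. When `frames` is a list of structures sharing one atom
#' roster, one MODEL per frame is written.
#'
#' @param s a [cof_structure()], or a list of them via `frames`.
#' @param path output file.
#' @param frames optional list of `cof_structure` frames (overrides `s`).
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path, frames = NULL) {
  if (is.null(frames)) frames <- list(s)
  a <- frames[[1L]]$atoms
  xyz <- do.call(rbind, lapply(frames, function(f)
    as.numeric(t(atom_xyz(f$atoms)))))
  bio3d::write.pdb(file = path, xyz = xyz, type = a$type, resno = a$resno,
                   resid = a$resid, eleno = a$eleno, elety = a$elety,
                   chain = ifelse(a$chain == " ", "", a$chain),
                   o = a$o, b = a$b, elesy = a$elesy)
  invisible(path)
}

#' Read a multi-MODEL PDB file as a trajectory
#'
#' Each MODEL becomes one frame; all frames share the atom roster of the
#' first model (the multi-model PDB convention for MD snapshots).
#'
#' @param path multi-MODEL PDB file.
#' @param frame_interval time between frames in ps (metadata only).
#' @return object of class `cof_trajectory`: list with `frames` (list of
#'   [cof_structure()]) and `frame_interval`.
#' @export
read_trajectory <- function(path, frame_interval = 50) {
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e)
                    stop("cannot parse PDB file '", path, "': ",
                         conditionMessage(e)))
  base <- pdb$atom
  base$chain[is.na(base$chain)] <- " "
  frames <- lapply(seq_len(nrow(pdb$xyz)), function(i) {
    xyz <- matrix(pdb$xyz[i, ], ncol = 3, byrow = TRUE)
    a <- base
    a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
    cof_structure(a[, c("type", "eleno", "elety", "resid", "chain",
                        "resno", "x", "y", "z", "o", "b", "elesy")])
  })
  cof_trajectory(frames, frame_interval)
}

#' Trajectory container
#'
#' @param frames list of [cof_structure()] snapshots sharing one atom roster.
#' @param frame_interval sampling interval in ps.
#' @return object of class `cof_trajectory`.
#' @export
cof_trajectory <- function(frames, frame_interval = 50) {
  if (!length(frames)) stop("a trajectory needs at least one frame")
  roster <- lapply(frames, function(f)
    paste(f$atoms$chain, f$atoms$resno, f$atoms$resid, f$atoms$elety))
  if (!all(vapply(roster, identical, TRUE, roster[[1L]])))
    stop("all frames must share the same atom roster")
  structure(list(frames = frames, frame_interval = frame_interval),
            class = "cof_trajectory")
}

#' One-letter sequences of the protein chains
#'
#' @param s a [cof_structure()].
#' @return named character vector, one sequence per chain (from CA atoms).
#' @export
chain_sequences <- function(s) {
  a <- s$atoms
  ca <- a[a$type == "ATOM" & a$elety == "CA", ]
  if (!nrow(ca)) return(character())
  vapply(split(ca, ca$chain), function(d) {
    d <- d[order(d$resno), ]
    paste(bio3d::aa321(d$resid), collapse = "")
  }, "")
}

#' Find NADP+ ligand copies in a structure
#'
#' Every HETATM residue whose residue name is in `codes` (default the NAP
#' chemical-component identifier for NADP+; the reduced form NDP is excluded
#' by default).
#'
#' @param s a [cof_structure()].
#' @param codes residue names to accept.
#' @return list of atom data.frames, one per ligand copy (possibly empty).
#' @export
find_nadp_ligands <- function(s, codes = "NAP") {
  a <- s$atoms
  lig <- a[a$type == "HETATM" & a$resid %in% codes, ]
  if (!nrow(lig)) return(list())
  unname(split(lig, paste(lig$chain, lig$resno)))
}

#' Completeness and extension report for one NADP+ ligand
#'
#' Applies the two per-ligand screens of the structural survey: the cofactor
#' must be complete (all 48 heavy atoms of the NAP component present) and in
#' an extended conformation (strictly more than `min_extension` angstrom,
#' default 12, between nicotinamide C2 and adenine C6 -- the Rossmann-bound
#' pose, as opposed to a folded dinucleotide).
#'
#' @param lig atom data.frame of one ligand (an element of
#'   [find_nadp_ligands()] output).
#' @param min_extension extension cutoff in angstrom (strict >).
#' @return object of class `ligand_report`: `heavy_atom_count`, `complete`,
#'   `extension_distance`, `extended` (NA when C2N/C6A is missing, reported
#'   as a filter failure via `passes`), `passes`.
#' @export
check_ligand <- function(lig, min_extension = 12) {
  heavy <- lig[lig$elesy != "H", ]
  n_heavy <- nrow(heavy)
  complete <- n_heavy == 48L
  c2n <- heavy[heavy$elety == "C2N", ]
  c6a <- heavy[heavy$elety == "C6A", ]
  if (nrow(c2n) == 1L && nrow(c6a) == 1L) {
    ext <- sqrt(sum((as.numeric(c2n[, c("x", "y", "z")]) -
                     as.numeric(c6a[, c("x", "y", "z")]))^2))
    extended <- ext > min_extension
  } else {
    ext <- NA_real_
    extended <- NA
  }
  structure(list(chain = lig$chain[1L], resno = lig$resno[1L],
                 heavy_atom_count = n_heavy, complete = complete,
                 extension_distance = ext, extended = extended,
                 passes = complete && isTRUE(extended)),
            class = "ligand_report")
}

#' @export
print.ligand_report <- function(x, ...) {
  cat(sprintf(
    "Ligand %s/%s: %d heavy atoms (complete: %s); C2N-C6A %s A (extended: %s)\n",
    x$chain, x$resno, x$heavy_atom_count, x$complete,
    if (is.na(x$extension_distance)) "?" else
      format(x$extension_distance, digits = 4), x$extended))
  invisible(x)
}

# side-chain nitrogen atoms considered for electrostatic 2'-phosphate
# contacts; charged nitrogens only (not CZ/CD carbons)
positive_nitrogens <- list(
  ARG = c("NE", "NH1", "NH2"),
  LYS = "NZ",
  HIS = c("ND1", "NE2"))

#' Enumerate positive residues contacting the 2'-phosphate
#'
#' One contact per protein residue of an allowed type (default Arg and Lys;
#' His optional, off by default because its protonation state is ambiguous)
#' having any charged side-chain nitrogen strictly closer than `cutoff`
#' (default 4 angstrom) to any 2'-phosphate atom of the ligand (NAP
#' component names P2B, O1X, O2X, O3X -- phosphorus and the three free
#' oxygens; configurable).
#'
#' @param s a [cof_structure()].
#' @param lig atom data.frame of one NADP+ ligand.
#' @param cutoff contact cutoff in angstrom (strict <).
#' @param residue_types allowed residue types.
#' @param phosphate_atoms ligand atom names making up the 2'-phosphate.
#' @return data.frame with one row per contacting residue: `resid`, `chain`,
#'   `resno`, `min_distance`, `residue_atom`, `phosphate_atom`.
#' @export
phosphate_contacts <- function(s, lig, cutoff = 4.0,
                               residue_types = c("ARG", "LYS"),
                               phosphate_atoms = c("P2B", "O1X", "O2X", "O3X")) {
  ph <- lig[lig$elety %in% phosphate_atoms, ]
  if (!nrow(ph))
    stop("ligand has no 2'-phosphate atoms (looked for: ",
         paste(phosphate_atoms, collapse = ", "), ")")
  bad <- setdiff(residue_types, names(positive_nitrogens))
  if (length(bad))
    stop("unsupported residue type(s): ", paste(bad, collapse = ", "))
  a <- s$atoms
  cand <- a[a$type == "ATOM" & a$resid %in% residue_types, ]
  cand <- cand[mapply(function(rt, at) at %in% positive_nitrogens[[rt]],
                      cand$resid, cand$elety), , drop = FALSE]
  if (!nrow(cand))
    return(data.frame(resid = character(), chain = character(),
                      resno = integer(), min_distance = numeric(),
                      residue_atom = character(),
                      phosphate_atom = character()))
  d <- pairwise_distances(atom_xyz(cand), atom_xyz(ph))
  rows <- lapply(split(seq_len(nrow(cand)),
                       paste(cand$chain, cand$resno, cand$resid)),
                 function(idx) {
    sub <- d[idx, , drop = FALSE]
    k <- arrayInd(which.min(sub), dim(sub))
    dmin <- sub[k]
    if (dmin >= cutoff) return(NULL)
    i <- idx[k[1L]]
    data.frame(resid = cand$resid[i], chain = cand$chain[i],
               resno = cand$resno[i], min_distance = dmin,
               residue_atom = cand$elety[i],
               phosphate_atom = ph$elety[k[2L]])
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(resid = character(), chain = character(),
                      resno = integer(), min_distance = numeric(),
                      residue_atom = character(), phosphate_atom = character())
  out[order(out$chain, out$resno), , drop = FALSE]
}

#' Survey one NADP+ complex
#'
#' Applies the full per-structure screen: find NAP ligands, keep the first
#' copy passing the completeness and extension filters, and enumerate its
#' 2'-phosphate contacts.
#'
#' @param s a [cof_structure()].
#' @param id structure identifier for the survey row.
#' @inheritParams phosphate_contacts
#' @inheritParams check_ligand
#' @param codes ligand residue names (see [find_nadp_ligands()]).
#' @return one-row data.frame (a survey row): `id`, `n_ligands`,
#'   `pass_filters`, `n_positive`, `has_arg_lys_pair`, plus the contact table
#'   in attribute `"contacts"`.
#' @export
survey_structure <- function(s, id = "structure", cutoff = 4.0,
                             min_extension = 12, codes = "NAP",
                             residue_types = c("ARG", "LYS")) {
  ligs <- find_nadp_ligands(s, codes = codes)
  reports <- lapply(ligs, check_ligand, min_extension = min_extension)
  pass <- vapply(reports, `[[`, TRUE, "passes")
  row <- data.frame(id = id, n_ligands = length(ligs),
                    pass_filters = any(pass), n_positive = 0L,
                    has_arg_lys_pair = FALSE)
  if (any(pass)) {
    lig <- ligs[[which(pass)[1L]]]
    ct <- phosphate_contacts(s, lig, cutoff = cutoff,
                             residue_types = residue_types)
    row$n_positive <- nrow(ct)
    row$has_arg_lys_pair <- all(c("ARG", "LYS") %in% ct$resid)
    attr(row, "contacts") <- ct
  }
  row
}

#' Summarise a structural survey
#'
#' Counts, over many survey rows (see [survey_structure()]), how many
#' structures pass the ligand filters, how many of those have at least two
#' positive residues contacting the 2'-phosphate, and how many of the latter
#' involve an Arg + Lys pair; fractions are reported relative to the filter
#' survivors and to the two-positive subset respectively (NA when the
#' denominator is zero).
#'
#' @param rows data.frame of survey rows (rbind of [survey_structure()]
#'   outputs).
#' @return object of class `survey_summary`.
#' @export
summarize_survey <- function(rows) {
  if (is.null(rows) || !nrow(rows)) {
    rows <- data.frame(pass_filters = logical(), n_positive = integer(),
                       has_arg_lys_pair = logical())
  }
  passed <- rows[rows$pass_filters, , drop = FALSE]
  two <- passed[passed$n_positive >= 2L, , drop = FALSE]
  pair <- two[two$has_arg_lys_pair, , drop = FALSE]
  structure(list(
    n_structures = nrow(rows),
    n_pass_filters = nrow(passed),
    n_with_two_positive = nrow(two),
    n_arg_lys_pair = nrow(pair),
    fraction_two_positive =
      if (nrow(passed)) nrow(two) / nrow(passed) else NA_real_,
    fraction_arg_lys_among_two =
      if (nrow(two)) nrow(pair) / nrow(two) else NA_real_),
    class = "survey_summary")
}

#' @export
print.survey_summary <- function(x, ...) {
  cat(sprintf(
    "Survey: %d structures, %d pass filters; %d with >=2 positive contacts (%s), %d Arg+Lys pairs (%s of those)\n",
    x$n_structures, x$n_pass_filters, x$n_with_two_positive,
    if (is.na(x$fraction_two_positive)) "-" else
      sprintf("%.0f%%", 100 * x$fraction_two_positive),
    x$n_arg_lys_pair,
    if (is.na(x$fraction_arg_lys_among_two)) "-" else
      sprintf("%.0f%%", 100 * x$fraction_arg_lys_among_two)))
  invisible(x)
}

#' Greedy redundancy reduction by global sequence identity
#'
#' Greedy selection in input order: a sequence joins the representative set
#' iff its global-alignment identity (matches / alignment length, gaps
#' included in the length) to every representative chosen so far is strictly
#' below `threshold`. Alignment uses [Biostrings::pairwiseAlignment()] with
#' BLOSUM62 and gap penalties 10 (open) / 0.5 (extend). Deterministic for a
#' given input order; empty sequences are skipped with a warning.
#'
#' @param sequences character vector of one-letter protein sequences
#'   (optionally named).
#' @param threshold identity threshold in \[0, 1\] (default 0.70).
#' @return indices of the representatives into `sequences`.
#' @export
cluster_by_identity <- function(sequences, threshold = 0.70) {
  if (!length(sequences)) stop("need at least one sequence")
  reps <- integer()
  for (i in seq_along(sequences)) {
    s <- sequences[[i]]
    if (is.na(s) || !nzchar(s)) {
      warning("sequence ", i, " is empty; skipped")
      next
    }
    redundant <- FALSE
    for (j in reps) {
      if (sequence_identity(s, sequences[[j]]) >= threshold) {
        redundant <- TRUE
        break
      }
    }
    if (!redundant) reps <- c(reps, i)
  }
  reps
}

#' Global-alignment identity between two protein sequences
#'
#' @param a,b protein sequences (one-letter strings).
#' @return identity = matches / alignment length (gaps counted in length).
#' @export
sequence_identity <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5)
  Biostrings::nmatch(aln) /
    nchar(as.character(Biostrings::alignedPattern(aln)))
}

backbone_atom_names <- c("N", "CA", "C", "O")

#' Write per-residue values into the B-factor column
#'
#' Maps values keyed by (chain, residue number, moiety) onto the atoms of a
#' structure, e.g. to paint per-residue binding free energies onto a model
#' for visualisation. Moiety `"backbone"` covers atom names N, CA, C, O;
#' `"sidechain"` everything else; `"all"` the whole residue. Atoms with no
#' mapped value get 0.
#'
#' @param s a [cof_structure()].
#' @param values data.frame with columns `chain`, `resno`, `moiety`
#'   (`"backbone"`, `"sidechain"` or `"all"`), `value`.
#' @return a new [cof_structure()] with the `b` column replaced.
#' @export
annotate_bfactor <- function(s, values) {
  need <- c("chain", "resno", "moiety", "value")
  if (!is.data.frame(values) || !all(need %in% names(values)))
    stop("'values' needs columns: ", paste(need, collapse = ", "))
  a <- s$atoms
  a$b <- 0
  moiety <- ifelse(a$elety %in% backbone_atom_names, "backbone", "sidechain")
  for (i in seq_len(nrow(values))) {
    v <- values[i, ]
    hit <- a$chain == v$chain & a$resno == v$resno &
      (v$moiety == "all" | moiety == v$moiety)
    a$b[hit] <- v$value
  }
  cof_structure(a)
}
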