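# Independent oracles and fixture builders shared across the test files.
# These deliberately use plain loops / direct arithmetic, not the package's
# vectorised implementation paths.

# exhaustive triple enumeration for hydrogen bonds: for every donor heavy
# atom listed in `spec` with its hydrogen present in the same residue, and
# every acceptor in a different residue, test the two geometric criteria
brute_force_hbonds <- function(frame, spec, d_max = 3.5, angle_min = 120) {
  a <- frame$atoms
  reskey <- paste(a$chain, a$resno, sep = ":")
  found <- list()
  for (di in seq_len(nrow(a))) {
    drows <- spec$donors[spec$donors$resid == a$resid[di] &
                         spec$donors$heavy == a$elety[di], , drop = FALSE]
    if (!nrow(drows)) next
    for (k in seq_len(nrow(drows))) {
      hi <- which(reskey == reskey[di] & a$elety == drows$hydrogen[k])
      if (!length(hi)) next
      for (ai in seq_len(nrow(a))) {
        if (reskey[ai] == reskey[di]) next
        arows <- spec$acceptors[spec$acceptors$resid == a$resid[ai] &
                                spec$acceptors$heavy == a$elety[ai], ,
                                drop = FALSE]
        if (!nrow(arows)) next
        d <- sqrt((a$x[di] - a$x[ai])^2 + (a$y[di] - a$y[ai])^2 +
                  (a$z[di] - a$z[ai])^2)
        if (d >= d_max) next
        v1 <- c(a$x[di] - a$x[hi], a$y[di] - a$y[hi], a$z[di] - a$z[hi])
        v2 <- c(a$x[ai] - a$x[hi], a$y[ai] - a$y[hi], a$z[ai] - a$z[hi])
        ang <- acos(min(1, max(-1, sum(v1 * v2) /
                                 sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
        if (ang <= angle_min) next
        found[[length(found) + 1L]] <- data.frame(
          donor_key = reskey[di], donor_atom = a$elety[di],
          acceptor_key = reskey[ai], acceptor_atom = a$elety[ai],
          distance = d, angle = ang)
      }
    }
  }
  if (!length(found))
    return(data.frame(donor_key = character(), donor_atom = character(),
                      acceptor_key = character(),
                      acceptor_atom = character(),
                      distance = numeric(), angle = numeric()))
  out <- do.call(rbind, found)
  out[order(out$donor_key, out$acceptor_key, out$donor_atom,
            out$acceptor_atom), , drop = FALSE]
}

# random frame of SER (OG/HG/CB) and GLY (O/CA) residues in a cubic box;
# every SER hydroxyl is a donor, every carbonyl/hydroxyl oxygen an acceptor
random_hbond_frame <- function(n_ser = 30, n_gly = 48, box = 18) {
  rows <- list()
  eleno <- 0L
  resno <- 0L
  add <- function(resid, names, elesy, xyz) {
    resno <<- resno + 1L
    df <- data.frame(type = "ATOM", eleno = eleno + seq_along(names),
                     elety = names, resid = resid, chain = "A",
                     resno = resno, x = xyz[, 1L], y = xyz[, 2L],
                     z = xyz[, 3L], o = 1, b = 0, elesy = elesy)
    eleno <<- eleno + length(names)
    rows[[length(rows) + 1L]] <<- df
  }
  for (i in seq_len(n_ser)) {
    og <- runif(3, 0, box)
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    hg <- og + 0.96 * u
    cb <- og - 1.4 * u
    add("SER", c("OG", "HG", "CB"), c("O", "H", "C"), rbind(og, hg, cb))
  }
  for (i in seq_len(n_gly)) {
    o <- runif(3, 0, box)
    ca <- o + c(1.4, 0, 0)
    add("GLY", c("O", "CA"), c("O", "C"), rbind(o, ca))
  }
  cof_structure(do.call(rbind, rows))
}

# one serine hydroxyl donor and one glycine carbonyl acceptor at a chosen
# donor-acceptor distance and D-H-A angle, donor at the origin
fixed_pair_frame <- function(distance, angle) {
  dh <- 0.96
  phi <- (180 - angle) * pi / 180
  r <- -dh * cos(phi) + sqrt(dh^2 * cos(phi)^2 - dh^2 + distance^2)
  A <- c(dh, 0, 0) + r * c(cos(phi), sin(phi), 0)
  atoms <- data.frame(
    type = "ATOM", eleno = 1:4,
    elety = c("OG", "HG", "CB", "O"),
    resid = c("SER", "SER", "SER", "GLY"),
    chain = "A", resno = c(1L, 1L, 1L, 2L),
    x = c(0, dh, -1.4, A[1]), y = c(0, 0, 0, A[2]), z = c(0, 0, 0, A[3]),
    o = 1, b = 0, elesy = c("O", "H", "C", "O"))
  cof_structure(atoms)
}

# reduced donor/acceptor dictionary matching random_hbond_frame
ser_gly_spec <- function() {
  hbond_spec(
    donors = data.frame(resid = "SER", heavy = "OG", hydrogen = "HG"),
    acceptors = data.frame(resid = c("GLY", "SER"), heavy = c("O", "OG")))
}

# exhaustive SSE grid search oracle for the Michaelis-Menten fit
grid_search_mm <- function(s, v, km_true, vmax_true, n = 200) {
  kms <- exp(seq(log(0.1 * km_true), log(10 * km_true), length.out = n))
  vms <- exp(seq(log(0.1 * vmax_true), log(10 * vmax_true), length.out = n))
  best <- list(sse = Inf)
  for (km in kms) {
    pred <- outer(s / (km + s), vms)      # n_obs x n_vmax
    sse <- colSums((pred - v)^2)
    j <- which.min(sse)
    if (sse[j] < best$sse) best <- list(sse = sse[j], km = km, vmax = vms[j])
  }
  best$km_step <- kms[2] / kms[1]
  best$vmax_step <- vms[2] / vms[1]
  best
}

# brute-force 2'-phosphate contact scan: plain double loop over candidate
# nitrogens and phosphate atoms
brute_force_contacts <- function(s, lig, cutoff = 4.0,
                                 residue_types = c("ARG", "LYS")) {
  nitro <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ",
                HIS = c("ND1", "NE2"))
  ph <- lig[lig$elety %in% c("P2B", "O1X", "O2X", "O3X"), ]
  a <- s$atoms
  a <- a[a$type == "ATOM" & a$resid %in% residue_types, ]
  out <- list()
  for (key in unique(paste(a$chain, a$resno))) {
    res <- a[paste(a$chain, a$resno) == key, ]
    res <- res[res$elety %in% nitro[[res$resid[1L]]], , drop = FALSE]
    if (!nrow(res)) next
    dmin <- Inf
    for (i in seq_len(nrow(res))) for (j in seq_len(nrow(ph))) {
      d <- sqrt((res$x[i] - ph$x[j])^2 + (res$y[i] - ph$y[j])^2 +
                (res$z[i] - ph$z[j])^2)
      if (d < dmin) dmin <- d
    }
    if (dmin < cutoff)
      out[[length(out) + 1L]] <- data.frame(
        chain = res$chain[1L], resno = res$resno[1L],
        resid = res$resid[1L], min_distance = dmin)
  }
  if (!length(out))
    return(data.frame(chain = character(), resno = integer(),
                      resid = character(), min_distance = numeric()))
  out <- do.call(rbind, out)
  out[order(out$chain, out$resno), , drop = FALSE]
}

# random protein sequence families: seeds mutated within-family
make_sequence_families <- function(n_families = 3, per_family = 5,
                                   len = 80, mut_rate = 0.1) {
  aas <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  unlist(lapply(seq_len(n_families), function(k) {
    seed_seq <- sample(aas, len, replace = TRUE)
    vapply(seq_len(per_family), function(j) {
      v <- seed_seq
      i <- which(runif(len) < mut_rate)
      v[i] <- sample(aas, length(i), replace = TRUE)
      paste(v, collapse = "")
    }, "")
  }))
}

# rigid motion helper for invariance tests
apply_rigid_motion <- function(s, rot, shift) {
  a <- s$atoms
  xyz <- t(rot %*% t(as.matrix(a[, c("x", "y", "z")]))) +
    matrix(shift, nrow(a), 3, byrow = TRUE)
  a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
  cof_structure(a)
}

rotation_about <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}

# Table-1-style noiseless datasets generated from KM and the printed
# specificity constant (kcat = KM * kcat/KM), both cofactors per variant
table1_noiseless_datasets <- function(e0 = 0.01) {
  tab <- ecoli_g6pdh_kinetics()
  tab <- tab[tab$enzyme %in% c("WT", "K18A", "R50A", "K18A-R50A"), ]
  lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    simulate_rate_dataset(
      km = r$km, kcat = r$km * r$kcat_over_km, enzyme_conc = e0,
      s_grid = r$km * c(0.2, 0.5, 1, 2, 5, 10, 20), noise_cv = 0,
      seed = 1L, enzyme_label = r$enzyme, cofactor_label = r$cofactor)
  })
}
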