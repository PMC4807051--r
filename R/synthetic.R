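#' Synthetic idealized NADP+ (NAP) template
#'
#' Builds the 48-heavy-atom NADP+ ligand used by the synthetic structure
#' generators: all atom names follow the NAP chemical-component convention
#' (nicotinamide ring N1N..C6N with the C7N/O7N/N7N carboxamide, the two
#' riboses, the pyrophosphate bridge, the adenine ring N9A..N6A, and the
#' 2'-phosphate P2B/O1X/O2X/O3X). Coordinates are a synthetic idealized
#' geometry constructed in code -- bond lengths are plausible and the
#' conformation is extended (C2N-C6A well above 12 angstrom) -- not
#' experimental or dictionary coordinates.
#'
#' @param chain chain identifier for the ligand.
#' @param resno residue number.
#' @return a [cof_structure()] holding the 48 HETATM records.
#' @export
nap_template <- function(chain = "A", resno = 500L) {
  xyz <- rbind(
    # nicotinamide ring (planar hexagon, r = 1.395 A) + carboxamide
    N1N = c(0.000, 1.395, 0.00),
    C2N = c(-1.208, 0.6975, 0.00),
    C3N = c(-1.208, -0.6975, 0.00),
    C4N = c(0.000, -1.395, 0.00),
    C5N = c(1.208, -0.6975, 0.00),
    C6N = c(1.208, 0.6975, 0.00),
    C7N = c(-2.507, -1.4475, 0.00),
    O7N = c(-2.800, -2.620, 0.55),
    N7N = c(-3.550, -0.850, -0.30),
    # nicotinamide ribose
    C1D = c(0.000, 2.850, 0.00),
    O4D = c(1.150, 3.550, 0.10),
    C4D = c(2.350, 2.850, 0.35),
    C3D = c(1.950, 1.550, 0.70),
    C2D = c(0.550, 1.650, 0.55),
    O2D = c(0.250, 0.900, 1.55),
    O3D = c(2.650, 0.500, 1.10),
    C5D = c(3.650, 3.400, 0.20),
    O5D = c(4.850, 2.700, 0.10),
    # pyrophosphate bridge
    PN  = c(6.250, 2.850, 0.00),
    O1N = c(6.600, 4.250, 0.05),
    O2N = c(6.950, 2.000, 1.05),
    O3  = c(7.000, 2.350, -1.35),
    PA  = c(8.500, 2.150, -1.65),
    O1A = c(9.000, 3.400, -2.15),
    O2A = c(8.650, 1.000, -2.60),
    O5B = c(9.350, 1.800, -0.40),
    # adenine ribose with the 2'-phosphate
    C5B = c(10.750, 1.650, -0.45),
    C4B = c(11.350, 1.050, 0.80),
    O4B = c(12.650, 1.450, 1.05),
    C1B = c(13.250, 0.500, 1.90),
    C2B = c(12.250, -0.650, 2.05),
    C3B = c(11.000, -0.250, 1.35),
    O3B = c(10.300, -1.250, 1.95),
    O2B = c(12.850, -1.850, 1.60),
    P2B = c(12.950, -3.300, 2.30),
    O1X = c(11.650, -4.000, 2.25),
    O2X = c(13.950, -4.100, 1.55),
    O3X = c(13.350, -3.200, 3.75),
    # adenine
    N9A = c(14.550, 0.950, 2.20),
    C8A = c(15.050, 2.200, 2.00),
    N7A = c(16.350, 2.200, 2.40),
    C5A = c(16.650, 0.950, 2.90),
    C4A = c(15.550, 0.150, 2.85),
    N3A = c(15.550, -1.200, 3.25),
    C2A = c(16.750, -1.750, 3.65),
    N1A = c(17.950, -1.050, 3.70),
    C6A = c(17.950, 0.350, 3.30),
    N6A = c(19.100, 1.050, 3.35))
  atoms <- data.frame(
    type = "HETATM", eleno = seq_len(nrow(xyz)), elety = rownames(xyz),
    resid = "NAP", chain = chain, resno = as.integer(resno),
    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L], o = 1, b = 0,
    elesy = substr(rownames(xyz), 1L, 1L))
  cof_structure(atoms)
}

# atom names of the 2'-phosphate moiety in the NAP component
nap_phosphate_atoms <- c("P2B", "O1X", "O2X", "O3X")

#' Simulate an initial-rate dataset from known parameters
#'
#' Rates follow v = kcat * E0 * S / (KM + S) with independent multiplicative
#' Gaussian noise per point and replicate (constant coefficient of
#' variation, matching the roughly proportional error bars of published
#' kinetic tables). Deterministic for a given seed.
#'
#' @param km Michaelis constant, uM.
#' @param kcat turnover number, 1/s.
#' @param enzyme_conc enzyme concentration E0, uM.
#' @param s_grid substrate concentrations, uM.
#' @param noise_cv coefficient of variation of the noise (0 for noiseless).
#' @param replicates replicates per concentration.
#' @param seed RNG seed.
#' @param enzyme_label,cofactor_label labels carried into the dataset.
#' @return a [kinetic_dataset()].
#' @export
simulate_rate_dataset <- function(km, kcat, enzyme_conc, s_grid,
                                  noise_cv = 0.05, replicates = 3L, seed = 1L,
                                  enzyme_label = "synthetic",
                                  cofactor_label = "NADP+") {
  if (any(c(km, kcat, enzyme_conc) <= 0) || any(s_grid <= 0))
    stop("kinetic parameters and substrate concentrations must be positive")
  if (noise_cv < 0) stop("'noise_cv' must be non-negative")
  set.seed(seed)
  s <- rep(s_grid, each = replicates)
  rep_id <- rep(seq_len(replicates), times = length(s_grid))
  v <- kcat * enzyme_conc * s / (km + s)
  v <- v * (1 + stats::rnorm(length(s)) * noise_cv)
  kinetic_dataset(enzyme_label, cofactor_label, enzyme_conc,
                  data.frame(substrate_conc = s, rate = v,
                             replicate = rep_id))
}

#' Simulate an integrated Michaelis-Menten progress curve
#'
#' Integrates dS/dt = -Vmax * S / (KM + S) with [deSolve::lsoda()] at
#' relative tolerance 1e-9 and reports product formation P(t) = S0 - S(t),
#' optionally with additive Gaussian noise (matching the additive character
#' of absorbance noise).
#'
#' @param km Michaelis constant, uM.
#' @param vmax maximal velocity, uM/s.
#' @param s0 initial substrate concentration, uM.
#' @param t_grid increasing time grid, seconds.
#' @param noise_sd additive noise standard deviation, uM.
#' @param seed RNG seed (only used when `noise_sd > 0`).
#' @return a [progress_curve()].
#' @export
simulate_progress_curve <- function(km, vmax, s0, t_grid, noise_sd = 0,
                                    seed = 1L) {
  if (any(c(km, vmax, s0) <= 0)) stop("parameters must be positive")
  if (any(diff(t_grid) <= 0)) stop("'t_grid' must be strictly increasing")
  if (noise_sd < 0) stop("'noise_sd' must be non-negative")
  times <- t_grid
  prepend <- times[1L] > 0
  if (prepend) times <- c(0, times)
  sol <- deSolve::lsoda(
    y = c(S = s0), times = times,
    func = function(t, y, p) list(-vmax * y[1L] / (km + y[1L])),
    rtol = 1e-9, atol = 1e-12)
  S <- sol[, "S"]
  if (prepend) S <- S[-1L]
  product <- s0 - S
  if (noise_sd > 0) {
    set.seed(seed)
    product <- product + stats::rnorm(length(product)) * noise_sd
  }
  progress_curve(t_grid, product, signal_to_conc = 1, initial_substrate = s0)
}

# random unit vector
runif_sphere <- function() {
  repeat {
    v <- stats::rnorm(3L)
    n <- sqrt(sum(v^2))
    if (n > 1e-6) return(v / n)
  }
}

#' Build a toy NADP+ complex with planted 2'-phosphate contacts
#'
#' Embeds the synthetic NAP template plus positively charged side-chain
#' probe atoms (ARG NH1 / LYS NZ / HIS NE2) placed at exactly the requested
#' minimum distances from the nearest 2'-phosphate atom, together with decoy
#' residues whose atoms stay at least 6 angstrom away. Ground truth for the
#' contact screen is therefore known by construction.
#'
#' @param n_positive number of planted positive residues.
#' @param types residue types of the planted residues (ARG/LYS/HIS),
#'   recycled to `n_positive`.
#' @param distances planted minimum distances in angstrom (>= 1.5),
#'   recycled to `n_positive`.
#' @param decoys number of decoy residues (cycled over ARG, LYS, ALA).
#' @param seed RNG seed.
#' @return a [cof_structure()] with the NAP ligand (chain A) and protein
#'   residues (chain B).
#' @export
make_toy_complex <- function(n_positive = 2L, types = c("ARG", "LYS"),
                             distances = c(3.5, 3.8), decoys = 5L,
                             seed = 1L) {
  if (n_positive < 0) stop("'n_positive' must be >= 0")
  types <- rep_len(types, n_positive)
  distances <- rep_len(as.numeric(distances), n_positive)
  if (n_positive > 0 && any(distances < 1.5))
    stop("planted distances below 1.5 angstrom are sterically nonsensical")
  probe_atom <- c(ARG = "NH1", LYS = "NZ", HIS = "NE2")
  extra_atoms <- list(ARG = c("NE", "NH2"), LYS = "CE", HIS = "ND1")
  if (n_positive > 0 && !all(types %in% names(probe_atom)))
    stop("'types' must be ARG, LYS or HIS")

  set.seed(seed)
  nap <- nap_template(chain = "A", resno = 500L)$atoms
  ph <- nap[nap$elety %in% nap_phosphate_atoms, ]
  ph_xyz <- atom_xyz(ph)
  centroid <- colMeans(ph_xyz)

  rows <- list(nap)
  eleno <- nrow(nap)
  resno <- 0L
  add_residue <- function(resid, names, coords) {
    resno <<- resno + 1L
    n <- length(names)
    df <- data.frame(type = "ATOM", eleno = eleno + seq_len(n),
                     elety = names, resid = resid, chain = "B",
                     resno = resno, x = coords[, 1L], y = coords[, 2L],
                     z = coords[, 3L], o = 1, b = 0,
                     elesy = substr(names, 1L, 1L))
    eleno <<- eleno + n
    rows[[length(rows) + 1L]] <<- df
  }

  free_ox <- c("O1X", "O2X", "O3X")
  for (i in seq_len(n_positive)) {
    target <- ph[ph$elety == free_ox[(i - 1L) %% 3L + 1L], ]
    t_xyz <- as.numeric(target[, c("x", "y", "z")])
    d <- distances[i]
    for (try in 1:200) {
      u <- (t_xyz - centroid) / sqrt(sum((t_xyz - centroid)^2))
      u <- u + 0.35 * runif_sphere()
      u <- u / sqrt(sum(u^2))
      probe <- t_xyz + d * u
      dall <- pairwise_distances(matrix(probe, ncol = 3), ph_xyz)
      if (abs(min(dall) - d) < 1e-9) break
      if (try == 200L) stop("failed to place probe atom")
    }
    nm <- c(probe_atom[[types[i]]], extra_atoms[[types[i]]], "CA")
    offsets <- seq(0, by = 1.4, length.out = length(nm))
    coords <- t(vapply(offsets, function(o) probe + o * u, numeric(3)))
    add_residue(types[i], nm, coords)
  }

  decoy_types <- rep_len(c("ARG", "LYS", "ALA"), decoys)
  decoy_atoms <- list(ARG = c("NE", "NH1", "NH2", "CA"),
                      LYS = c("NZ", "CA"), ALA = c("CB", "CA"))
  for (i in seq_len(decoys)) {
    ty <- decoy_types[i]
    repeat {
      base <- centroid + stats::runif(1, 8, 15) * runif_sphere()
      nm <- decoy_atoms[[ty]]
      coords <- t(vapply(seq_along(nm) - 1L,
                         function(k) base + k * 1.4 * runif_sphere(),
                         numeric(3)))
      if (min(pairwise_distances(coords, ph_xyz)) >= 6) break
    }
    add_residue(ty, nm, coords)
  }

  cof_structure(do.call(rbind, rows))
}

# random proper rotation matrix (uniform via QR of a Gaussian matrix)
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9L), 3L))
  q <- qr.Q(qr_)
  q <- q %*% diag(sign(diag(qr.R(qr_))))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

#' Build trajectory frames with scheduled hydrogen-bond geometry
#'
#' One donor/hydrogen/acceptor triple per frame, realised at exactly the
#' scheduled donor-acceptor distance and D-H-A angle, embedded in a rigid
#' decoy scaffold; every frame is then rigidly rotated and translated at
#' random, so detection must be invariant under rigid motions. The donor is
#' a serine OG-HG pair (residue 1), the acceptor a glycine backbone O
#' (residue 2).
#'
#' @param schedule data.frame (or 2-column matrix) with columns `distance`
#'   (angstrom, > 0.96, the D-H bond length used) and `angle` (degrees, in
#'   (0, 180\]); one row per frame.
#' @param seed RNG seed for the rigid motions.
#' @param frame_interval nominal sampling interval in ps.
#' @return a [cof_trajectory()].
#' @export
make_hbond_frames <- function(schedule, seed = 1L, frame_interval = 50) {
  schedule <- as.data.frame(schedule)
  if (ncol(schedule) == 2L && !all(c("distance", "angle") %in% names(schedule)))
    names(schedule) <- c("distance", "angle")
  if (!nrow(schedule)) stop("'schedule' must have at least one frame")
  if (any(schedule$angle <= 0 | schedule$angle > 180))
    stop("scheduled angles must lie in (0, 180]")
  dh <- 0.96  # O-H bond length
  if (any(schedule$distance <= dh))
    stop("scheduled distances must exceed the D-H bond length (", dh, " A)")
  set.seed(seed)

  scaffold <- data.frame(
    type = "ATOM",
    eleno = 1:8,
    elety = c("OG", "HG", "CB", "O", rep("CA", 4L)),
    resid = c("SER", "SER", "SER", "GLY", rep("GLY", 4L)),
    chain = "A",
    resno = c(1L, 1L, 1L, 2L, 3L, 4L, 5L, 6L),
    x = 0, y = 0, z = 0, o = 1, b = 0,
    elesy = c("O", "H", "C", "O", "C", "C", "C", "C"))
  decoy_xyz <- rbind(c(8, 8, 8), c(-9, 7, -6), c(10, -8, 5), c(-8, -9, -8))

  frames <- lapply(seq_len(nrow(schedule)), function(i) {
    d <- schedule$distance[i]
    theta <- schedule$angle[i]
    phi <- (180 - theta) * pi / 180
    w <- c(cos(phi), sin(phi), 0)
    # solve |H + r w| = d for r > 0 with donor at origin, H at (dh, 0, 0)
    r <- -dh * cos(phi) + sqrt(dh^2 * cos(phi)^2 - dh^2 + d^2)
    D <- c(0, 0, 0)
    H <- c(dh, 0, 0)
    A <- H + r * w
    xyz <- rbind(D, H, D + c(-1.4, 0, 0), A, decoy_xyz)
    rot <- random_rotation()
    shift <- stats::runif(3L, -10, 10)
    xyz <- t(rot %*% t(xyz)) + matrix(shift, nrow(xyz), 3L, byrow = TRUE)
    a <- scaffold
    a$x <- xyz[, 1L]; a$y <- xyz[, 2L]; a$z <- xyz[, 3L]
    cof_structure(a)
  })
  cof_trajectory(frames, frame_interval = frame_interval)
}
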