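# Seeded synthetic structures: ideal-geometry chains, graded decoy ladders
# with known ground truth, and training sets. These generators make the full
# train -> score -> benchmark pipeline testable offline; they emulate
# single-chain heavy-atom proteins, not real side-chain rotamers.

# Ideal peptide internal coordinates (Engh-Huber-like values).
PEPTIDE_GEOMETRY <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  b_ca_cb = 1.521,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
  a_ca_c_o = 120.8, a_c_ca_cb = 110.1,
  t_n_c_ca_cb = 122.55, omega = 180)

PHI_PSI <- list(helix = c(phi = -57, psi = -47),
                strand = c(phi = -120, psi = 120))

# Distance (Angstrom) of the pseudo side-chain atom beyond CB along the
# CA->CB direction, roughly tracking side-chain size. ALA/GLY have none.
PSEUDO_SC_EXTENSION <- c(
  ARG = 2.4, ASN = 1.5, ASP = 1.5, CYS = 1.3, GLN = 1.9, GLU = 1.9,
  HIS = 1.9, ILE = 1.4, LEU = 1.6, LYS = 2.2, MET = 2.0, PHE = 2.1,
  PRO = 1.2, SER = 1.0, THR = 1.1, TRP = 2.5, TYR = 2.3, VAL = 1.2)

# Place atom D given A, B, C with bond |C-D|, angle B-C-D and torsion
# A-B-C-D (degrees): the standard internal-to-Cartesian (NeRF) step.
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180; tor <- torsion * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  n <- pracma_cross(b - a, bc)
  n <- n / sqrt(sum(n^2))
  m <- pracma_cross(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  c + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}

pracma_cross <- function(u, v) {
  c(u[2L] * v[3L] - u[3L] * v[2L],
    u[3L] * v[1L] - u[1L] * v[3L],
    u[1L] * v[2L] - u[2L] * v[1L])
}

resolve_sequence <- function(n_residues, sequence) {
  if (length(sequence) == 1L && identical(sequence, "random"))
    return(sample(STANDARD_AA, n_residues, replace = TRUE))
  if (length(sequence) == 1L && !sequence %in% STANDARD_AA) {
    letters1 <- strsplit(toupper(sequence), "")[[1L]]
    seq3 <- AA_ONE_TO_THREE[letters1]
    if (any(is.na(seq3))) stop("invalid one-letter residue code in sequence")
    sequence <- unname(seq3)
  }
  sequence <- rep_len(toupper(sequence), n_residues)
  if (!all(sequence %in% STANDARD_AA)) stop("invalid residue code in sequence")
  sequence
}

phi_psi_for <- function(fold, n) {
  switch(fold,
    helix = matrix(rep(PHI_PSI$helix, each = n), ncol = 2,
                   dimnames = list(NULL, c("phi", "psi"))),
    strand = matrix(rep(PHI_PSI$strand, each = n), ncol = 2,
                    dimnames = list(NULL, c("phi", "psi"))),
    mixed = {
      # alternating 8-residue helix / strand blocks
      block <- ((seq_len(n) - 1L) %/% 8L) %% 2L
      cbind(phi = ifelse(block == 0L, PHI_PSI$helix["phi"],
                         PHI_PSI$strand["phi"]),
            psi = ifelse(block == 0L, PHI_PSI$helix["psi"],
                         PHI_PSI$strand["psi"]))
    },
    stop("fold must be one of helix, strand, mixed"))
}

#' Generate an ideal-geometry synthetic chain
#'
#' Builds a single chain with an ideal peptide backbone (N, CA, C, O) at the
#' requested backbone dihedrals (helix: phi = -57, psi = -47; strand:
#' phi = -120, psi = +120; mixed alternates 8-residue blocks), a C-beta by
#' ideal internal coordinates on every non-glycine residue, and one pseudo
#' side-chain heavy atom per non-glycine/alanine residue placed beyond the
#' C-beta along the CA->CB direction at a residue-type-specific distance
#' (named after the residue's real gamma heavy atom, e.g. OG for serine).
#' Fully deterministic given the seed.
#'
#' @param n_residues number of residues (>= 4).
#' @param sequence `"random"`, a one-letter-code string, or a character
#'   vector of 3-letter codes (recycled to length).
#' @param fold `"helix"`, `"strand"` or `"mixed"`.
#' @param seed integer seed (used for random sequences).
#' @param chain_id chain identifier.
#' @return a `chain` object.
#' @export
make_chain <- function(n_residues, sequence = "random", fold = "helix",
                       seed = 1L, chain_id = "A") {
  if (n_residues < 4L) stop("n_residues must be >= 4")
  seq3 <- with_seed(seed, resolve_sequence(n_residues, sequence))
  g <- PEPTIDE_GEOMETRY
  tors <- phi_psi_for(fold, n_residues)

  # backbone N, CA, C by sequential NeRF; first residue laid out manually
  N <- CA <- C <- matrix(NA_real_, n_residues, 3L)
  N[1L, ] <- c(0, 0, 0)
  CA[1L, ] <- c(g$b_n_ca, 0, 0)
  ang <- g$a_n_ca_c * pi / 180
  C[1L, ] <- CA[1L, ] + g$b_ca_c * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n_residues)[-1L]) {
    N[i, ] <- place_atom(N[i - 1L, ], CA[i - 1L, ], C[i - 1L, ],
                         g$b_c_n, g$a_ca_c_n, tors[i - 1L, "psi"])
    CA[i, ] <- place_atom(CA[i - 1L, ], C[i - 1L, ], N[i, ],
                          g$b_n_ca, g$a_c_n_ca, g$omega)
    C[i, ] <- place_atom(C[i - 1L, ], N[i, ], CA[i, ],
                         g$b_ca_c, g$a_n_ca_c, tors[i, "phi"])
  }

  rows <- vector("list", n_residues)
  for (i in seq_len(n_residues)) {
    rt <- seq3[i]
    at <- list(N = N[i, ], CA = CA[i, ], C = C[i, ])
    at$O <- place_atom(N[i, ], CA[i, ], C[i, ],
                       g$b_c_o, g$a_ca_c_o, tors[i, "psi"] + 180)
    if (rt != "GLY") {
      at$CB <- place_atom(N[i, ], C[i, ], CA[i, ],
                          g$b_ca_cb, g$a_c_ca_cb, g$t_n_c_ca_cb)
      if (!rt %in% c("ALA", "GLY")) {
        u <- at$CB - at$CA
        u <- u / sqrt(sum(u^2))
        gname <- AA_SIDECHAIN_ATOMS[[rt]][2L]   # the gamma heavy atom
        at[[gname]] <- at$CB + PSEUDO_SC_EXTENSION[[rt]] * u
      }
    }
    m <- do.call(rbind, at)
    rows[[i]] <- data.frame(
      res_type = rt, res_seq = i, icode = "", ordinal = i,
      atom_name = names(at), element = toupper(guess_element(names(at))),
      x = m[, 1L], y = m[, 2L], z = m[, 3L], occupancy = 1,
      stringsAsFactors = FALSE)
  }
  new_chain(do.call(rbind, rows), chain_id)
}

#' Generate a graded decoy ladder from a native chain
#'
#' For each noise level, adds i.i.d. Gaussian noise (sd = sigma, Angstrom)
#' to every atom coordinate of the native; ground-truth TM-scores are
#' computed against the native. Expected TM decreases with sigma.
#'
#' @param native a `chain` object.
#' @param noise_sigmas strictly increasing positive noise levels (Angstrom).
#' @param n_decoys_per_sigma decoys per level.
#' @param seed integer seed.
#' @param compute_tm compute TM-scores (set `FALSE` to skip the similarity
#'   step when only coordinates are needed).
#' @return list with `decoys` (named list of `chain`) and `manifest`
#'   (data.frame model_id, sigma, tm).
#' @export
make_decoy_ladder <- function(native, noise_sigmas = c(0.5, 1, 2, 4, 8),
                              n_decoys_per_sigma = 1L, seed = 1L,
                              compute_tm = TRUE) {
  stopifnot(all(noise_sigmas > 0), !is.unsorted(noise_sigmas, strictly = TRUE))
  xyz <- chain_coords(native)
  decoys <- list()
  manifest <- list()
  with_seed(seed, {
    for (sg in noise_sigmas) {
      for (k in seq_len(n_decoys_per_sigma)) {
        noisy <- xyz + matrix(stats::rnorm(length(xyz), sd = sg), ncol = 3L)
        id <- sprintf("s%g_d%02d", sg, k)
        ch <- set_chain_coords(native, noisy)
        decoys[[id]] <- ch
        manifest[[id]] <- data.frame(
          model_id = id, sigma = sg,
          tm = if (compute_tm) tm_score(ch, native) else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  })
  list(decoys = decoys, manifest = do.call(rbind, unname(manifest)))
}

#' Generate a synthetic training set
#'
#' `n_chains` chains with random sequences, folds cycling through helix /
#' strand / mixed, and small Gaussian jitter (sd 0.2 Angstrom) on every
#' coordinate so that distance distributions have realistic width.
#' Deterministic given the seed.
#'
#' @param n_chains number of chains (>= 1).
#' @param n_residues residues per chain.
#' @param seed integer seed.
#' @param jitter_sd coordinate jitter, Angstrom; default 0.2.
#' @return list of `chain` objects.
#' @export
make_training_set <- function(n_chains, n_residues = 60L, seed = 1L,
                              jitter_sd = 0.2) {
  stopifnot(n_chains >= 1L)
  folds <- c("helix", "strand", "mixed")
  with_seed(seed, {
    lapply(seq_len(n_chains), function(i) {
      ch <- make_chain(n_residues, "random", folds[(i - 1L) %% 3L + 1L],
                       seed = stats::runif(1L, 1, 2^30))
      xyz <- chain_coords(ch)
      set_chain_coords(ch, xyz + matrix(stats::rnorm(length(xyz),
                                                     sd = jitter_sd),
                                        ncol = 3L))
    })
  })
}
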