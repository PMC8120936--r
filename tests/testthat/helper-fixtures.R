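# Fixtures built in code: tiny PDB files, hand-built models, oracles.

# A minimal PDB text fixture: backbone-only residues on a line, optional
# extra records appended verbatim.
fixture_pdb_lines <- function(n_res = 3L, res_type = "ALA", extra = character(0)) {
  lines <- character(0)
  serial <- 1L
  for (i in seq_len(n_res)) {
    for (at in c("N", "CA", "C", "O")) {
      x <- (i - 1L) * 3.8 + match(at, c("N", "CA", "C", "O")) * 0.4
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           %1s",
        serial, at, res_type, i, x, 1.0, 2.0, 1.00, 10.0,
        substr(at, 1L, 1L)))
      serial <- serial + 1L
    }
  }
  c(lines, extra, "END")
}

write_fixture_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(lines, path)
  path
}

# A chain with one complete tryptophan residue (all heavy atoms, arbitrary
# but distinct coordinates) framed by alanines so min-length checks pass.
full_trp_chain <- function() {
  trp_atoms <- c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "NE1",
                 "CE2", "CE3", "CZ2", "CZ3", "CH2")
  rows <- list()
  add_res <- function(i, rt, atoms) {
    n <- length(atoms)
    data.frame(res_type = rt, res_seq = i, icode = "", ordinal = i,
               atom_name = atoms, element = substr(atoms, 1L, 1L),
               x = i * 10 + seq_len(n) * 0.9, y = seq_len(n) * 0.7,
               z = rev(seq_len(n)) * 0.5, occupancy = 1,
               stringsAsFactors = FALSE)
  }
  atoms <- rbind(add_res(1L, "ALA", c("N", "CA", "C", "O", "CB")),
                 add_res(2L, "TRP", trp_atoms),
                 add_res(3L, "ALA", c("N", "CA", "C", "O", "CB")))
  ddscore::new_chain(atoms, "A")
}

# A chain of bare CA sites at given coordinates (one residue per site).
ca_only_chain <- function(xyz, res_type = "ALA") {
  n <- nrow(xyz)
  ddscore::new_chain(data.frame(
    res_type = rep_len(res_type, n), res_seq = seq_len(n), icode = "",
    ordinal = seq_len(n), atom_name = "CA", element = "C",
    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L], occupancy = 1,
    stringsAsFactors = FALSE), "A")
}

# Hand-built potential model on a tiny grid: 2 scoring bins of width 5 A
# (score_cutoff 10 = train_cutoff), CA representation, with explicitly given
# bin probabilities per class and for the reference.
hand_model <- function(conditional_probs, reference_probs,
                       spec = ddscore::representation_spec("CA")) {
  config <- ddscore::training_config(train_cutoff = 10, score_cutoff = 10,
                                     bin_width = 5, min_separation = 3L,
                                     truncate_at_scoring = FALSE)
  mk <- function(p) structure(
    list(probs = p, bin_width = 5, cutoff = 10, n_samples = 100L,
         bandwidth = 1, low_confidence = FALSE),
    class = "distance_distribution")
  structure(list(
    spec = spec, config = config,
    conditional = lapply(conditional_probs, mk),
    reference = mk(reference_probs),
    provenance = list(n_chains = 0L, n_observations = 0L,
                      n_classes = length(conditional_probs),
                      prior = "HAND")),
    class = "potential_model")
}

# Independent brute-force scorer: enumerates all site pairs directly from a
# chain, applies the separation and cutoff filters, and looks up bin
# probabilities one by one. Never calls collect_pairs/score_*.
brute_force_score <- function(model, chain, formalism = c("pmf", "tig")) {
  formalism <- match.arg(formalism)
  cfg <- model$config
  sites <- ddscore::project(chain, model$spec)
  n_score <- round(cfg$score_cutoff / cfg$bin_width)
  total <- 0; n_pairs <- 0L
  for (i in seq_len(nrow(sites))) for (j in seq_len(nrow(sites))) {
    if (j <= i) next
    if (abs(sites$seq_ordinal[i] - sites$seq_ordinal[j]) < cfg$min_separation)
      next
    d <- sqrt(sum((as.numeric(sites[i, c("x", "y", "z")]) -
                   as.numeric(sites[j, c("x", "y", "z")]))^2))
    if (d > cfg$score_cutoff) next
    bin <- min(floor(d / cfg$bin_width) + 1L, n_score)
    key <- ddscore::canonical_pair_key(sites[i, ], sites[j, ])
    dist1 <- model$conditional[[key]]
    p1 <- if (is.null(dist1)) 1 / n_score else dist1$probs[bin]
    p2 <- model$reference$probs[bin]
    total <- total +
      if (formalism == "pmf") -log(p1 / p2) else -(p1 / p2 - 1)
    n_pairs <- n_pairs + 1L
  }
  list(total = total, n_pairs = n_pairs)
}

# A random rotation matrix (QR of a Gaussian matrix, determinant forced +1).
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

# Synthetic decoy table: per target a decoy ladder with real TM ground truth
# and scores drawn independently at random (the random-scorer null).
random_score_table <- function(n_targets, sigmas, n_per_sigma, n_res, seed) {
  ddscore::STANDARD_AA  # force package load
  rows <- vector("list", n_targets)
  for (t in seq_len(n_targets)) {
    native <- ddscore::make_chain(n_res, "random", "mixed",
                                  seed = seed + 7L * t)
    lad <- ddscore::make_decoy_ladder(native, sigmas, n_per_sigma,
                                      seed = seed + 1000L + t)
    man <- lad$manifest
    rows[[t]] <- data.frame(target_id = sprintf("T%03d", t),
                            model_id = man$model_id, tm = man$tm,
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  set.seed(seed + 99L)
  tab$score <- stats::runif(nrow(tab))
  tab$is_native <- FALSE
  tab
}
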