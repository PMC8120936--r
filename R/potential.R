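# Distance-dependent statistical potentials.
#
# Two distance distributions are learned from native structures: a
# conditional model M1 per pair class (residue types + site labels of the
# pair) and an unconditioned reference model M2, the "reference state".
# A conformation is scored by summing, over all site pairs within the scoring
# cutoff and at sequence separation >= 3,
#   PMF:  -log( P(d | M1) / P(d | M2) )          (negative log-likelihood ratio)
#   TIG:  -( P(d | M1) / P(d | M2) - 1 )         (relative difference)
# Lower totals indicate more native-like distance statistics.

#' Training configuration for a statistical potential
#'
#' @param train_cutoff distance cutoff (Angstrom) for collecting training
#'   pairs; default 17.0.
#' @param score_cutoff distance cutoff (Angstrom) at scoring time; default
#'   15.0; must not exceed `train_cutoff`.
#' @param bin_width discretization width (Angstrom); default 0.5; must divide
#'   both cutoffs into whole bins.
#' @param min_separation minimum sequence separation (residue positions)
#'   between paired sites; pairs closer than this are not processed;
#'   default 3.
#' @param probability_floor small positive lower bound applied to every bin
#'   probability before renormalization, preventing log(0) and division by
#'   zero; default 1e-10.
#' @param bandwidth one of `"per_class"` (default; each distribution gets its
#'   own Scott bandwidth) or `"global"` (one bandwidth from the pooled
#'   reference sample reused for every conditional fit).
#' @param truncate_at_scoring if `TRUE` (default) the trained distributions
#'   are truncated to the scoring cutoff and renormalized when scoring; if
#'   `FALSE` the raw training-grid probabilities are read.
#' @return object of class `training_config`.
#' @export
training_config <- function(train_cutoff = 17.0, score_cutoff = 15.0,
                            bin_width = 0.5, min_separation = 3L,
                            probability_floor = 1e-10,
                            bandwidth = c("per_class", "global"),
                            truncate_at_scoring = TRUE) {
  bandwidth <- match.arg(bandwidth)
  if (!(score_cutoff > 0 && score_cutoff <= train_cutoff))
    stop("need 0 < score_cutoff <= train_cutoff")
  whole <- function(x) abs(x / bin_width - round(x / bin_width)) < 1e-9
  if (!(whole(train_cutoff) && whole(score_cutoff)))
    stop("bin_width must divide both cutoffs into whole bins")
  if (min_separation < 1L) stop("min_separation must be >= 1")
  if (probability_floor <= 0) stop("probability_floor must be positive")
  structure(list(train_cutoff = train_cutoff, score_cutoff = score_cutoff,
                 bin_width = bin_width,
                 min_separation = as.integer(min_separation),
                 probability_floor = probability_floor,
                 bandwidth = bandwidth,
                 truncate_at_scoring = isTRUE(truncate_at_scoring)),
            class = "training_config")
}

#' Collect scorable site pairs
#'
#' All unordered site pairs whose residues are at least `min_separation`
#' positions apart in sequence and whose Euclidean distance does not exceed
#' `cutoff`; each unordered pair appears exactly once.
#'
#' @param sites site data.frame from [project()].
#' @param cutoff distance cutoff, Angstrom.
#' @param min_separation minimum residue-ordinal separation.
#' @return data.frame with columns `key` (canonical pair class) and
#'   `distance` (Angstrom). May be empty.
#' @export
collect_pairs <- function(sites, cutoff, min_separation = 3L) {
  n <- nrow(sites)
  empty <- data.frame(key = character(0), distance = numeric(0),
                      stringsAsFactors = FALSE)
  if (n < 2L) return(empty)
  xyz <- as.matrix(sites[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  sep <- abs(outer(sites$seq_ordinal, sites$seq_ordinal, "-"))
  take <- upper.tri(d) & sep >= min_separation & d <= cutoff
  idx <- which(take, arr.ind = TRUE)
  if (!nrow(idx)) return(empty)
  data.frame(
    key = pair_key(sites$res_type[idx[, 1L]], sites$site_label[idx[, 1L]],
                   sites$res_type[idx[, 2L]], sites$site_label[idx[, 2L]]),
    distance = d[take],
    stringsAsFactors = FALSE)
}

#' Scott's rule-of-thumb bandwidth
#'
#' One-dimensional Scott bandwidth `h = sd(x) * n^(-1/5)`.
#'
#' @param samples numeric vector of distances, length >= 2 with nonzero
#'   variance.
#' @return bandwidth in the units of `samples`.
#' @export
scott_bandwidth <- function(samples) {
  n <- length(samples)
  if (n < 2L) stop("scott_bandwidth needs at least 2 samples")
  s <- stats::sd(samples)
  if (!is.finite(s) || s == 0) stop("scott_bandwidth needs nonzero variance")
  s * n^(-1 / 5)
}

# Gaussian KDE evaluated at given points, chunked to bound temporaries.
kde_eval <- function(x, h, at) {
  n <- length(x)
  dens <- numeric(length(at))
  step <- 200000L
  for (s in seq(1L, n, by = step)) {
    xx <- x[s:min(n, s + step - 1L)]
    dens <- dens + vapply(at, function(c0) sum(stats::dnorm(c0, xx, h)), 0)
  }
  dens / n
}

floor_and_renormalize <- function(p, floor) {
  p <- pmax(p, floor)
  p <- p / sum(p)
  p <- pmax(p, floor)
  p / sum(p)
}

#' Fit a binned distance distribution
#'
#' Gaussian KDE with Scott bandwidth evaluated at the bin centers of a grid
#' of width `bin_width` on (0, cutoff]; converted to bin probabilities
#' (density times width), floored at `probability_floor` and renormalized.
#' Degenerate samples (fewer than 2, or zero variance) fall back to a plain
#' histogram; an empty sample yields the uniform distribution, flagged
#' low-confidence.
#'
#' @param samples numeric vector of distances in (0, cutoff].
#' @param cutoff grid upper end, Angstrom.
#' @param config a [training_config()].
#' @param bandwidth optional fixed bandwidth overriding Scott's rule.
#' @return object of class `distance_distribution` with elements `probs`,
#'   `bin_width`, `cutoff`, `n_samples`, `bandwidth`, `low_confidence`.
#' @export
fit_distribution <- function(samples, cutoff, config, bandwidth = NULL) {
  w <- config$bin_width
  nbins <- as.integer(round(cutoff / w))
  centers <- (seq_len(nbins) - 0.5) * w
  n <- length(samples)
  low_confidence <- FALSE
  h <- NA_real_
  if (n == 0L) {
    probs <- rep(1 / nbins, nbins)
    low_confidence <- TRUE
  } else {
    h <- if (!is.null(bandwidth)) bandwidth
         else tryCatch(scott_bandwidth(samples), error = function(e) NA_real_)
    if (is.na(h)) {
      # histogram fallback for degenerate samples
      bins <- pmin(pmax(floor(samples / w) + 1L, 1L), nbins)
      probs <- tabulate(bins, nbins) / n
    } else {
      probs <- kde_eval(samples, h, centers) * w
    }
  }
  probs <- floor_and_renormalize(probs, config$probability_floor)
  structure(list(probs = probs, bin_width = w, cutoff = cutoff,
                 n_samples = n, bandwidth = h,
                 low_confidence = low_confidence),
            class = "distance_distribution")
}

#' Train a statistical potential
#'
#' Projects every training chain under the representation, collects pairs at
#' the training cutoff, fits the conditional model M1 per pair class from the
#' pooled observations, and fits the reference model M2 from the pooled
#' (class-blind) observations of the prior projection: the all-heavy-atom
#' projection under `reference_mode = "all_atom_prior"` (all beads, for bead
#' representations) or the representation's own projection under
#' `"representation_prior"`.
#'
#' @param structures list of `chain` objects (native structures).
#' @param spec a [representation_spec()].
#' @param config a [training_config()].
#' @return object of class `potential_model`.
#' @export
train_potential <- function(structures, spec, config = training_config()) {
  stopifnot(length(structures) >= 1L, inherits(spec, "representation_spec"),
            inherits(config, "training_config"))
  obs <- do.call(rbind, lapply(structures, function(ch)
    collect_pairs(project(ch, spec), config$train_cutoff,
                  config$min_separation)))
  pspec <- prior_spec(spec)
  ref_obs <- if (identical(pspec$name, spec$name)) obs else
    do.call(rbind, lapply(structures, function(ch)
      collect_pairs(project(ch, pspec), config$train_cutoff,
                    config$min_separation)))
  if (is.null(obs) || nrow(obs) == 0L || nrow(ref_obs) == 0L)
    stop("no pair observations collected; cannot train")

  global_h <- if (config$bandwidth == "global")
    scott_bandwidth(ref_obs$distance) else NULL
  reference <- fit_distribution(ref_obs$distance, config$train_cutoff, config)
  conditional <- lapply(split(obs$distance, obs$key), fit_distribution,
                        cutoff = config$train_cutoff, config = config,
                        bandwidth = global_h)
  structure(list(
    spec = spec, config = config,
    conditional = conditional, reference = reference,
    provenance = list(n_chains = length(structures),
                      n_observations = nrow(obs),
                      n_reference_observations = nrow(ref_obs),
                      n_classes = length(conditional),
                      prior = pspec$name)),
    class = "potential_model")
}

#' @export
print.potential_model <- function(x, ...) {
  cat(sprintf(
    "<potential_model %s: %d classes from %d chains (%d pairs), prior %s>\n",
    x$spec$name, x$provenance$n_classes, x$provenance$n_chains,
    x$provenance$n_observations, x$provenance$prior))
  invisible(x)
}

# ---- scoring ----------------------------------------------------------------

# Probabilities on the scoring grid: first n_score bins, renormalized when
# the config says to truncate.
scoring_probs <- function(probs, config) {
  n_score <- as.integer(round(config$score_cutoff / config$bin_width))
  p <- probs[seq_len(n_score)]
  if (config$truncate_at_scoring) p <- p / sum(p)
  p
}

# Bin index of a distance on the scoring grid; d exactly at the cutoff falls
# in the last bin (half-open bins [k*w, (k+1)*w)).
score_bin <- function(d, config) {
  n_score <- as.integer(round(config$score_cutoff / config$bin_width))
  pmin(pmax(floor(d / config$bin_width) + 1L, 1L), n_score)
}

# Shared scoring pipeline; returns per-pair P1, P2 and metadata.
pair_probabilities <- function(model, chain) {
  config <- model$config
  sites <- project(chain, model$spec)
  pairs <- collect_pairs(sites, config$score_cutoff, config$min_separation)
  n_score <- as.integer(round(config$score_cutoff / config$bin_width))
  if (nrow(pairs) == 0L)
    return(list(p1 = numeric(0), p2 = numeric(0), pairs = pairs,
                n_unknown = 0L))
  bins <- score_bin(pairs$distance, config)
  p2_grid <- scoring_probs(model$reference$probs, config)
  cls <- match(pairs$key, names(model$conditional))
  unknown <- is.na(cls)
  p1 <- numeric(nrow(pairs))
  if (any(!unknown)) {
    grids <- vapply(model$conditional[unique(cls[!unknown])],
                    function(d) scoring_probs(d$probs, config),
                    numeric(n_score))
    col <- match(cls[!unknown], unique(cls[!unknown]))
    p1[!unknown] <- grids[cbind(bins[!unknown], col)]
  }
  # unseen class: floored-uniform conditional, i.e. no information
  p1[unknown] <- 1 / n_score
  list(p1 = p1, p2 = p2_grid[bins], pairs = pairs,
       n_unknown = sum(unknown))
}

score_result <- function(terms, n_unknown, keep_terms) {
  structure(list(total = sum(terms), n_pairs = length(terms),
                 n_unknown_classes = n_unknown,
                 terms = if (keep_terms) terms else NULL,
                 flagged = length(terms) == 0L),
            class = "score_result")
}

#' @export
print.score_result <- function(x, ...) {
  cat(sprintf("<score %.4f over %d pairs%s>\n", x$total, x$n_pairs,
              if (x$flagged) " (no scorable pairs)" else ""))
  invisible(x)
}

#' Score a conformation with the PMF formalism
#'
#' Sums the negative log-likelihood ratio `-log(P(d|M1)/P(d|M2))` over all
#' scorable pairs. Lower is more native-like.
#'
#' @param model a trained `potential_model`.
#' @param chain a `chain` object to score.
#' @param keep_terms keep the per-pair terms in the result.
#' @return object of class `score_result` with `total`, `n_pairs`,
#'   `n_unknown_classes`, optional `terms`.
#' @export
score_pmf <- function(model, chain, keep_terms = FALSE) {
  pp <- pair_probabilities(model, chain)
  score_result(-log(pp$p1 / pp$p2), pp$n_unknown, keep_terms)
}

#' Score a conformation with the TIG formalism
#'
#' Identical pipeline to [score_pmf()], with the log-likelihood ratio
#' replaced by the relative difference; the per-pair term is
#' `-(P(d|M1)/P(d|M2) - 1)`, keeping the lower-is-better orientation.
#'
#' @inheritParams score_pmf
#' @export
score_tig <- function(model, chain, keep_terms = FALSE) {
  pp <- pair_probabilities(model, chain)
  score_result(-(pp$p1 / pp$p2 - 1), pp$n_unknown, keep_terms)
}

#' Information gain of an observed distance
#'
#' The Shannon-surprisal difference `dI = (-log P(d|M2)) - (-log P(d|M1))`:
#' how much information the conditional model adds over the reference at this
#' distance. The PMF total of a chain equals minus the sum of `dI` over its
#' scored pairs.
#'
#' @param distance numeric vector of distances, Angstrom.
#' @param key matching character vector of canonical pair-class keys.
#' @param model a trained `potential_model`.
#' @return numeric vector of information gains (nats).
#' @export
information_gain <- function(distance, key, model) {
  config <- model$config
  n_score <- as.integer(round(config$score_cutoff / config$bin_width))
  bins <- score_bin(distance, config)
  p2 <- scoring_probs(model$reference$probs, config)[bins]
  cls <- match(key, names(model$conditional))
  p1 <- vapply(seq_along(distance), function(i) {
    if (is.na(cls[i])) 1 / n_score
    else scoring_probs(model$conditional[[cls[i]]]$probs, config)[bins[i]]
  }, 0)
  log(p1) - log(p2)
}

# ---- serialization ----------------------------------------------------------

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

#' Write a potential model to a portable text file
#'
#' Self-describing versioned plain-text format; [read_model()] reproduces the
#' model bit-exactly.
#'
#' @param model a `potential_model`.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "potential_model"))
  con <- file(path, "w")
  on.exit(close(con))
  cfg <- model$config
  hdr <- c(
    "# ddscore potential model format 1",
    paste("spec.name", model$spec$name),
    paste("spec.glycine_policy", model$spec$glycine_policy),
    paste("spec.reference_mode", model$spec$reference_mode),
    paste("config.train_cutoff", fmt_num(cfg$train_cutoff)),
    paste("config.score_cutoff", fmt_num(cfg$score_cutoff)),
    paste("config.bin_width", fmt_num(cfg$bin_width)),
    paste("config.min_separation", cfg$min_separation),
    paste("config.probability_floor", fmt_num(cfg$probability_floor)),
    paste("config.bandwidth", cfg$bandwidth),
    paste("config.truncate_at_scoring", cfg$truncate_at_scoring),
    paste("provenance.n_chains", model$provenance$n_chains),
    paste("provenance.n_observations", model$provenance$n_observations),
    paste("provenance.prior", model$provenance$prior))
  writeLines(hdr, con)
  dist_line <- function(tag, d)
    paste(tag, d$n_samples, fmt_num(d$bandwidth), as.integer(d$low_confidence),
          paste(fmt_num(d$probs), collapse = " "))
  writeLines(dist_line("reference -", model$reference), con)
  for (k in names(model$conditional))
    writeLines(dist_line(paste("class", k), model$conditional[[k]]), con)
  invisible(path)
}

#' Read a potential model written by [write_model()]
#'
#' @param path model file path.
#' @return a `potential_model`.
#' @export
read_model <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1L], "# ddscore potential model format 1"))
    stop("unrecognized model file: ", path)
  kv <- lines[grepl("^(spec|config|provenance)\\.", lines)]
  key <- sub(" .*$", "", kv)
  val <- sub("^[^ ]+ ", "", kv)
  getv <- function(k) val[match(k, key)]
  spec <- representation_spec(getv("spec.name"),
                              getv("spec.glycine_policy"),
                              getv("spec.reference_mode"))
  config <- training_config(
    train_cutoff = as.numeric(getv("config.train_cutoff")),
    score_cutoff = as.numeric(getv("config.score_cutoff")),
    bin_width = as.numeric(getv("config.bin_width")),
    min_separation = as.integer(getv("config.min_separation")),
    probability_floor = as.numeric(getv("config.probability_floor")),
    bandwidth = getv("config.bandwidth"),
    truncate_at_scoring = as.logical(getv("config.truncate_at_scoring")))
  parse_dist <- function(rest, cutoff) {
    parts <- strsplit(rest, " ", fixed = TRUE)[[1L]]
    structure(list(probs = as.numeric(parts[-(1:3)]),
                   bin_width = config$bin_width, cutoff = cutoff,
                   n_samples = as.integer(parts[1L]),
                   bandwidth = suppressWarnings(as.numeric(parts[2L])),
                   low_confidence = parts[3L] == "1"),
              class = "distance_distribution")
  }
  ref_line <- lines[startsWith(lines, "reference ")]
  reference <- parse_dist(sub("^reference - ", "", ref_line),
                          config$train_cutoff)
  cls_lines <- lines[startsWith(lines, "class ")]
  keys <- sub("^class ([^ ]+) .*$", "\\1", cls_lines)
  conditional <- lapply(sub("^class [^ ]+ ", "", cls_lines), parse_dist,
                        cutoff = config$train_cutoff)
  names(conditional) <- keys
  structure(list(
    spec = spec, config = config, conditional = conditional,
    reference = reference,
    provenance = list(
      n_chains = as.integer(getv("provenance.n_chains")),
      n_observations = as.integer(getv("provenance.n_observations")),
      n_classes = length(conditional),
      prior = getv("provenance.prior"))),
    class = "potential_model")
}
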