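# Structural representations: projecting a chain onto typed scoring sites.
#
# Ten representations are supported, from a single C-alpha per residue up to
# all heavy atoms, plus MARTINI-style coarse-grained backbone/side-chain
# beads. A projection yields "sites": points with a residue type, a site
# label (atom or bead name) and the residue ordinal, which together define
# the pair classes of the statistical models.

REPRESENTATION_NAMES <- c("CA", "CB", "CA_CB", "BACKBONE", "BACKBONE_CB",
                          "SIDECHAINS", "ALL_ATOM", "BB", "SC", "BB_SC")
BEAD_REPRESENTATIONS <- c("BB", "SC", "BB_SC")

#' Define a structural representation
#'
#' @param name one of `"CA"`, `"CB"`, `"CA_CB"`, `"BACKBONE"`,
#'   `"BACKBONE_CB"`, `"SIDECHAINS"`, `"ALL_ATOM"`, `"BB"`, `"SC"`,
#'   `"BB_SC"` (case-insensitive).
#' @param glycine_policy how glycine enters C-beta-containing
#'   representations: `"substitute_ca"` (default; glycine is represented by
#'   its C-alpha) or `"exclude"` (glycine contributes nothing).
#' @param reference_mode which projection feeds the reference (background)
#'   distance distribution at training time: `"all_atom_prior"` (default;
#'   all heavy atoms, or all beads for bead representations) or
#'   `"representation_prior"` (the representation's own sites).
#' @return object of class `representation_spec`.
#' @export
representation_spec <- function(name,
                                glycine_policy = c("substitute_ca", "exclude"),
                                reference_mode = c("all_atom_prior",
                                                   "representation_prior")) {
  nm <- toupper(gsub("[+-]", "_", as.character(name)[1L]))
  if (!nm %in% REPRESENTATION_NAMES)
    stop("unknown representation '", name, "'; valid names are: ",
         paste(REPRESENTATION_NAMES, collapse = ", "))
  structure(list(name = nm,
                 glycine_policy = match.arg(glycine_policy),
                 reference_mode = match.arg(reference_mode)),
            class = "representation_spec")
}

#' @export
print.representation_spec <- function(x, ...) {
  cat(sprintf("<representation %s (glycine: %s, reference: %s)>\n",
              x$name, x$glycine_policy, x$reference_mode))
  invisible(x)
}

# The projection whose pooled pairs train the reference state under the
# default all-atom prior. Bead representations live in a bead universe, so
# their widest prior is BB_SC.
prior_spec <- function(spec) {
  if (spec$reference_mode == "representation_prior") return(spec)
  nm <- if (spec$name %in% BEAD_REPRESENTATIONS) "BB_SC" else "ALL_ATOM"
  representation_spec(nm, spec$glycine_policy, spec$reference_mode)
}

empty_sites <- function() {
  data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
             res_type = character(0), site_label = character(0),
             seq_ordinal = integer(0), stringsAsFactors = FALSE)
}

sites_from_atoms <- function(a, labels = a$atom_name) {
  data.frame(x = a$x, y = a$y, z = a$z, res_type = a$res_type,
             site_label = labels, seq_ordinal = a$ordinal,
             stringsAsFactors = FALSE)
}

# CB selection with the glycine policy applied; glycine contributes its CA
# (labelled "CA") under substitute_ca, nothing under exclude.
select_cb <- function(a, glycine_policy) {
  cb <- a[a$atom_name == "CB" & a$res_type != "GLY", , drop = FALSE]
  out <- sites_from_atoms(cb)
  if (glycine_policy == "substitute_ca") {
    gly <- a[a$atom_name == "CA" & a$res_type == "GLY", , drop = FALSE]
    out <- rbind(out, sites_from_atoms(gly))
  }
  out
}

#' Project a chain onto a representation
#'
#' Missing atoms are skipped silently (the chain's completeness report tracks
#' them); sites are returned in residue order.
#'
#' @param chain a `chain` object.
#' @param spec a `representation_spec`.
#' @return data.frame of sites with columns `x`, `y`, `z`, `res_type`,
#'   `site_label`, `seq_ordinal`.
#' @export
project <- function(chain, spec) {
  stopifnot(inherits(chain, "chain"), inherits(spec, "representation_spec"))
  if (spec$name %in% BEAD_REPRESENTATIONS) return(project_beads(chain, spec))
  a <- chain$atoms
  s <- switch(spec$name,
    CA = sites_from_atoms(a[a$atom_name == "CA", , drop = FALSE]),
    CB = select_cb(a, spec$glycine_policy),
    CA_CB = rbind(sites_from_atoms(a[a$atom_name == "CA", , drop = FALSE]),
                  select_cb(a, spec$glycine_policy)),
    BACKBONE = sites_from_atoms(
      a[a$atom_name %in% BACKBONE_ATOMS, , drop = FALSE]),
    BACKBONE_CB = rbind(
      sites_from_atoms(a[a$atom_name %in% BACKBONE_ATOMS, , drop = FALSE]),
      select_cb(a, spec$glycine_policy)),
    SIDECHAINS = sites_from_atoms(
      a[!(a$atom_name %in% BACKBONE_ATOMS), , drop = FALSE]),
    ALL_ATOM = sites_from_atoms(a))
  # a site is identified by (residue, label): the glycine CA produced by the
  # CB selector and the CA selector is one and the same site
  s <- s[!duplicated(paste(s$seq_ordinal, s$site_label)), , drop = FALSE]
  s <- s[order(s$seq_ordinal), , drop = FALSE]
  rownames(s) <- NULL
  s
}

# Cached side-chain bead mapping table: named list res_type -> named list
# bead -> character vector of atom names.
.bead_cache <- new.env(parent = emptyenv())

bead_mapping <- function() {
  if (!is.null(.bead_cache$map)) return(.bead_cache$map)
  path <- system.file("extdata", "martini_beads_v2.tsv", package = "ddscore")
  if (path == "") path <- file.path("inst", "extdata", "martini_beads_v2.tsv")
  tab <- utils::read.delim(path, comment.char = "#", header = FALSE,
                           col.names = c("res_type", "bead", "atoms"),
                           stringsAsFactors = FALSE)
  map <- lapply(split(tab, tab$res_type), function(d) {
    beads <- lapply(strsplit(d$atoms, " +"), trimws)
    names(beads) <- d$bead
    beads[order(names(beads))]
  })
  map$ALA <- list(); map$GLY <- list()
  .bead_cache$map <- map
  map
}

#' Project a chain onto coarse-grained beads
#'
#' One backbone bead (`"BB"`) per residue at the unweighted centroid of its
#' backbone heavy atoms, and zero to four side-chain beads (`"SC1"`..`"SC4"`)
#' at centroids of fixed residue-type-specific atom groups following the
#' MARTINI 2.x amino-acid definitions (shipped as a plain-text table).
#'
#' @inheritParams project
#' @export
project_beads <- function(chain, spec) {
  stopifnot(inherits(chain, "chain"), inherits(spec, "representation_spec"))
  a <- chain$atoms
  map <- bead_mapping()
  want_bb <- spec$name %in% c("BB", "BB_SC")
  want_sc <- spec$name %in% c("SC", "BB_SC")
  res_ord <- unique(a$ordinal)
  out <- vector("list", length(res_ord))
  for (k in seq_along(res_ord)) {
    ra <- a[a$ordinal == res_ord[k], , drop = FALSE]
    rt <- ra$res_type[1L]
    if (is.null(map[[rt]]) && !rt %in% STANDARD_AA) {
      warning("skipping residue of unknown type ", rt)
      next
    }
    rows <- list()
    if (want_bb) {
      bb <- ra[ra$atom_name %in% BACKBONE_ATOMS, , drop = FALSE]
      if (nrow(bb))
        rows[["BB"]] <- c(mean(bb$x), mean(bb$y), mean(bb$z))
    }
    if (want_sc) {
      for (bead in names(map[[rt]])) {
        ba <- ra[ra$atom_name %in% map[[rt]][[bead]], , drop = FALSE]
        if (nrow(ba))
          rows[[bead]] <- c(mean(ba$x), mean(ba$y), mean(ba$z))
      }
    }
    if (length(rows)) {
      m <- do.call(rbind, rows)
      out[[k]] <- data.frame(x = m[, 1L], y = m[, 2L], z = m[, 3L],
                             res_type = rt, site_label = names(rows),
                             seq_ordinal = res_ord[k],
                             stringsAsFactors = FALSE)
    }
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) return(empty_sites())
  s <- do.call(rbind, out)
  rownames(s) <- NULL
  s
}

# All (res_type, site_label) single-site types a complete residue of each
# standard type could emit under the representation. Generated enumeration;
# deduplicated so that e.g. glycine's substituted C-alpha is one type.
site_type_universe <- function(spec) {
  labels_for <- function(rt) {
    cb_labels <- if (rt == "GLY") {
      if (spec$glycine_policy == "substitute_ca") "CA" else character(0)
    } else "CB"
    switch(spec$name,
      CA = "CA",
      CB = cb_labels,
      CA_CB = unique(c("CA", cb_labels)),
      BACKBONE = BACKBONE_ATOMS,
      BACKBONE_CB = unique(c(BACKBONE_ATOMS, cb_labels)),
      SIDECHAINS = AA_SIDECHAIN_ATOMS[[rt]],
      ALL_ATOM = c(BACKBONE_ATOMS, AA_SIDECHAIN_ATOMS[[rt]]),
      BB = "BB",
      SC = names(bead_mapping()[[rt]]),
      BB_SC = c("BB", names(bead_mapping()[[rt]])))
  }
  rows <- lapply(STANDARD_AA, function(rt) {
    labs <- labels_for(rt)
    if (!length(labs)) return(NULL)
    data.frame(res_type = rt, site_label = labs, stringsAsFactors = FALSE)
  })
  u <- do.call(rbind, rows)
  u <- u[!duplicated(paste(u$res_type, u$site_label)), , drop = FALSE]
  rownames(u) <- NULL
  u
}

#' Count the distinct pair classes of a representation
#'
#' Enumerates every canonical unordered pair (self-pairs included) over the
#' representation's possible (residue type, site label) types and counts the
#' distinct keys. For the C-beta representation with glycine substituted this
#' is 210; with glycine excluded, 190.
#'
#' @param spec a `representation_spec`.
#' @return integer count of distinct pair classes.
#' @export
enumerate_pair_classes <- function(spec) {
  u <- site_type_universe(spec)
  n <- nrow(u)
  if (n == 0L) return(0L)
  idx <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  keys <- pair_key(u$res_type[idx[, 1L]], u$site_label[idx[, 1L]],
                   u$res_type[idx[, 2L]], u$site_label[idx[, 2L]])
  length(unique(keys))
}

# Vectorized canonical key for pairs of (res_type, site_label) types.
pair_key <- function(res1, lab1, res2, lab2) {
  a <- paste(res1, lab1, sep = ":")
  b <- paste(res2, lab2, sep = ":")
  ifelse(a <= b, paste(a, b, sep = "|"), paste(b, a, sep = "|"))
}

#' Canonical pair key of two sites
#'
#' Order-independent: `canonical_pair_key(a, b)` equals
#' `canonical_pair_key(b, a)`.
#'
#' @param a,b single-row site data.frames (as returned by [project()]).
#' @return character key of the form `"RES:LABEL|RES:LABEL"` with the two
#'   halves in lexicographic order.
#' @export
canonical_pair_key <- function(a, b) {
  pair_key(a$res_type, a$site_label, b$res_type, b$site_label)
}
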