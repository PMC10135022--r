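# Alignment-free descriptor space.
#
# Peptides become points in a d-dimensional physicochemical space: amino
# acid composition plus global sequence properties. Columns are min-max
# normalised to [0,1] and compared by Euclidean distance; similarity is the
# complement of the distance scaled by the global maximum, so the cutoff
# grid 0..0.95 applies directly.

# Kyte-Doolittle hydropathy
KD_HYDROPATHY <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
                   Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
                   L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
                   S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

# Eisenberg consensus hydrophobicity (moment calculation)
EISENBERG <- c(A = 0.62, R = -2.53, N = -0.78, D = -0.90, C = 0.29,
               Q = -0.85, E = -0.74, G = 0.48, H = -0.40, I = 1.38,
               L = 1.06, K = -1.50, M = 0.64, F = 1.19, P = 0.12,
               S = -0.18, T = -0.05, W = 0.81, Y = 0.26, V = 1.08)

# water-to-cyclohexane transfer free energies (kcal/mol) behind the
# Boman-style protein-binding/solubility term; proline has no published
# value and contributes 0
BOMAN_SCALE <- c(L = -4.92, I = -4.92, V = -4.04, F = -2.98, M = -2.35,
                 W = -2.33, A = -1.81, C = -1.28, G = -0.94, Y = -0.14,
                 P = 0, T = 2.57, S = 3.40, H = 4.66, Q = 5.54, K = 5.55,
                 N = 6.64, E = 6.81, D = 8.72, R = 14.92)

RESIDUE_CLASSES <- list(
  aliphatic = c("A", "I", "L", "V"),
  aromatic  = c("F", "H", "W", "Y"),
  polar     = c("C", "N", "Q", "S", "T", "Y"),
  positive  = c("H", "K", "R"),
  negative  = c("D", "E"),
  tiny      = c("A", "C", "G", "S", "T")
)

aa_counts <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  tab <- table(factor(chars, levels = AA_ALPHABET20))
  as.numeric(tab)
}

net_charge_ph7 <- function(chars) {
  sum(chars == "K") + sum(chars == "R") + 0.5 * sum(chars == "H") -
    sum(chars == "D") - sum(chars == "E")
}

hydrophobic_moment <- function(chars, window = 11L, delta_deg = 100) {
  n <- length(chars)
  h <- EISENBERG[chars]
  delta <- delta_deg * pi / 180
  moment_of <- function(idx) {
    ang <- seq_along(idx) * delta
    hi <- h[idx]
    sqrt(sum(hi * sin(ang))^2 + sum(hi * cos(ang))^2) / length(idx)
  }
  if (n <= window) return(moment_of(seq_len(n)))
  starts <- seq_len(n - window + 1L)
  mean(vapply(starts, function(s) moment_of(s:(s + window - 1L)),
              numeric(1)))
}

descriptor_vector <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  comp <- aa_counts(seq) / n
  names(comp) <- paste0("comp_", AA_ALPHABET20)
  classes <- vapply(RESIDUE_CLASSES,
                    function(cl) mean(chars %in% cl), numeric(1))
  names(classes) <- paste0("frac_", names(classes))
  c(comp,
    length = n,
    net_charge = net_charge_ph7(chars),
    hydropathy = mean(KD_HYDROPATHY[chars]),
    hydrophobic_moment = hydrophobic_moment(chars),
    classes,
    aromaticity = mean(chars %in% c("F", "W", "Y")),
    boman = mean(BOMAN_SCALE[chars]))
}

#' Names of the default alignment-free descriptor panel
#'
#' The default panel holds the 20 amino-acid composition fractions plus
#' sequence length, net charge at pH 7 (K/R +1, H +0.5, D/E -1),
#' mean Kyte-Doolittle hydropathy, a mean Eisenberg hydrophobic-moment
#' term (window 11, alpha-helical 100 degrees, full-sequence fallback for
#' short peptides), six residue-class fractions, aromaticity (F+W+Y) and a
#' Boman-style mean solubility term.
#'
#' @return Character vector of descriptor names.
#' @export
default_descriptor_panel <- function() {
  names(descriptor_vector("ACDEFGHIKLMNPQRSTVWY"))
}

#' Compute alignment-free descriptors for a peptide set
#'
#' @param set A non-empty `peptide_set`.
#' @param panel Character vector of descriptor names to keep (a subset of
#'   [default_descriptor_panel()]); unknown names are an error.
#' @return A `descriptor_matrix`: peptides in rows (set order), descriptors
#'   in columns, not yet normalised.
#' @export
compute_descriptors <- function(set, panel = default_descriptor_panel()) {
  stopifnot(inherits(set, "peptide_set"))
  if (length(set) == 0L) stop("empty peptide set", call. = FALSE)
  known <- default_descriptor_panel()
  unknown <- setdiff(panel, known)
  if (length(unknown)) {
    stop("unknown descriptor(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  values <- t(vapply(set$sequences, descriptor_vector,
                     numeric(length(known))))
  values <- values[, panel, drop = FALSE]
  rownames(values) <- set$ids
  structure(list(ids = set$ids, values = values,
                 descriptor_names = panel, normalized = FALSE),
            class = "descriptor_matrix")
}

#' Min-max normalise a descriptor matrix
#'
#' Each column x maps to (x - min)/(max - min); constant columns map to all
#' zeros. The per-column bounds are stored for reuse on new data.
#'
#' @param m An unnormalised `descriptor_matrix` with >= 2 rows.
#' @return The normalised `descriptor_matrix`, every column in \[0, 1\],
#'   with attribute `bounds` (min/max per column).
#' @export
minmax_normalize <- function(m) {
  stopifnot(inherits(m, "descriptor_matrix"))
  if (isTRUE(m$normalized)) stop("matrix is already normalized", call. = FALSE)
  if (nrow(m$values) < 2L) {
    stop("min-max normalization needs at least 2 peptides", call. = FALSE)
  }
  mins <- apply(m$values, 2, min)
  maxs <- apply(m$values, 2, max)
  rng <- maxs - mins
  vals <- sweep(m$values, 2, mins, "-")
  vals <- sweep(vals, 2, ifelse(rng > 0, rng, 1), "/")
  vals[, rng == 0] <- 0
  m$values <- vals
  m$normalized <- TRUE
  m$bounds <- data.frame(descriptor = m$descriptor_names,
                         min = mins, max = maxs, row.names = NULL)
  m
}

#' Euclidean distance matrix over normalised descriptors
#'
#' @param m A normalised `descriptor_matrix`.
#' @return A `distance_matrix`: symmetric, zero diagonal, entries >= 0.
#' @export
distance_matrix <- function(m) {
  stopifnot(inherits(m, "descriptor_matrix"))
  if (!isTRUE(m$normalized)) {
    stop("distance_matrix requires a min-max normalized descriptor matrix",
         call. = FALSE)
  }
  d <- as.matrix(stats::dist(m$values, method = "euclidean"))
  dimnames(d) <- list(m$ids, m$ids)
  structure(list(ids = m$ids, values = d), class = "distance_matrix")
}

#' Similarity matrix from distances
#'
#' s(i, j) = 1 - d(i, j) / d_max with d_max the largest off-diagonal
#' distance (global normalisation); a degenerate all-zero distance matrix
#' yields all-ones similarity. Ordering is the exact reverse of the
#' distance ordering.
#'
#' @param d A `distance_matrix`.
#' @return A `similarity_matrix` with unit diagonal and entries in \[0, 1\].
#' @export
to_similarity <- function(d) {
  stopifnot(inherits(d, "distance_matrix"))
  dmax <- max(d$values)
  s <- if (dmax > 0) 1 - d$values / dmax else
    matrix(1, nrow(d$values), ncol(d$values))
  diag(s) <- 1
  dimnames(s) <- list(d$ids, d$ids)
  structure(list(ids = d$ids, values = s), class = "similarity_matrix")
}

#' Principal-component coordinates of the descriptor space
#'
#' First two PCs of the normalised descriptor matrix, used as 2-D node
#' coordinates in GraphML exports so viewers can draw the chemical space
#' without a layout algorithm.
#'
#' @param m A normalised `descriptor_matrix`.
#' @return Data.frame with columns id, pc1, pc2.
#' @export
pca_coords <- function(m) {
  stopifnot(inherits(m, "descriptor_matrix"), isTRUE(m$normalized))
  p <- stats::prcomp(m$values, center = TRUE, scale. = FALSE)
  k <- min(2L, ncol(p$x))
  out <- data.frame(id = m$ids, pc1 = p$x[, 1],
                    pc2 = if (k > 1) p$x[, 2] else 0)
  rownames(out) <- NULL
  out
}
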