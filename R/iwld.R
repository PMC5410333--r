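# Improved Weber Local Descriptor (IWLD) of a PSSM.
#
# The descriptor treats the L x 20 score matrix as a texture image.  Two
# fields are computed per cell: the differential excitation xi (arctan of
# the summed differences to the 8-neighbourhood, relative to the centre
# intensity) and the gradient orientation gamma (atan2 of vertical over
# horizontal Sobel responses, shifted into [0, 2pi)).  Both fields are
# quantised (M excitation bins, T orientations) and accumulated into a
# joint M x T histogram per sub-block of a V x H partition; block
# histograms are concatenated into the final feature vector of length
# M*T*V*H (256 at the defaults M = T = 8, V = H = 2).

#' IWLD descriptor parameters
#'
#' @param M Number of differential-excitation bins (default 8).
#' @param T Number of dominant orientations (default 8).
#' @param V,H Number of sub-blocks vertically (along the sequence) and
#'   horizontally (across the 20 score columns); default 2 x 2.
#' @param epsilon Positive guard added to the excitation denominator so the
#'   ratio is defined for zero intensities.
#' @param scale If `TRUE` (default) scores are passed through the logistic
#'   map `1 / (1 + exp(-s))` before filtering, giving strictly positive
#'   intensities in (0, 1); `FALSE` filters the raw scores with only the
#'   epsilon guard.
#' @param normalize If `TRUE`, each block histogram is L1-normalised;
#'   default `FALSE` keeps raw counts (their total equals the number of
#'   matrix cells, a useful conservation check).
#'
#' @return A list of class `iwld_params`.
#' @export
iwld_params <- function(M = 8L, T = 8L, V = 2L, H = 2L, epsilon = 1e-8,
                        scale = TRUE, normalize = FALSE) {
  stopifnot(M >= 1, T >= 1, V >= 1, H >= 1, epsilon > 0)
  structure(list(M = as.integer(M), T = as.integer(T), V = as.integer(V),
                 H = as.integer(H), epsilon = epsilon, scale = scale,
                 normalize = normalize),
            class = "iwld_params")
}

#' Logistic intensity scaling
#'
#' Maps integer log-odds scores into (0, 1) with `1 / (1 + exp(-s))`,
#' preserving order.  A strictly positive intensity keeps the excitation
#' denominator well defined.
#'
#' @param m Numeric matrix (or a [pssm()] object, whose scores are used).
#' @return Numeric matrix of the same shape with entries in (0, 1).
#' @export
logistic_scale <- function(m) {
  if (inherits(m, "pssm")) m <- m$scores
  1 / (1 + exp(-m))
}

# Replicate padding: every cell, including borders of the 20-wide matrix,
# gets a full 3x3 neighbourhood.
pad1 <- function(m) {
  L <- nrow(m); W <- ncol(m)
  m[c(1L, seq_len(L), L), c(1L, seq_len(W), W), drop = FALSE]
}

# The 8 one-cell shifts of a padded matrix, as a list of L x W matrices.
shift_stack <- function(m) {
  p <- pad1(m)
  L <- nrow(m); W <- ncol(m)
  idx <- function(dr, dc) p[seq_len(L) + 1L + dr, seq_len(W) + 1L + dc,
                            drop = FALSE]
  list(nw = idx(-1L, -1L), n = idx(-1L, 0L), ne = idx(-1L, 1L),
       w = idx(0L, -1L), e = idx(0L, 1L),
       sw = idx(1L, -1L), s = idx(1L, 0L), se = idx(1L, 1L))
}

#' Differential excitation field
#'
#' For each cell, the excitation is
#' `xi = arctan( sum_j (x_j - x_i) / max(x_i, epsilon) )` over the 8
#' neighbours `x_j` of the cell (replicate-padded at the borders).  The
#' arctangent compresses the relative-change ratio into
#' \[-pi/2, pi/2\].
#'
#' @param m Numeric matrix, at least 2 x 2.
#' @param epsilon Positive denominator guard.
#' @return Numeric matrix of the same shape with entries in \[-pi/2, pi/2\].
#' @export
differential_excitation <- function(m, epsilon = 1e-8) {
  stopifnot(nrow(m) >= 2, ncol(m) >= 2, epsilon > 0)
  s <- shift_stack(m)
  neigh_sum <- Reduce(`+`, s)
  atan((neigh_sum - 8 * m) / pmax(m, epsilon))
}

#' Gradient orientation field
#'
#' Horizontal and vertical Sobel responses are computed on the
#' replicate-padded matrix and combined as
#' `gamma = atan2(v_vert, v_horiz) + pi`, wrapped so that 2*pi maps to 0.
#' Flat regions (both responses zero) use the `atan2(0, 0) = 0` convention
#' and therefore map to `gamma = pi`.
#'
#' @param m Numeric matrix, at least 2 x 2.
#' @return Numeric matrix of the same shape with entries in \[0, 2*pi).
#' @export
orientation_field <- function(m) {
  stopifnot(nrow(m) >= 2, ncol(m) >= 2)
  s <- shift_stack(m)
  # Sobel kernels: horizontal [[-1,0,1],[-2,0,2],[-1,0,1]], vertical its
  # transpose; responses by direct correlation
  v10 <- -s$nw + s$ne - 2 * s$w + 2 * s$e - s$sw + s$se
  v11 <- -s$nw - 2 * s$n - s$ne + s$sw + 2 * s$s + s$se
  g <- atan2(v11, v10) + pi
  g[g >= 2 * pi] <- 0
  g
}

#' Quantise differential excitation into M bins
#'
#' Bin m (0-based) covers the interval from `(m/M - 1/2)*pi` to
#' `((m+1)/M - 1/2)*pi`, half-open except the top bin, which is closed at
#' `pi/2`.
#'
#' @param xi Numeric vector or matrix with values in \[-pi/2, pi/2\].
#' @param M Number of bins.
#' @return Integer bin indices in `0:(M-1)`, same shape as `xi`.
#' @export
quantize_excitation <- function(xi, M = 8L) {
  if (any(xi < -pi / 2 - 1e-12 | xi > pi / 2 + 1e-12)) {
    abort("excitation values must lie in [-pi/2, pi/2]",
          class = "ppidvm_error_domain")
  }
  out <- pmin(floor((xi + pi / 2) / (pi / M)), M - 1L)
  storage.mode(out) <- "integer"
  out
}

#' Quantise orientation into T dominant directions
#'
#' Nearest-dominant-orientation assignment with wraparound:
#' `t = floor(gamma / (2*pi/T) + 1/2) mod T`, so each angle maps to the
#' closest of the T directions `2*pi*t/T`.
#'
#' @param gamma Numeric vector or matrix with values in \[0, 2*pi).
#' @param T Number of dominant orientations.
#' @return Integer bin indices in `0:(T-1)`, same shape as `gamma`.
#' @export
quantize_orientation <- function(gamma, T = 8L) {
  if (any(gamma < 0 | gamma >= 2 * pi)) {
    abort("orientation values must lie in [0, 2*pi)",
          class = "ppidvm_error_domain")
  }
  out <- floor(gamma / (2 * pi / T) + 0.5) %% T
  storage.mode(out) <- "integer"
  out
}

# Contiguous band index for each of n positions split into B bands of size
# floor(n/B), remainder rows going to the last band.
band_index <- function(n, B) {
  s <- n %/% B
  pmin((seq_len(n) - 1L) %/% s + 1L, B)
}

#' Joint block histogram of excitation and orientation
#'
#' The matrix is partitioned into `V` contiguous row bands and `H` column
#' bands (band sizes `floor(dim/bands)`, remainder cells joining the last
#' band).  Within each block a joint M x T histogram is accumulated,
#' flattened m-major (orientation varying fastest), and blocks are
#' concatenated row-band-major.
#'
#' @param xi_field,gamma_field Matrices of identical shape from
#'   [differential_excitation()] and [orientation_field()].
#' @param params [iwld_params()].
#' @return Numeric vector of length `M*T*V*H`; raw counts summing to the
#'   number of cells unless `params$normalize` is set.
#' @export
block_histogram <- function(xi_field, gamma_field, params = iwld_params()) {
  stopifnot(identical(dim(xi_field), dim(gamma_field)))
  L <- nrow(xi_field); W <- ncol(xi_field)
  M <- params$M; T <- params$T; V <- params$V; H <- params$H
  if (L < V) {
    abort(sprintf("matrix has %d rows but %d vertical blocks requested",
                  L, V), class = "ppidvm_error_domain")
  }
  if (W < H) {
    abort(sprintf("matrix has %d columns but %d horizontal blocks requested",
                  W, H), class = "ppidvm_error_domain")
  }
  m_idx <- quantize_excitation(xi_field, M)
  t_idx <- quantize_orientation(gamma_field, T)
  rb <- band_index(L, V)
  cb <- band_index(W, H)
  block <- (rb[row(xi_field)] - 1L) * H + (cb[col(xi_field)] - 1L)  # 0-based
  flat <- block * (M * T) + m_idx * T + t_idx + 1L
  counts <- tabulate(flat, nbins = M * T * V * H)
  out <- as.numeric(counts)
  if (isTRUE(params$normalize)) {
    for (b in seq_len(V * H)) {
      sl <- ((b - 1L) * M * T + 1L):(b * M * T)
      tot <- sum(out[sl])
      if (tot > 0) out[sl] <- out[sl] / tot
    }
  }
  out
}

#' IWLD descriptor of a PSSM
#'
#' Full descriptor computation: optional logistic intensity scaling, the
#' differential-excitation and Sobel-orientation fields, quantisation, and
#' the concatenated block histogram.
#'
#' @param p A [pssm()] object (or a plain numeric matrix).
#' @param params [iwld_params()].
#' @return An object of class `iwld`: a list with `values` (numeric vector
#'   of length `M*T*V*H`), `params`, and `protein_id`.
#' @examples
#' d <- iwld(synth_pssm(60, seed = 5, texture = "rough", amplitude = 5))
#' length(d$values)  # 256 at the defaults
#' sum(d$values)     # 60 * 20 cells
#' @export
iwld <- function(p, params = iwld_params()) {
  id <- if (inherits(p, "pssm")) p$protein_id else "matrix"
  m <- if (inherits(p, "pssm")) p$scores else as.matrix(p)
  intens <- if (isTRUE(params$scale)) logistic_scale(m) else m
  xi <- differential_excitation(intens, params$epsilon)
  gam <- orientation_field(intens)
  structure(
    list(values = block_histogram(xi, gam, params), params = params,
         protein_id = id),
    class = "iwld"
  )
}

#' @export
print.iwld <- function(x, ...) {
  cat(sprintf("<iwld> %s: %d bins (M=%d T=%d V=%d H=%d), total mass %.6g\n",
              x$protein_id, length(x$values), x$params$M, x$params$T,
              x$params$V, x$params$H, sum(x$values)))
  invisible(x)
}

#' Concatenated pair feature
#'
#' Joins the descriptors of the two proteins of a pair, first protein
#' first, yielding a vector of length `2*M*T*V*H` (512 at the defaults).
#'
#' @param a,b [iwld()] descriptors computed with identical parameters.
#' @return Numeric vector `c(a$values, b$values)`.
#' @export
pair_feature <- function(a, b) {
  stopifnot(inherits(a, "iwld"), inherits(b, "iwld"))
  pa <- a$params; pb <- b$params
  if (!identical(pa[c("M", "T", "V", "H", "scale", "normalize")],
                 pb[c("M", "T", "V", "H", "scale", "normalize")])) {
    abort("pair_feature requires descriptors with identical parameters",
          class = "ppidvm_error_domain")
  }
  c(a$values, b$values)
}

#' Assemble the pair feature table
#'
#' Computes one IWLD descriptor per distinct protein and concatenates them
#' per pair record, returning a tibble ready for dimensionality reduction
#' and classification.
#'
#' @param pairs Tibble with columns `id_a`, `id_b`, `label`.
#' @param pssms Named list of [pssm()] objects covering every id in `pairs`.
#' @param params [iwld_params()].
#' @return A tibble with `id_a`, `id_b`, `label` and `2*M*T*V*H` feature
#'   columns named `f001`, `f002`, ...
#' @examples
#' d <- synth_pair_dataset(4, effect = 2, seed = 1)
#' ft <- featurize_pairs(d$pairs, d$pssms)
#' dim(ft)
#' @export
featurize_pairs <- function(pairs, pssms, params = iwld_params()) {
  validate_pair_table(pairs, pssms)
  ids <- unique(c(pairs$id_a, pairs$id_b))
  descs <- lapply(pssms[ids], iwld, params = params)
  feat <- t(vapply(seq_len(nrow(pairs)),
                   function(i) pair_feature(descs[[pairs$id_a[i]]],
                                            descs[[pairs$id_b[i]]]),
                   numeric(2L * params$M * params$T * params$V * params$H)))
  colnames(feat) <- sprintf("f%0*d", max(3L, nchar(ncol(feat))),
                            seq_len(ncol(feat)))
  dplyr::bind_cols(pairs[, c("id_a", "id_b", "label")],
                   tibble::as_tibble(feat))
}

# Extract the feature matrix (and labels) back out of a feature table.
feature_matrix <- function(feature_table) {
  fcols <- grep("^f[0-9]+$", names(feature_table), value = TRUE)
  as.matrix(feature_table[, fcols])
}
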