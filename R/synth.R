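# Synthetic PSSMs and labelled pair datasets.  The generator emulates the
# score magnitudes of real PSI-BLAST profiles (integer scores, clipped to
# [-16, 13]) while giving explicit control over the local-gradient texture
# that the IWLD descriptor measures.

PSSM_SCORE_MIN <- -16L
PSSM_SCORE_MAX <- 13L

# Base i.i.d. score noise, in score units.  Chosen to match the spread of
# typical PSI-BLAST log-odds columns.
SYNTH_NOISE_SD <- 4

# Square-wave row stripe planted by the "motif" regime: period in rows, and
# the stripe amplitude contributed per unit of `amplitude`/`effect`.
MOTIF_PERIOD <- 4L
MOTIF_GAIN <- 2

clip_scores <- function(m) {
  m <- round(m)
  m[m < PSSM_SCORE_MIN] <- PSSM_SCORE_MIN
  m[m > PSSM_SCORE_MAX] <- PSSM_SCORE_MAX
  storage.mode(m) <- "integer"
  m
}

# Replicate-padded moving-average smoothing with a (2r+1)^2 window; used by
# the "smooth" regime to suppress local gradients.
smooth_field <- function(m, r = 2L) {
  L <- nrow(m); W <- ncol(m)
  pad <- m[pmin(pmax(seq(1 - r, L + r), 1), L),
           pmin(pmax(seq(1 - r, W + r), 1), W), drop = FALSE]
  out <- matrix(0, L, W)
  for (dr in -r:r) {
    for (dc in -r:r) {
      out <- out + pad[seq_len(L) + r + dr, seq_len(W) + r + dc, drop = FALSE]
    }
  }
  out / (2 * r + 1)^2
}

stripe_field <- function(L, width = 20L, amplitude) {
  phase <- ((seq_len(L) - 1L) %% MOTIF_PERIOD) < (MOTIF_PERIOD %/% 2L)
  matrix(ifelse(phase, amplitude, -amplitude), L, width)
}

synth_scores <- function(length, texture, amplitude) {
  raw <- matrix(rnorm(length * 20), length, 20)
  field <- switch(texture,
    rough = amplitude * raw,
    smooth = {
      sm <- smooth_field(raw)
      # rescale so the marginal spread matches the rough regime at equal
      # amplitude; only the local gradients differ
      s <- stats::sd(as.vector(sm))
      if (s > 0) sm <- sm / s
      amplitude * sm
    },
    motif = amplitude * raw / 4 +
      stripe_field(length, 20L, MOTIF_GAIN * amplitude),
    abort(sprintf("unknown texture '%s'", texture),
          class = "ppidvm_error_domain")
  )
  clip_scores(field)
}

#' Generate a synthetic PSSM
#'
#' Draws an integer score matrix with PSI-BLAST-like magnitudes under one of
#' three texture regimes: `"smooth"` (spatially correlated scores, low local
#' gradients), `"rough"` (i.i.d. noise, high local gradients) or `"motif"`
#' (a periodic row stripe over mild noise).  The regimes produce
#' distinguishable IWLD histograms, which makes them useful for exercising
#' the full pipeline without real profile searches.
#'
#' @param length Number of sequence positions (rows), at least 2.
#' @param seed Integer seed; output is deterministic in
#'   `(length, seed, texture, amplitude)`.
#' @param texture One of `"rough"`, `"smooth"`, `"motif"`.
#' @param amplitude Nonnegative noise scale in score units; 0 yields a
#'   constant matrix for `"smooth"` and `"rough"`.
#' @param protein_id Identifier for the generated protein.
#'
#' @return A [pssm()] object.
#' @examples
#' p <- synth_pssm(50, seed = 1, texture = "rough", amplitude = 5)
#' range(p$scores)
#' @export
synth_pssm <- function(length, seed,
                       texture = c("rough", "smooth", "motif"),
                       amplitude = SYNTH_NOISE_SD,
                       protein_id = sprintf("synth_%s_%d", texture[1], seed)) {
  texture <- match.arg(texture)
  if (length < 2) {
    abort("synthetic PSSM length must be >= 2", class = "ppidvm_error_domain")
  }
  if (amplitude < 0) {
    abort("amplitude must be >= 0", class = "ppidvm_error_domain")
  }
  scores <- withr::with_seed(seed, synth_scores(length, texture, amplitude))
  pssm(scores, protein_id = protein_id)
}

#' Generate a labelled synthetic protein-pair dataset
#'
#' Emits `n_pairs` protein pairs (half interacting, half not) together with
#' one synthetic PSSM per protein.  All proteins carry i.i.d. background
#' score noise; proteins of the "signal" regime additionally carry a
#' periodic row stripe whose amplitude scales with `effect`.  Interacting
#' pairs join two signal-regime proteins; non-interacting pairs join one
#' signal and one background protein in random order.  At `effect = 0` the
#' regimes coincide and labels are independent of the features, so any
#' classifier is reduced to chance.
#'
#' @param n_pairs Even number of pairs to generate.
#' @param length_range Length-2 integer vector; protein lengths are drawn
#'   uniformly from this range.
#' @param effect Nonnegative class-separation scale (stripe amplitude is
#'   `2 * effect` score units).
#' @param seed Integer seed; the dataset is bit-reproducible given
#'   `(n_pairs, length_range, effect, seed)`.
#'
#' @return A list with `pssms` (named list of [pssm()] objects) and `pairs`
#'   (tibble `id_a`, `id_b`, `label` with exactly `n_pairs / 2` records per
#'   class).
#' @examples
#' d <- synth_pair_dataset(10, effect = 2, seed = 1)
#' table(d$pairs$label)
#' @export
synth_pair_dataset <- function(n_pairs, length_range = c(30L, 80L),
                               effect = 1, seed = 1) {
  if (n_pairs %% 2 != 0 || n_pairs < 2) {
    abort("n_pairs must be a positive even number",
          class = "ppidvm_error_domain")
  }
  if (effect < 0) {
    abort("effect must be >= 0", class = "ppidvm_error_domain")
  }
  n_pos <- n_pairs %/% 2L
  withr::with_seed(seed, {
    n_prot <- 2L * n_pairs
    lens <- sample(seq(length_range[1], length_range[2]), n_prot,
                   replace = TRUE)
    # protein regimes: positives use proteins 1..2*n_pos (all signal);
    # each negative pair gets one signal and one background protein,
    # shuffled within the pair
    ids <- sprintf("P%04d", seq_len(n_prot))
    regime <- c(rep(TRUE, 2L * n_pos),
                as.vector(vapply(seq_len(n_pairs - n_pos),
                                 function(i) sample(c(TRUE, FALSE)),
                                 logical(2))))
    pssms <- lapply(seq_len(n_prot), function(i) {
      base <- matrix(rnorm(lens[i] * 20, sd = SYNTH_NOISE_SD), lens[i], 20)
      if (regime[i]) {
        base <- base + stripe_field(lens[i], 20L, MOTIF_GAIN * effect)
      }
      pssm(clip_scores(base), protein_id = ids[i])
    })
    names(pssms) <- ids
    pairs <- tibble::tibble(
      id_a = ids[seq(1L, n_prot, by = 2L)],
      id_b = ids[seq(2L, n_prot, by = 2L)],
      label = rep(c(1L, 0L), c(n_pos, n_pairs - n_pos))
    )
    list(pssms = pssms, pairs = pairs)
  })
}
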