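# Synthetic-data module: generates every input the pipeline consumes with
# known ground truth -- biased module frequencies, per-brain cluster tables,
# bleed-through mixing matrices, and labeled multichannel volumes with
# traces. Every generator is a pure function of its seed and configuration.

#' Generate per-module recombination frequencies
#'
#' The `"bitbow-like"` preset emulates the recombination bias seen with
#' heat-shock induction: the mNeonGreen module (slot G, driven by the most
#' recombinogenic FRT) is the most frequently ON, followed by mAmetrine (A)
#' and tdKatushka2 (K), with mTFP1 (T) and mKO2 (O) similarly lowest. A
#' small seeded jitter decorrelates compartment groups without disturbing
#' that ordering.
#'
#' @param n_bits Total bit count, a multiple of 5 (5, 10, or 15).
#' @param preset Currently `"bitbow-like"`.
#' @param values Optional explicit frequency vector (length `n_bits`),
#'   passed through unchanged.
#' @param jitter Half-width of the uniform jitter (default 0.02).
#' @param seed RNG seed (required for reproducibility).
#' @return A tibble with columns `slot`, `compartment`, `fluorophore`,
#'   `frequency`.
#' @export
gen_module_frequencies <- function(n_bits = 5L, preset = "bitbow-like",
                                   values = NULL, jitter = 0.02, seed = 1L) {
  if (!is.null(values)) {
    p <- module_probs(values)
    if (length(p) != n_bits) stop("`values` must have length `n_bits`", call. = FALSE)
  } else {
    preset <- match.arg(preset, "bitbow-like")
    if (n_bits %% 5L != 0L) stop("preset frequencies require a multiple of 5 bits", call. = FALSE)
    base <- c(A = 0.35, T = 0.12, G = 0.55, O = 0.10, K = 0.25)
    set.seed(seed)
    p <- rep(unname(base), n_bits %/% 5L) + runif(n_bits, -jitter, jitter)
    p <- pmin(pmax(p, 0.02), 0.98)
  }
  tibble::tibble(
    slot = slot_labels(n_bits),
    compartment = slot_compartments(n_bits),
    fluorophore = slot_fluorophores(n_bits),
    frequency = p
  )
}

#' Generate a per-brain cluster table with ground truth
#'
#' Emulates a larval heat-shock lineage-labeling experiment: in each brain,
#' every lineage independently activates (its neuroblast recombines) with
#' `activation_rate`; an activated lineage becomes one labeled cluster
#' carrying a single code drawn from the induced code distribution.
#'
#' @param freqs Module frequencies (vector or table); the code distribution
#'   is `build_code_distribution(freqs)`.
#' @param brains Number of brains (default 6).
#' @param lineages_per_brain Lineages per brain (default 200).
#' @param activation_rate Per-lineage labeling probability (default 0.4808,
#'   the estimated lineage labeling rate).
#' @param seed RNG seed.
#' @return A cluster table tibble (`brain_id`, `cluster_id`, `code`) with
#'   the hidden lineage truth attached as attribute `truth` (tibble:
#'   `brain_id`, `lineage`, `labeled`, `code`).
#' @export
gen_cluster_table <- function(freqs, brains = 6L, lineages_per_brain = 200L,
                              activation_rate = 0.4808, seed = 1L) {
  stopifnot(brains >= 1, lineages_per_brain >= 1,
            activation_rate >= 0, activation_rate <= 1)
  dist <- build_code_distribution(freqs)
  set.seed(seed)
  truth <- lapply(seq_len(brains), function(b) {
    labeled <- runif(lineages_per_brain) < activation_rate
    code <- rep(NA_character_, lineages_per_brain)
    code[labeled] <- sample_codes(dist, sum(labeled))
    tibble::tibble(
      brain_id = sprintf("brain%02d", b),
      lineage = seq_len(lineages_per_brain),
      labeled = labeled,
      code = code
    )
  })
  truth <- dplyr::bind_rows(truth)
  clusters <- truth |>
    dplyr::filter(.data$labeled) |>
    dplyr::group_by(.data$brain_id) |>
    dplyr::mutate(cluster_id = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select("brain_id", "cluster_id", "code")
  attr(clusters, "truth") <- truth
  attr(clusters, "distribution") <- dist
  clusters
}

#' Generate a spectral mixing matrix with bleed-through
#'
#' A diagonal-dominant reference matrix: each fluorophore puts `1 - bleed`
#' of its signal into its primary detection channel and spreads the
#' remaining `bleed` over the other channels with exponentially decaying
#' weight by channel distance. Columns are unit-sum; with `bleed = 0` and
#' `C = 5` the matrix is the identity.
#'
#' @param C Number of detection channels (>= 5).
#' @param bleed Off-target signal fraction, in `[0, 1)`.
#' @param spread Decay length (in channels) of the bleed-through.
#' @return A C x 5 mixing matrix with fluorophore column names and condition
#'   number attribute `kappa`.
#' @export
gen_mixing_matrix <- function(C = 5L, bleed = 0, spread = 1) {
  stopifnot(C >= 5, bleed >= 0, bleed < 1)
  n_fp <- 5L
  targets <- ceiling((seq_len(n_fp) - 0.5) * C / n_fp)
  M <- matrix(0, C, n_fp)
  for (f in seq_len(n_fp)) {
    M[targets[f], f] <- 1 - bleed
    if (bleed > 0) {
      off <- setdiff(seq_len(C), targets[f])
      w <- exp(-abs(off - targets[f]) / spread)
      M[off, f] <- bleed * w / sum(w)
    }
  }
  colnames(M) <- names(BITBOW_FPS)
  validate_mixing_matrix(M)
}

#' Generate a labeled multichannel volume with traces and ground truth
#'
#' Renders simple neuron proxies -- a spherical soma and a straight tubular
#' neurite per cell, laid out on a grid -- whose channel intensities follow
#' the spectral forward model of each cell's code: ON bits carry a per-cell
#' log-normal amplitude (expression level varies between cells; amplitude
#' variation must not change the called code), OFF bits are dark, the
#' fluorophore abundances are mixed through the mixing matrix, and Gaussian
#' detection noise is added everywhere (negative values clipped at zero).
#' Geometry is deliberately minimal: enough to exercise the 3x3x3 median and
#' the path smoothing, with no attempt at realistic neuroanatomy.
#'
#' @param n_cells Number of cells (default 200).
#' @param freqs Module frequencies for the 5-bit code distribution the cell
#'   codes are drawn from (default: the `"bitbow-like"` preset).
#' @param mixing Mixing matrix (C x 5); default `gen_mixing_matrix(5, bleed)`.
#' @param bleed Bleed-through used when `mixing` is not supplied.
#' @param noise_sd Gaussian noise SD in raw intensity units; the mean ON
#'   amplitude is ~1, so 0.05 is "5% of signal".
#' @param amp_meanlog,amp_sdlog Log-normal parameters of the per-cell,
#'   per-bit ON amplitude.
#' @param cell_box Per-cell bounding box in voxels `(x, y, z)`.
#' @param seed RNG seed; identical seeds give identical volumes and traces.
#' @return A list: `volume` (X x Y x Z x C array), `traces` (named list of
#'   SWC data frames, soma node type 1 first, neurite type 3), `truth`
#'   (tibble: `cell`, `code`), `mixing`, and `freqs`.
#' @export
gen_labeled_volume <- function(n_cells = 200L, freqs = NULL, mixing = NULL,
                               bleed = 0, noise_sd = 0.05,
                               amp_meanlog = 0, amp_sdlog = 0.3,
                               cell_box = c(16L, 12L, 9L), seed = 1L) {
  stopifnot(n_cells >= 1, noise_sd >= 0)
  if (is.null(freqs)) freqs <- gen_module_frequencies(5L, seed = seed)
  if (is.null(mixing)) mixing <- gen_mixing_matrix(5L, bleed = bleed)
  mixing <- validate_mixing_matrix(mixing)
  n_ch <- nrow(mixing)
  bx <- cell_box[1]; by <- cell_box[2]; bz <- cell_box[3]
  if (bx < 12 || by < 7 || bz < 7) {
    stop("cell_box too small to hold a soma and neurite with a clear margin", call. = FALSE)
  }
  dist <- build_code_distribution(freqs)
  set.seed(seed)
  codes <- sample_codes(dist, n_cells)
  bits <- codes_to_matrix(codes)
  amps <- matrix(rlnorm(n_cells * 5L, amp_meanlog, amp_sdlog), n_cells, 5L) * bits

  nx <- ceiling(sqrt(n_cells))
  ny <- ceiling(n_cells / nx)
  X <- nx * bx; Y <- ny * by; Z <- bz
  abundance <- array(0, dim = c(X, Y, Z, 5L))
  traces <- vector("list", n_cells)
  soma_r <- 2.2
  zc <- ceiling(Z / 2)
  for (ci in seq_len(n_cells)) {
    gx <- (ci - 1L) %% nx
    gy <- (ci - 1L) %/% nx
    ox <- gx * bx; oy <- gy * by
    sx <- ox + 4L; sy <- oy + ceiling(by / 2); sz <- zc
    # soma: voxels within soma_r of the center
    rr <- ceiling(soma_r)
    for (dx in -rr:rr) for (dy in -rr:rr) for (dz in -rr:rr) {
      if (dx^2 + dy^2 + dz^2 <= soma_r^2) {
        abundance[sx + dx, sy + dy, sz + dz, ] <- amps[ci, ]
      }
    }
    # neurite: straight tube along +x, cross-section radius 1
    xs <- (sx + 3L):(ox + bx - 2L)
    for (x in xs) {
      abundance[x, sy, sz, ] <- amps[ci, ]
      abundance[x, sy - 1L, sz, ] <- amps[ci, ]
      abundance[x, sy + 1L, sz, ] <- amps[ci, ]
      abundance[x, sy, sz - 1L, ] <- amps[ci, ]
      abundance[x, sy, sz + 1L, ] <- amps[ci, ]
    }
    n_neur <- length(xs)
    traces[[ci]] <- data.frame(
      id = seq_len(1L + n_neur),
      type = c(1L, rep(3L, n_neur)),
      x = c(sx, xs), y = sy, z = sz,
      radius = c(soma_r, rep(1, n_neur)),
      parent = c(-1L, seq_len(n_neur))
    )
  }
  names(traces) <- sprintf("cell%03d", seq_len(n_cells))

  A <- matrix(abundance, ncol = 5L)
  raw <- A %*% t(mixing)
  if (noise_sd > 0) raw <- raw + rnorm(length(raw), 0, noise_sd)
  raw[raw < 0] <- 0
  volume <- array(raw, dim = c(X, Y, Z, n_ch))

  list(
    volume = volume,
    traces = traces,
    truth = tibble::tibble(cell = names(traces), code = codes),
    mixing = mixing,
    freqs = freqs
  )
}
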