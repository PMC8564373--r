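# Color calling: from multichannel microscopy intensities to binary codes.
# The chain is unmix (against single-fluorophore reference spectra) ->
# smooth (3x3x3 median, then 10-sample rolling mean along the trace) ->
# sum-normalize per node -> aggregate per cell -> threshold per channel.

#' Validate and column-normalize a spectral mixing matrix
#'
#' Reference spectra measured from cells expressing one fluorophore at a
#' time: rows are detection channels (C >= number of fluorophores), columns
#' are fluorophores. Entries must be nonnegative, no column all zero, and
#' the matrix must have full column rank; columns are scaled to unit sum so
#' fluorophore abundances are comparable.
#'
#' @param M Numeric matrix, channels x fluorophores.
#' @return The column-normalized matrix, with the condition number as
#'   attribute `kappa`.
#' @export
validate_mixing_matrix <- function(M) {
  M <- as.matrix(M)
  if (!is.numeric(M) || anyNA(M)) stop("mixing matrix must be numeric", call. = FALSE)
  if (any(M < 0)) stop("mixing matrix entries must be nonnegative", call. = FALSE)
  cs <- colSums(M)
  if (any(cs == 0)) stop("mixing matrix has an all-zero fluorophore column", call. = FALSE)
  if (nrow(M) < ncol(M)) {
    stop("mixing matrix needs at least as many channels as fluorophores", call. = FALSE)
  }
  M <- sweep(M, 2, cs, "/")
  if (qr(M)$rank < ncol(M)) {
    stop(sprintf("mixing matrix is rank-deficient (condition number %.3g): reference spectra are collinear",
                 kappa(M)), call. = FALSE)
  }
  attr(M, "kappa") <- kappa(M)
  M
}

#' Linear spectral unmixing
#'
#' Recovers per-pixel fluorophore abundances `a` from detection-channel
#' intensities `y` by solving `M a ~ y` in the least-squares sense. The
#' default solver constrains abundances to be nonnegative (they are
#' physical); a plain least-squares solution with negative values clamped to
#' zero is available via `method = "ls"`. Noiseless mixtures are recovered
#' exactly when `M` has full column rank.
#'
#' @param y Channel intensities: a length-C vector or an n x C matrix (one
#'   pixel per row).
#' @param M Mixing matrix (C channels x F fluorophores); validated and
#'   column-normalized via [validate_mixing_matrix()].
#' @param method `"nnls"` (nonnegative least squares, default) or `"ls"`
#'   (unconstrained fit, negatives clamped).
#' @return Abundances in the same shape as the input: a length-F vector or
#'   an n x F matrix.
#' @examples
#' M <- diag(5)
#' unmix(c(2, 1, 0, 0, 0), M)
#' @export
unmix <- function(y, M, method = c("nnls", "ls")) {
  method <- match.arg(method)
  M <- validate_mixing_matrix(M)
  vec <- is.null(dim(y))
  Y <- if (vec) matrix(y, nrow = 1) else as.matrix(y)
  if (ncol(Y) != nrow(M)) {
    stop(sprintf("pixel vectors have %d channels but the mixing matrix has %d rows",
                 ncol(Y), nrow(M)), call. = FALSE)
  }
  qrM <- qr(M)
  A <- t(qr.coef(qrM, t(Y)))
  if (method == "nnls") {
    # Unconstrained and nonnegative solutions coincide when the former is
    # already nonnegative; solve the active-set problem only where needed.
    redo <- which(rowSums(A < -1e-10) > 0)
    for (i in redo) A[i, ] <- pracma::lsqnonneg(M, Y[i, ])$x
  }
  A[A < 0] <- 0
  colnames(A) <- colnames(M)
  if (vec) drop(A) else A
}

#' Smooth intensities along a neuron trace
#'
#' Two-step noise reduction used before color calling: (1) per node and
#' channel, the median over the 3x3x3 voxel neighborhood of the node (when
#' an image volume is supplied), or a running median of 3 along the trace
#' otherwise; (2) a centered rolling mean of `roll_window` samples along
#' trace order, with the window clipped (shrunk) at the ends so output
#' length equals input length. Both steps keep every output value inside the
#' range of its inputs, so smoothing never widens a channel's range.
#'
#' @param intensities Node intensities, an n_nodes x F matrix (ignored for
#'   the median step when `volume` is given, but defines F and n_nodes when
#'   it is not).
#' @param coords Optional n_nodes x 3 integer matrix of voxel coordinates
#'   (x, y, z), required with `volume`.
#' @param volume Optional X x Y x Z x F array of (already unmixed) channel
#'   intensities from which node neighborhoods are read.
#' @param roll_window Rolling-mean window in samples (default 10).
#' @return Smoothed n_nodes x F matrix.
#' @export
smooth_trace <- function(intensities = NULL, coords = NULL, volume = NULL,
                         roll_window = 10L) {
  if (!is.null(volume)) {
    if (is.null(coords)) stop("`coords` are required with a volume", call. = FALSE)
    med <- neighborhood_medians(volume, coords)
  } else {
    if (is.null(intensities)) stop("supply `intensities` or a volume", call. = FALSE)
    med <- as.matrix(intensities)
    if (nrow(med) >= 3) {
      med <- apply(med, 2, function(x) runmed(x, 3, endrule = "keep"))
    }
  }
  apply(med, 2, roll_mean_clipped, w = roll_window)
}

# Median over the 3x3x3 neighborhood of each node, clipped at the volume
# faces. Errors (naming the node) if a node lies outside the volume.
neighborhood_medians <- function(volume, coords) {
  dims <- dim(volume)
  if (length(dims) != 4) stop("volume must be an X x Y x Z x F array", call. = FALSE)
  coords <- matrix(as.integer(round(as.matrix(coords))), ncol = 3)
  inside <- coords[, 1] >= 1 & coords[, 1] <= dims[1] &
    coords[, 2] >= 1 & coords[, 2] <= dims[2] &
    coords[, 3] >= 1 & coords[, 3] <= dims[3]
  if (!all(inside)) {
    stop(sprintf("trace node %d lies outside the image volume", which(!inside)[1]),
         call. = FALSE)
  }
  nf <- dims[4]
  out <- matrix(0, nrow(coords), nf)
  for (i in seq_len(nrow(coords))) {
    xs <- max(1L, coords[i, 1] - 1L):min(dims[1], coords[i, 1] + 1L)
    ys <- max(1L, coords[i, 2] - 1L):min(dims[2], coords[i, 2] + 1L)
    zs <- max(1L, coords[i, 3] - 1L):min(dims[3], coords[i, 3] + 1L)
    for (f in seq_len(nf)) {
      out[i, f] <- median(volume[xs, ys, zs, f])
    }
  }
  out
}

# Centered rolling mean with the window clipped to the series at the ends;
# cumsum-based, O(n). For an even window the extra sample trails the center.
roll_mean_clipped <- function(x, w) {
  n <- length(x)
  if (n == 0 || w <= 1) return(x)
  lo_off <- floor((w - 1) / 2)
  hi_off <- ceiling((w - 1) / 2)
  i <- seq_len(n)
  lo <- pmax(1L, i - lo_off)
  hi <- pmin(n, i + hi_off)
  cs <- c(0, cumsum(x))
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Sum-normalize channel intensities
#'
#' Scales each pixel's channel vector to unit sum, bringing brighter and
#' dimmer pixels to the same color scale. Pixels whose summed intensity
#' falls below the background floor `eps` are flagged as background (all
#' `NA` in the output, with a logical `background` attribute).
#'
#' @param v A channel vector or an n x F matrix of pixel intensities, all
#'   nonnegative.
#' @param eps Background floor on the channel sum. In the volume pipeline
#'   the default is 1% of the 99th percentile of summed intensities; for a
#'   bare call it is a tiny positive value that only flags exact zeros.
#' @return Normalized values in the input's shape; background pixels are
#'   `NA` and marked in `attr(, "background")`.
#' @examples
#' normalize_channels(c(2, 1, 1, 0, 0))
#' @export
normalize_channels <- function(v, eps = 1e-12) {
  vec <- is.null(dim(v))
  V <- if (vec) matrix(v, nrow = 1) else as.matrix(v)
  if (anyNA(V) || any(V < 0)) {
    stop("channel intensities must be nonnegative and non-missing", call. = FALSE)
  }
  s <- rowSums(V)
  bg <- s < max(eps, .Machine$double.xmin)
  out <- V / s
  out[bg, ] <- NA_real_
  attr(out, "background") <- bg
  if (vec) {
    res <- drop(out)
    attr(res, "background") <- bg[1]
    res
  } else {
    out
  }
}

#' Aggregate a cell's pixels to one color vector
#'
#' Median (default; robust to soma/neurite brightness gradients) or mean of
#' the normalized channel vectors over a cell's non-background pixels.
#'
#' @param pixels n x F matrix of normalized pixel vectors; background rows
#'   (`NA`) are dropped.
#' @param method `"median"` (default) or `"mean"`.
#' @return Length-F aggregate vector.
#' @export
aggregate_cell <- function(pixels, method = c("median", "mean")) {
  method <- match.arg(method)
  P <- as.matrix(pixels)
  keep <- stats::complete.cases(P)
  if (!any(keep)) {
    stop("all pixels are background: cell appears unlabeled", call. = FALSE)
  }
  P <- P[keep, , drop = FALSE]
  apply(P, 2, if (method == "median") median else mean)
}

#' Otsu threshold for a numeric sample
#'
#' Histogram-based two-class separation: picks the cut maximizing the
#' between-class variance. Returns `NA` for a degenerate (constant) sample.
#'
#' @param x Numeric values.
#' @param n_bins Histogram resolution (default 256).
#' @return Threshold value, or `NA` if no split exists.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(NA_real_)
  rng <- range(x)
  if (diff(rng) == 0) return(NA_real_)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, edges, rightmost.closed = TRUE), nbins = n_bins)
  w <- h / sum(h)
  mids <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  w0 <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[n_bins]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  k <- which.max(between[-n_bins])
  edges[k + 1L]
}

#' Call binary bits from aggregated cell colors
#'
#' A channel's bit is ON when the cell's aggregated normalized intensity
#' meets or exceeds the channel threshold (ties count as ON). Thresholds are
#' either fixed per channel, or fitted automatically: Otsu's two-class
#' separation per channel across all cells, computed on log10-transformed
#' shares (with a 1% pseudocount) because ON shares are right-skewed while
#' OFF shares cluster near zero, and falling back to the configured fixed
#' threshold when a channel does not show two separated populations
#' (degenerate split, a class smaller than 2% of cells, or class means
#' closer than four pooled within-class SDs -- tail cuts of a unimodal
#' sample reach about three).
#'
#' @param aggregates A cells x F matrix of aggregated normalized intensities
#'   (or a single length-F vector).
#' @param thresholds `"auto"` (default) or a numeric threshold, scalar or
#'   per channel.
#' @param fallback Fixed threshold used where auto-thresholding declines
#'   (default 0.1).
#' @return A `bit_calls` list: `code` (character vector of code strings),
#'   `bits` (0/1 matrix), `thresholds` (per channel, with an `auto` logical
#'   attribute), and `margins` (|aggregate - threshold|, a confidence
#'   measure per cell and channel).
#' @examples
#' call_bits(c(0.5, 0.45, 0.02, 0.02, 0.01), thresholds = 0.1)$code
#' @export
call_bits <- function(aggregates, thresholds = "auto", fallback = 0.1) {
  A <- if (is.null(dim(aggregates))) matrix(aggregates, nrow = 1) else as.matrix(aggregates)
  nf <- ncol(A)
  auto <- identical(thresholds, "auto")
  if (auto) {
    if (nrow(A) < 2) {
      th <- rep(fallback, nf)
    } else {
      th <- vapply(seq_len(nf), function(f) auto_channel_threshold(A[, f], fallback),
                   numeric(1))
    }
  } else {
    th <- rep_len(as.numeric(thresholds), nf)
  }
  bits <- matrix(as.integer(sweep(A, 2, th, ">=")), nrow = nrow(A))
  group <- if (nf %% 5L == 0L) 5L else nf
  structure(
    list(
      code = bits_to_string(bits, group_size = group),
      bits = bits,
      thresholds = structure(th, auto = auto),
      margins = abs(sweep(A, 2, th, "-"))
    ),
    class = "bit_calls"
  )
}

# Otsu with a unimodality guard, applied in the log domain. Normalized ON
# shares are broad and right-skewed (they depend on how many other bits are
# ON and on expression level) while OFF shares cluster near zero; a log10
# transform with a 1% pseudocount compresses the ON spread so the
# between-class cut lands in the OFF/ON gap. The fitted cut is kept only
# when it separates two substantial, well-spaced classes; otherwise the
# fixed fallback is used.
auto_channel_threshold <- function(x, fallback, min_class_frac = 0.02,
                                   min_separation = 4, pseudocount = 0.01) {
  lx <- log10(x + pseudocount)
  th_l <- otsu_threshold(lx)
  if (is.na(th_l)) return(fallback)
  lo <- lx[lx < th_l]
  hi <- lx[lx >= th_l]
  if (length(lo) < 1 || length(hi) < 1) return(fallback)
  if (min(length(lo), length(hi)) / length(lx) < min_class_frac) return(fallback)
  pooled_sd <- sqrt((sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)) /
                      max(1, length(lx) - 2))
  if ((mean(hi) - mean(lo)) < min_separation * max(pooled_sd, 1e-12)) return(fallback)
  10^th_l - pseudocount
}

#' Soma/neurite labeling-consistency statistics
#'
#' Compares the color of a neuron's soma against its neurites: per channel,
#' the absolute difference of the median normalized intensities, and a
#' scalar consistency distance (the maximum over channels). Small distances
#' mean the code read at the soma transfers to the processes.
#'
#' @param soma,neurite Matrices of normalized pixel vectors (n x F), both
#'   nonempty.
#' @return List with `per_channel` (absolute median differences) and
#'   `distance` (their maximum).
#' @export
consistency_stats <- function(soma, neurite) {
  S <- as.matrix(soma)
  N <- as.matrix(neurite)
  if (nrow(S) == 0 || nrow(N) == 0) {
    stop("soma and neurite series must both be nonempty", call. = FALSE)
  }
  if (ncol(S) != ncol(N)) stop("channel counts differ", call. = FALSE)
  d <- abs(apply(S, 2, median, na.rm = TRUE) - apply(N, 2, median, na.rm = TRUE))
  list(per_channel = d, distance = max(d))
}

#' Nearest-centroid assignment of neurites to somas
#'
#' Assigns each cell's neurite color (median normalized vector) to the
#' nearest soma color centroid among all cells (Euclidean distance) and
#' reports the fraction assigned back to their own soma -- a population-level
#' consistency check.
#'
#' @param cells A list, one element per cell, each a list with `soma` and
#'   `neurite` pixel matrices (normalized, n x F).
#' @return List with `assigned` (index of the chosen soma per cell) and
#'   `accuracy` (fraction of self-assignments).
#' @export
neurite_assignment <- function(cells) {
  stopifnot(length(cells) >= 1)
  centroids <- t(vapply(cells, function(cl) apply(as.matrix(cl$soma), 2, median, na.rm = TRUE),
                        numeric(ncol(as.matrix(cells[[1]]$soma)))))
  assigned <- vapply(cells, function(cl) {
    v <- apply(as.matrix(cl$neurite), 2, median, na.rm = TRUE)
    which.min(colSums((t(centroids) - v)^2))
  }, integer(1))
  list(assigned = assigned, accuracy = mean(assigned == seq_along(cells)))
}

#' Call codes for traced cells from a raw image volume
#'
#' The full color-calling chain for a set of traced neurons in one
#' multichannel volume: per trace node, the raw C-channel intensities in the
#' node's 3x3x3 neighborhood are spectrally unmixed against the mixing
#' matrix, reduced to a per-node median, smoothed with a rolling mean along
#' the trace, sum-normalized, and aggregated to a per-cell color whose bits
#' are then thresholded.
#'
#' @param volume Raw X x Y x Z x C array.
#' @param traces A list of SWC-style data frames (columns `x`, `y`, `z` in
#'   voxel units, plus `type`), one per cell, in trace order.
#' @param mixing Mixing matrix (C x F); `NULL` if the volume is already
#'   unmixed (then C must equal F).
#' @param thresholds,fallback Passed to [call_bits()].
#' @param roll_window Rolling-mean window (default 10).
#' @param eps Background floor for [normalize_channels()]; default 1% of
#'   the 99th percentile of the summed node intensities.
#' @param method Unmixing solver, see [unmix()].
#' @return A tibble with one row per cell: `cell`, `code`, `n_nodes`, and
#'   `margin` (the smallest per-channel confidence margin). Aggregates and
#'   thresholds are attached as attributes.
#' @export
call_codes_from_volume <- function(volume, traces, mixing = NULL,
                                   thresholds = "auto", fallback = 0.1,
                                   roll_window = 10L, eps = NULL,
                                   method = "nnls") {
  stopifnot(length(dim(volume)) == 4, length(traces) >= 1)
  dims <- dim(volume)
  n_ch <- dims[4]

  # Gather the 3x3x3 neighborhoods of every node across all traces, dedup
  # shared voxels, and unmix each voxel once.
  node_tab <- lapply(traces, function(tr) {
    m <- matrix(as.integer(round(cbind(tr$x, tr$y, tr$z))), ncol = 3)
    inside <- m[, 1] >= 1 & m[, 1] <= dims[1] & m[, 2] >= 1 & m[, 2] <= dims[2] &
      m[, 3] >= 1 & m[, 3] <= dims[3]
    if (!all(inside)) {
      stop(sprintf("trace node %d lies outside the image volume", which(!inside)[1]),
           call. = FALSE)
    }
    m
  })
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  all_nodes <- do.call(rbind, node_tab)
  nb <- all_nodes[rep(seq_len(nrow(all_nodes)), each = 27L), ] +
    offsets[rep(seq_len(27L), times = nrow(all_nodes)), ]
  nb[, 1] <- pmin(pmax(nb[, 1], 1L), dims[1])
  nb[, 2] <- pmin(pmax(nb[, 2], 1L), dims[2])
  nb[, 3] <- pmin(pmax(nb[, 3], 1L), dims[3])
  lin <- (nb[, 3] - 1L) * dims[1] * dims[2] + (nb[, 2] - 1L) * dims[1] + nb[, 1]
  uniq <- unique(lin)
  raw <- matrix(0, length(uniq), n_ch)
  plane <- dims[1] * dims[2] * dims[3]
  for (ch in seq_len(n_ch)) raw[, ch] <- volume[uniq + (ch - 1) * plane]
  un <- if (is.null(mixing)) raw else unmix(raw, mixing, method = method)
  n_fp <- ncol(un)
  vox_row <- match(lin, uniq)

  # Per-node medians over each 27-voxel neighborhood, then per-trace
  # smoothing, normalization, and aggregation.
  node_med <- matrix(0, nrow(all_nodes), n_fp)
  idx0 <- (seq_len(nrow(all_nodes)) - 1L) * 27L
  for (i in seq_len(nrow(all_nodes))) {
    rows <- vox_row[idx0[i] + seq_len(27L)]
    for (f in seq_len(n_fp)) node_med[i, f] <- median(un[rows, f])
  }
  if (is.null(eps)) {
    s <- rowSums(node_med)
    eps <- 0.01 * as.numeric(stats::quantile(s, 0.99))
  }

  counts <- vapply(node_tab, nrow, integer(1))
  ends <- cumsum(counts)
  starts <- ends - counts + 1L
  cell_names <- if (!is.null(names(traces))) names(traces) else
    paste0("cell", seq_along(traces))
  aggregates <- matrix(NA_real_, length(traces), n_fp)
  for (ci in seq_along(traces)) {
    sm <- apply(node_med[starts[ci]:ends[ci], , drop = FALSE], 2,
                roll_mean_clipped, w = roll_window)
    if (is.null(dim(sm))) sm <- matrix(sm, nrow = 1)
    nm <- normalize_channels(sm, eps = eps)
    aggregates[ci, ] <- aggregate_cell(nm)
  }
  calls <- call_bits(aggregates, thresholds = thresholds, fallback = fallback)
  out <- tibble::tibble(
    cell = cell_names,
    code = calls$code,
    n_nodes = counts,
    margin = apply(calls$margins, 1, min)
  )
  attr(out, "aggregates") <- aggregates
  attr(out, "thresholds") <- calls$thresholds
  out
}
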