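#' Build the probability distribution over all nonzero codes
#'
#' Each module recombines ON independently with its own probability `p_i`,
#' so an unconditioned cell displays bit pattern `x` with probability
#' `prod(p_i^x_i (1-p_i)^(1-x_i))`. Unlabeled (all-zero) cells are invisible
#' in imaging, so the all-zero outcome is excluded and the remaining mass
#' renormalized over the `2^N - 1` nonzero codes.
#'
#' @param freqs Per-module ON probabilities: a numeric vector in bit order,
#'   or a module frequency table (tibble with a `frequency` column, as
#'   returned by [gen_module_frequencies()] or [read_module_frequencies()]).
#' @param conditional_marginals If `TRUE`, `freqs` are interpreted as
#'   observed per-slot ON fractions among labeled cells (which condition on
#'   "at least one bit ON") and are first inverted with
#'   [decondition_marginals()]. Default `FALSE`: frequencies are taken as
#'   unconditional recombination probabilities.
#' @return A `code_distribution`: a tibble with columns `code` (grouped 0/1
#'   string, lexicographic order) and `prob`, carrying the module
#'   probabilities and bit count as attributes. Probabilities sum to 1.
#' @examples
#' d <- build_code_distribution(rep(0.5, 5))
#' all.equal(d$prob, rep(1 / 31, 31))
#' @export
build_code_distribution <- function(freqs, conditional_marginals = FALSE) {
  p <- module_probs(freqs)
  if (conditional_marginals) p <- decondition_marginals(p)
  if (all(p == 0)) {
    stop("degenerate distribution: all module probabilities are zero", call. = FALSE)
  }
  n_bits <- length(p)
  bits <- enumerate_codes(n_bits)
  pr <- rep(1, nrow(bits))
  for (j in seq_len(n_bits)) {
    pr <- pr * ifelse(bits[, j] == 1L, p[j], 1 - p[j])
  }
  z <- sum(pr) # equals 1 - prod(1 - p): mass of "at least one bit ON"
  if (z <= 0) {
    stop("degenerate distribution: zero probability of labeling", call. = FALSE)
  }
  group <- if (n_bits %% 5L == 0L) 5L else n_bits
  new_code_distribution(
    code = bits_to_string(bits, group_size = group),
    prob = pr / z,
    n_bits = n_bits,
    module_probs = p
  )
}

new_code_distribution <- function(code, prob, n_bits, module_probs = NULL) {
  out <- tibble::tibble(code = code, prob = prob)
  attr(out, "n_bits") <- n_bits
  attr(out, "module_probs") <- module_probs
  class(out) <- c("code_distribution", class(out))
  out
}

#' @rdname build_code_distribution
#' @param n_bits Number of bits for a maximum-entropy (uniform) pool.
#' @export
uniform_code_distribution <- function(n_bits) {
  b <- code_capacity(n_bits)
  bits <- enumerate_codes(n_bits)
  group <- if (n_bits %% 5L == 0L) 5L else n_bits
  new_code_distribution(
    code = bits_to_string(bits, group_size = group),
    prob = rep(1 / b, b),
    n_bits = n_bits
  )
}

# Accept a numeric vector or a module frequency table.
module_probs <- function(freqs) {
  if (is.data.frame(freqs)) {
    if (!"frequency" %in% names(freqs)) {
      stop("module frequency table needs a `frequency` column", call. = FALSE)
    }
    p <- as.numeric(freqs$frequency)
  } else {
    p <- as.numeric(freqs)
  }
  if (length(p) < 1 || anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("module frequencies must be probabilities in [0, 1]", call. = FALSE)
  }
  p
}

#' Conditional per-slot marginals of a module probability vector
#'
#' Observed ON fractions in imaging data are conditional on the cell being
#' labeled at all: `m_i = p_i / (1 - prod(1 - p))`.
#'
#' @param p Unconditional per-module ON probabilities.
#' @return Per-slot ON fractions among labeled cells.
#' @export
conditional_marginals <- function(p) {
  p <- module_probs(p)
  z <- 1 - prod(1 - p)
  if (z <= 0) stop("zero labeling probability", call. = FALSE)
  p / z
}

#' Invert observed conditional marginals to module probabilities
#'
#' Solves `m_i = p_i / (1 - prod(1 - p))` for `p` by fixed-point iteration
#' `p <- m * (1 - prod(1 - p))` starting from `p = m`, so that the
#' conditional marginals of [build_code_distribution()] applied to the
#' result reproduce `m`.
#'
#' @param m Observed per-slot ON fractions among labeled cells, in `[0, 1]`,
#'   at least one positive.
#' @param tol Convergence tolerance on the reproduced marginals (default 1e-9).
#' @param max_iter Iteration cap.
#' @return Unconditional module probabilities `p`.
#' @examples
#' p <- decondition_marginals(rep(16 / 31, 5))
#' all.equal(p, rep(0.5, 5), tolerance = 1e-8)
#' @export
decondition_marginals <- function(m, tol = 1e-9, max_iter = 10000L) {
  m <- module_probs(m)
  if (all(m == 0)) {
    stop("all observed marginals are zero; no labeled cells to invert", call. = FALSE)
  }
  p <- m
  resid <- Inf
  for (it in seq_len(max_iter)) {
    p <- m * (1 - prod(1 - p))
    z <- 1 - prod(1 - p)
    if (z <= 0) break
    resid <- max(abs(p / z - m))
    if (resid < tol) return(p)
  }
  stop(sprintf(
    "decondition_marginals did not converge within %d iterations (residual %.3g); the supplied marginals may be infeasible",
    max_iter, resid), call. = FALSE)
}

#' Estimate per-module recombination frequencies from a cluster table
#'
#' For each (compartment, fluorophore) slot, the fraction of labeled clusters
#' in which that bit is ON, computed per brain and summarized across brains
#' as mean and SD (with a pooled all-cluster estimate alongside). These are
#' conditional marginals: they condition on the cluster being labeled, so use
#' `conditional_marginals = TRUE` (or [decondition_marginals()]) when feeding
#' them back into [build_code_distribution()].
#'
#' @param clusters A cluster table: data frame with columns `brain_id` and
#'   `code` (grouped 0/1 strings), one row per labeled clone.
#' @return A tibble with one row per slot: `slot`, `compartment`,
#'   `fluorophore`, `pooled` (all clusters), `mean` and `sd` (across brains).
#'   The per-brain frequency matrix is attached as attribute `per_brain`;
#'   with a single brain `sd` is `NA`.
#' @export
estimate_module_frequencies <- function(clusters) {
  clusters <- validate_cluster_table(clusters)
  bits <- codes_to_matrix(clusters$code)
  brain <- as.character(clusters$brain_id)
  per_brain <- rowsum(bits, brain) / as.vector(table(brain)[sort(unique(brain))])
  n_bits <- ncol(bits)
  out <- tibble::tibble(
    slot = slot_labels(n_bits),
    compartment = slot_compartments(n_bits),
    fluorophore = slot_fluorophores(n_bits),
    pooled = colMeans(bits),
    mean = colMeans(per_brain),
    sd = if (nrow(per_brain) > 1) apply(per_brain, 2, sd) else rep(NA_real_, n_bits)
  )
  attr(out, "per_brain") <- per_brain
  attr(out, "n_brains") <- nrow(per_brain)
  out
}

slot_compartments <- function(n_bits) {
  if (n_bits %% 5L == 0L) {
    rep(bitbow_compartments(n_bits %/% 5L), each = 5L)
  } else {
    rep(NA_character_, n_bits)
  }
}

slot_fluorophores <- function(n_bits) {
  if (n_bits %% 5L == 0L) {
    rep(unname(BITBOW_FPS), n_bits %/% 5L)
  } else {
    paste0("bit", seq_len(n_bits))
  }
}

slot_labels <- function(n_bits) {
  if (n_bits %% 5L == 0L) {
    paste(slot_compartments(n_bits), slot_fluorophores(n_bits), sep = ":")
  } else {
    paste0("bit", seq_len(n_bits))
  }
}

#' Whitelist of low-frequency codes
#'
#' Removes the `m` highest-probability codes from a pool, retaining the
#' lower-frequency codes whose occurrences can be assigned to a lineage with
#' high confidence (for the full 15-bit pool, excluding the top 67 or 767
#' codes leaves 32,700 or 32,000). Ties in probability are broken by
#' lexicographic code order so whitelists are reproducible.
#'
#' @param dist A `code_distribution`.
#' @param m Number of highest-probability codes to exclude
#'   (`0 <= m < pool size`).
#' @return Character vector of retained codes in lexicographic order, with
#'   attributes `excluded` (the removed codes, most probable first) and
#'   `mass` (total probability retained).
#' @export
whitelist_exclude_top <- function(dist, m) {
  stopifnot(inherits(dist, "code_distribution"))
  if (length(m) != 1 || !is.finite(m) || m < 0 || m != floor(m)) {
    stop("`m` must be a single nonnegative integer", call. = FALSE)
  }
  b <- nrow(dist)
  if (m >= b) {
    stop(sprintf("cannot exclude %d codes from a pool of %d", m, b), call. = FALSE)
  }
  ord <- order(-dist$prob, dist$code)
  excluded <- dist$code[ord[seq_len(m)]]
  keep <- !(dist$code %in% excluded)
  wl <- sort(dist$code[keep])
  attr(wl, "excluded") <- excluded
  attr(wl, "mass") <- sum(dist$prob[keep])
  wl
}

#' @rdname whitelist_exclude_top
#' @param whitelist A character vector of codes (or `NULL` for the full pool).
#' @return `whitelist_mass()`: total probability of the whitelisted codes.
#' @export
whitelist_mass <- function(dist, whitelist = NULL) {
  stopifnot(inherits(dist, "code_distribution"))
  if (is.null(whitelist)) return(1)
  sum(dist$prob[dist$code %in% whitelist])
}

#' Draw codes i.i.d. from a code distribution
#'
#' Module-level sampling conditioned on at least one bit ON is equivalent to
#' sampling directly from the renormalized nonzero-code distribution, which
#' is what this does.
#'
#' @param dist A `code_distribution`.
#' @param n Number of draws.
#' @return Character vector of `n` code strings.
#' @export
sample_codes <- function(dist, n) {
  stopifnot(inherits(dist, "code_distribution"), n >= 0)
  if (n == 0) return(character(0))
  dist$code[sample.int(nrow(dist), n, replace = TRUE, prob = dist$prob)]
}
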