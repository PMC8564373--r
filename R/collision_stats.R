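# Collision statistics: how often do two lineages in one brain end up with
# the same code? "Collision rate" is standardized package-wide as the
# expected fraction of draws that repeat an earlier draw,
# E[(n - #distinct)/n] under i.i.d. sampling of n codes. The experimental
# cluster-level statistic (fraction of clusters not uniquely labeled) is a
# different quantity and lives under cluster_collision_summary().

validate_cluster_table <- function(clusters) {
  if (!is.data.frame(clusters)) stop("cluster table must be a data frame", call. = FALSE)
  need <- c("brain_id", "code")
  miss <- setdiff(need, names(clusters))
  if (length(miss) > 0) {
    stop(sprintf("cluster table is missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (nrow(clusters) == 0) stop("cluster table is empty", call. = FALSE)
  check_code_strings(clusters$code)
  if (any(gsub("[-0]", "", clusters$code) == "")) {
    stop("cluster table contains an all-zero (unlabeled) code", call. = FALSE)
  }
  if ("cluster_id" %in% names(clusters)) {
    key <- paste(clusters$brain_id, clusters$cluster_id, sep = "\r")
    if (anyDuplicated(key)) {
      stop("(brain_id, cluster_id) pairs must be unique", call. = FALSE)
    }
  }
  tibble::as_tibble(clusters)
}

new_collision_estimate <- function(n, b, expected_collisions, method,
                                   reps = NULL, seed = NULL, se = NULL) {
  rate <- if (n > 0) expected_collisions / n else 0
  structure(
    list(n = n, b = b, expected_collisions = expected_collisions,
         rate = rate, method = method, reps = reps, seed = seed, se = se),
    class = "collision_estimate"
  )
}

#' @export
print.collision_estimate <- function(x, ...) {
  cat(sprintf("<collision_estimate> method=%s  n=%g  pool=%g\n",
              x$method, x$n, x$b))
  cat(sprintf("  expected collisions: %.4g   rate: %.4g (%s%%)\n",
              x$expected_collisions, x$rate, format(percent1(x$rate))))
  if (!is.null(x$se)) {
    cat(sprintf("  reps: %d   SE(rate): %.3g   seed: %s\n",
                x$reps, x$se, format(x$seed)))
  }
  invisible(x)
}

#' Report a rate as a percentage at one decimal
#'
#' Printed-value convention: 1 decimal place, round-half-even (base R
#' [round()]).
#'
#' @param rate A proportion in `[0, 1]`.
#' @return Percentage rounded to one decimal.
#' @export
percent1 <- function(rate) round(100 * rate, 1)

#' Closed-form collision rate for a uniform code pool
#'
#' The birthday-problem expectation: drawing `n` lineages i.i.d. from a
#' uniform pool of `b` codes, the expected number of collisions (draws minus
#' distinct codes) is `c = n - b * (1 - ((b - 1) / b)^n)`, and the collision
#' rate is `c / n`. At `n = 200` this gives 84.5%, 9.1%, and 0.3% for pools
#' of 31, 1,023, and 32,767 codes (5-, 10-, and 15-bit designs).
#'
#' @param b Pool size (number of equally likely codes), `>= 1`.
#' @param n Number of coded lineages drawn, `>= 0`.
#' @return A `collision_estimate` with method `"closed_form"`.
#' @examples
#' percent1(expected_collision_rate_uniform(31, 200)$rate)  # 84.5
#' @export
expected_collision_rate_uniform <- function(b, n) {
  stopifnot(length(b) == 1, length(n) == 1, b >= 1, n >= 0)
  cc <- n - b * (1 - ((b - 1) / b)^n)
  new_collision_estimate(n = n, b = b, expected_collisions = cc,
                         method = "closed_form")
}

#' Analytic collision rate for an arbitrary code distribution
#'
#' Exact expectation of `(draws - distinct codes) / draws` under i.i.d.
#' sampling of `n` codes with probabilities `p`: the expected number of
#' distinct codes is `sum(1 - (1 - p_i)^n)`, so
#' `c = n - sum(1 - (1 - p_i)^n)`. Reduces to the uniform closed form when
#' all `p_i = 1/b`. With a whitelist, probabilities are first restricted to
#' the whitelisted codes and renormalized (sampling conditioned on the
#' whitelist).
#'
#' @param dist A `code_distribution`.
#' @param n Number of coded lineages drawn, `>= 0`.
#' @param whitelist Optional character vector of admissible codes.
#' @return A `collision_estimate` with method `"analytic_general"`.
#' @export
expected_collision_rate_general <- function(dist, n, whitelist = NULL) {
  stopifnot(inherits(dist, "code_distribution"), length(n) == 1, n >= 0)
  p <- restrict_probs(dist, whitelist)
  expected_distinct <- sum(1 - (1 - p)^n)
  new_collision_estimate(n = n, b = length(p),
                         expected_collisions = n - expected_distinct,
                         method = "analytic_general")
}

restrict_probs <- function(dist, whitelist) {
  if (is.null(whitelist)) return(dist$prob)
  keep <- dist$code %in% whitelist
  z <- sum(dist$prob[keep])
  if (z <= 0) {
    stop("whitelist has zero probability mass under this distribution", call. = FALSE)
  }
  dist$prob[keep] / z
}

#' Replicate schedule for collision simulations
#'
#' Default Monte Carlo replicate counts by system size: 100,000 replicates
#' for systems under 100 lineages, 1,000 between 100 and 1,000, and 10 above
#' that (cost grows with `n`).
#'
#' @param n Number of lineages.
#' @return Replicate count.
#' @export
default_collision_reps <- function(n) {
  if (n < 100) 100000L else if (n <= 1000) 1000L else 10L
}

#' Monte Carlo collision rate
#'
#' Draws `n` codes i.i.d. from the distribution, counts repeated codes, and
#' averages `(n - distinct)/n` over replicates. Identical seeds give
#' identical output.
#'
#' @inheritParams expected_collision_rate_general
#' @param reps Number of replicate draws; defaults to
#'   [default_collision_reps()] of `n`.
#' @param seed Optional RNG seed for reproducibility.
#' @param whitelist_method How a whitelist restricts sampling:
#'   `"renormalize"` (default) samples from the distribution conditioned on
#'   the whitelist; `"discard"` samples from the full pool and drops
#'   non-whitelisted draws from the tally.
#' @return A `collision_estimate` with method `"monte_carlo"`, carrying the
#'   replicate count, seed, and standard error of the mean rate.
#' @export
simulate_collision_rate <- function(dist, n, reps = NULL, seed = NULL,
                                    whitelist = NULL,
                                    whitelist_method = c("renormalize", "discard")) {
  stopifnot(inherits(dist, "code_distribution"), length(n) == 1, n >= 0)
  whitelist_method <- match.arg(whitelist_method)
  if (is.null(reps)) reps <- default_collision_reps(n)
  if (reps < 1) stop("`reps` must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  if (n <= 1) {
    return(new_collision_estimate(n = n, b = nrow(dist), expected_collisions = 0,
                                  method = "monte_carlo", reps = as.integer(reps),
                                  seed = seed, se = 0))
  }

  if (whitelist_method == "renormalize" || is.null(whitelist)) {
    p <- restrict_probs(dist, whitelist)
    rates <- sim_collision_rates(p, n, reps)
  } else {
    ok <- dist$code %in% whitelist
    if (!any(ok)) stop("whitelist has zero probability mass under this distribution", call. = FALSE)
    rates <- vapply(seq_len(reps), function(r) {
      idx <- sample.int(nrow(dist), n, replace = TRUE, prob = dist$prob)
      idx <- idx[ok[idx]]
      m <- length(idx)
      if (m <= 1) 0 else (m - length(unique(idx))) / m
    }, numeric(1))
  }
  new_collision_estimate(
    n = n, b = nrow(dist), expected_collisions = mean(rates) * n,
    method = "monte_carlo", reps = as.integer(reps), seed = seed,
    se = sd(rates) / sqrt(reps)
  )
}

# Vectorized replicate draws: sample all reps at once in chunks, count
# repeats per replicate via adjacent equality after a per-column sort.
sim_collision_rates <- function(p, n, reps) {
  npool <- length(p)
  chunk <- max(1L, min(reps, floor(2e6 / n)))
  rates <- numeric(reps)
  done <- 0L
  while (done < reps) {
    k <- min(chunk, reps - done)
    m <- matrix(sample.int(npool, n * k, replace = TRUE, prob = p), nrow = n)
    sorted <- apply(m, 2, sort.int, method = "radix")
    dup <- colSums(sorted[-1, , drop = FALSE] == sorted[-n, , drop = FALSE])
    rates[done + seq_len(k)] <- dup / n
    done <- done + k
  }
  rates
}

#' Cluster-level collision summary
#'
#' Within each brain, classifies labeled clusters by how many clusters share
#' their code: uniquely labeled, in a pair, or in a group of three or more.
#' The experimental collision rate is the fraction of clusters that are not
#' uniquely labeled. Summaries are per brain, with mean and SD across brains.
#'
#' @param clusters A cluster table (columns `brain_id`, `code`, optionally
#'   `cluster_id`).
#' @return A list with `per_brain` (tibble: `brain_id`, `n_clusters`,
#'   `frac_unique`, `frac_pair`, `frac_multi`, `collision_rate`, and
#'   `repeat_rate` = (clusters - distinct codes)/clusters, the observed
#'   counterpart of the expectation computed by
#'   [expected_collision_rate_general()]) and `summary` (mean and SD of each
#'   fraction across brains).
#' @export
cluster_collision_summary <- function(clusters) {
  clusters <- validate_cluster_table(clusters)
  per_brain <- clusters |>
    dplyr::add_count(.data$brain_id, .data$code, name = ".mult") |>
    dplyr::group_by(.data$brain_id) |>
    dplyr::summarise(
      n_clusters = dplyr::n(),
      frac_unique = mean(.data$.mult == 1),
      frac_pair = mean(.data$.mult == 2),
      frac_multi = mean(.data$.mult >= 3),
      collision_rate = 1 - mean(.data$.mult == 1),
      repeat_rate = 1 - dplyr::n_distinct(.data$code) / dplyr::n(),
      .groups = "drop"
    )
  list(per_brain = per_brain, summary = summarise_brain_fracs(per_brain))
}

#' Code occupancy summary
#'
#' The dual view of [cluster_collision_summary()]: within each brain,
#' classifies each distinct observed code by how many clusters express it
#' (1, 2, or >= 3 clusters).
#'
#' @inheritParams cluster_collision_summary
#' @return A list with `per_brain` (tibble: `brain_id`, `n_codes`,
#'   `frac_in1`, `frac_in2`, `frac_in3plus`) and `summary` (mean and SD
#'   across brains).
#' @export
code_occupancy_summary <- function(clusters) {
  clusters <- validate_cluster_table(clusters)
  per_brain <- clusters |>
    dplyr::count(.data$brain_id, .data$code, name = ".mult") |>
    dplyr::group_by(.data$brain_id) |>
    dplyr::summarise(
      n_codes = dplyr::n(),
      frac_in1 = mean(.data$.mult == 1),
      frac_in2 = mean(.data$.mult == 2),
      frac_in3plus = mean(.data$.mult >= 3),
      .groups = "drop"
    )
  list(per_brain = per_brain, summary = summarise_brain_fracs(per_brain))
}

summarise_brain_fracs <- function(per_brain) {
  vals <- per_brain[setdiff(names(per_brain), "brain_id")]
  vals <- vals[vapply(vals, is.numeric, logical(1))]
  tibble::tibble(
    statistic = names(vals),
    mean = vapply(vals, mean, numeric(1)),
    sd = if (nrow(per_brain) > 1) vapply(vals, sd, numeric(1))
         else rep(NA_real_, length(vals))
  )
}

#' Lineage labeling rate
#'
#' Fraction of lineages labeled per animal: total observed clusters divided
#' by (brains x lineages per brain). 577 clusters over 6 brains of 200
#' lineages gives 48.08%.
#'
#' @param clusters A cluster table, or `NULL` if `n_clusters`/`n_brains` are
#'   given directly.
#' @param lineages_per_brain Estimated lineage count per brain (e.g. 200 for
#'   the central brain), `>= 1`.
#' @param n_brains Number of brains surveyed; defaults to the number of
#'   distinct `brain_id`s in `clusters`.
#' @param n_clusters Total cluster count; defaults to `nrow(clusters)`.
#' @return The labeling rate as a fraction in `[0, 1]` (can exceed 1 if the
#'   lineage count is underestimated).
#' @examples
#' labeling_rate(lineages_per_brain = 200, n_brains = 6, n_clusters = 577)
#' @export
labeling_rate <- function(clusters = NULL, lineages_per_brain,
                          n_brains = NULL, n_clusters = NULL) {
  if (length(lineages_per_brain) != 1 || !is.finite(lineages_per_brain) ||
      lineages_per_brain < 1) {
    stop("`lineages_per_brain` must be a single number >= 1", call. = FALSE)
  }
  if (!is.null(clusters)) {
    clusters <- validate_cluster_table(clusters)
    if (is.null(n_brains)) n_brains <- length(unique(clusters$brain_id))
    if (is.null(n_clusters)) n_clusters <- nrow(clusters)
  }
  if (is.null(n_brains) || is.null(n_clusters)) {
    stop("supply a cluster table or both `n_brains` and `n_clusters`", call. = FALSE)
  }
  if (n_brains < 1) stop("at least one brain is required", call. = FALSE)
  n_clusters / (n_brains * lineages_per_brain)
}
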