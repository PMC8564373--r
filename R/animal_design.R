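# Experiment sizing: how many animals until every lineage has been validly
# sampled at least once? Per animal, each not-yet-sampled lineage activates
# independently with `activation_rate`; an activated lineage draws a code
# from the code distribution, and the sample only counts when the code is on
# the whitelist (otherwise its lineage identity cannot be confidently
# assigned). This is a coupon-collector problem with per-coupon success
# probability q = activation_rate * whitelist mass.

#' Named activation-rate presets
#'
#' Lineage labeling rates used in experiment-sizing comparisons:
#' `bitbow` (48.08%, from 577 clusters over 6 brains of ~200 lineages) and
#' two single-color MARCM-style presets, `marcm` (1%, the rate quoted when
#' ensuring at most one labeled lineage per brain) and `marcm_low` (0.5%, the
#' rate used in the sizing simulation itself). The two MARCM figures come
#' from different parts of the original analysis; both are surfaced rather
#' than reconciled.
#'
#' @return Named numeric vector of activation rates.
#' @export
activation_presets <- function() {
  c(bitbow = 0.4808, marcm = 0.01, marcm_low = 0.005)
}

#' Monte Carlo estimate of the number of animals needed
#'
#' Simulates animals until every one of `L` lineages has been validly
#' sampled at least once, and averages the animal count over trials.
#' Already-sampled lineages are not re-drawn (equivalent in distribution,
#' cheaper). A labeled lineage bearing a non-whitelisted code does not count
#' as sampled, but does not block future sampling of that lineage.
#'
#' @param L Number of lineages per brain (e.g. 200 for the central brain).
#' @param activation_rate Probability that a lineage is labeled in one
#'   animal, in `(0, 1]`.
#' @param dist Optional `code_distribution` the labeled lineages draw codes
#'   from; only consulted when a `whitelist` is supplied (code identity is
#'   otherwise irrelevant to sampling success).
#' @param whitelist Optional character vector of admissible codes (see
#'   [whitelist_exclude_top()]).
#' @param trials Number of simulation trials (default 500).
#' @param seed Optional RNG seed; identical seeds give identical per-trial
#'   sequences.
#' @return An `animal_sim_result`: list with `mean`, `sd`, `per_trial`,
#'   and the configuration echo.
#' @examples
#' simulate_animals_needed(L = 10, activation_rate = 1, trials = 5)$mean  # 1
#' @export
simulate_animals_needed <- function(L, activation_rate, dist = NULL,
                                    whitelist = NULL, trials = 500L,
                                    seed = NULL) {
  stopifnot(length(L) == 1, L >= 1, L == floor(L),
            length(trials) == 1, trials >= 1)
  if (length(activation_rate) != 1 || !is.finite(activation_rate) ||
      activation_rate < 0 || activation_rate > 1) {
    stop("`activation_rate` must be a probability", call. = FALSE)
  }
  if (activation_rate == 0) {
    stop("activation_rate = 0: no lineage can ever be sampled", call. = FALSE)
  }
  use_codes <- !is.null(whitelist)
  if (use_codes) {
    if (is.null(dist)) {
      stop("a whitelist requires a code distribution to draw from", call. = FALSE)
    }
    valid <- dist$code %in% whitelist
    if (sum(dist$prob[valid]) <= 0) {
      stop("whitelist has zero probability mass: no lineage can ever be validly sampled",
           call. = FALSE)
    }
  }
  if (!is.null(seed)) set.seed(seed)

  per_trial <- vapply(seq_len(trials), function(trial) {
    remaining <- L
    animals <- 0L
    while (remaining > 0) {
      animals <- animals + 1L
      k <- sum(runif(remaining) < activation_rate)
      if (k > 0) {
        if (use_codes) {
          idx <- sample.int(nrow(dist), k, replace = TRUE, prob = dist$prob)
          k <- sum(valid[idx])
        }
        remaining <- remaining - k
      }
    }
    animals
  }, integer(1))

  structure(
    list(
      mean = mean(per_trial),
      sd = sd(per_trial),
      per_trial = per_trial,
      config = list(L = L, activation_rate = activation_rate,
                    whitelist_mass = if (use_codes) sum(dist$prob[valid]) else 1,
                    trials = as.integer(trials), seed = seed)
    ),
    class = "animal_sim_result"
  )
}

#' @export
print.animal_sim_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<animal_sim_result> L=%d  activation=%.4g  whitelist mass=%.4g\n",
              cfg$L, cfg$activation_rate, cfg$whitelist_mass))
  cat(sprintf("  animals needed: %.2f +/- %.2f (mean +/- SD over %d trials)\n",
              x$mean, x$sd, cfg$trials))
  invisible(x)
}

#' Analytic expectation of the number of animals needed
#'
#' The number of animals until a given lineage is validly sampled is
#' geometric with success probability `q = activation_rate * whitelist
#' mass`; the animals needed overall is the maximum of `L` independent
#' geometrics, with expectation `sum_{a >= 0} 1 - (1 - (1-q)^a)^L`. The sum
#' is truncated once the tail term drops below `tol`.
#'
#' @inheritParams simulate_animals_needed
#' @param whitelist_mass Probability that a drawn code is admissible
#'   (default 1, the full pool); multiply in place of `dist`/`whitelist`.
#' @param tol Truncation tolerance for the tail of the series.
#' @return Expected number of animals (a real number `>= 1`).
#' @examples
#' expected_animals_analytic(L = 1, activation_rate = 0.5)  # 2
#' @export
expected_animals_analytic <- function(L, activation_rate, whitelist_mass = 1,
                                      tol = 1e-12) {
  stopifnot(length(L) == 1, L >= 1, L == floor(L))
  q <- activation_rate * whitelist_mass
  if (length(q) != 1 || !is.finite(q) || q < 0 || q > 1) {
    stop("effective sampling probability must be in [0, 1]", call. = FALSE)
  }
  if (q == 0) stop("effective sampling probability is zero", call. = FALSE)
  if (q == 1) return(1)
  total <- 0
  a <- 0
  repeat {
    term <- 1 - (1 - (1 - q)^a)^L
    total <- total + term
    a <- a + 1
    if (term < tol) break
    if (a > 1e8) stop("series failed to converge", call. = FALSE)
  }
  total
}
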