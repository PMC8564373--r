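#' bitbowr: design and analysis of combinatorial fluorophore lineage tracing
#'
#' A Bitbow cassette carries N independently recombining fluorophore modules,
#' each of which ends up ON or OFF, so a labeled cell displays one of
#' `2^N - 1` nonzero binary color codes. This package implements the
#' quantitative layer of such experiments: code capacity and entropy,
#' code-frequency modelling, collision statistics, experiment sizing, and
#' calling binary codes from multichannel image intensities.
#'
#' @keywords internal
#' @importFrom stats median rnorm runif rlnorm sd setNames runmed
#' @importFrom utils head
#' @importFrom dplyr .data
"_PACKAGE"

# Fluorophore alphabet: one-letter labels in fixed bit order within a
# 5-module group.
BITBOW_FPS <- c(
  mAmetrine   = "A",
  mTFP1       = "T",
  mNeonGreen  = "G",
  mKO2        = "O",
  tdKatushka2 = "K"
)

#' Default fluorophore and compartment labels
#'
#' The five spectrally distinct fluorophores, in fixed bit order
#' (mAmetrine, mTFP1, mNeonGreen, mKO2, tdKatushka2 -- letters A, T, G, O, K),
#' and the subcellular compartment order used when the same five modules are
#' targeted to multiple compartments (membrane, then nucleus, then Golgi).
#'
#' @param n_compartments Number of compartment groups (1 for a 5-bit code,
#'   2 for 10 bits, 3 for 15 bits).
#' @return `bitbow_fluorophores()`: named character vector of one-letter
#'   labels. `bitbow_compartments()`: character vector of compartment names.
#' @export
bitbow_fluorophores <- function() BITBOW_FPS

#' @rdname bitbow_fluorophores
#' @export
bitbow_compartments <- function(n_compartments) {
  stopifnot(length(n_compartments) == 1, n_compartments >= 1)
  base <- c("membrane", "nucleus", "golgi")
  if (n_compartments <= 3) {
    base[seq_len(n_compartments)]
  } else {
    c(base, paste0("compartment", seq(4L, n_compartments)))
  }
}

#' Number of distinct nonzero codes for a given bit count
#'
#' With N independently recombining ON/OFF modules, `2^N - 1` distinct
#' nonzero codes can be displayed by a labeled cell (the all-zero state is
#' unlabeled and invisible).
#'
#' @param n_bits Number of binary modules (bits); a single integer >= 1.
#' @return The code capacity `2^n_bits - 1`, as integer when representable.
#' @examples
#' code_capacity(5)   # 31
#' code_capacity(15)  # 32767
#' @export
code_capacity <- function(n_bits) {
  if (length(n_bits) != 1 || !is.numeric(n_bits) || !is.finite(n_bits) ||
      n_bits < 1 || n_bits != floor(n_bits)) {
    stop("`n_bits` must be a single integer >= 1", call. = FALSE)
  }
  cap <- 2^n_bits - 1
  if (cap <= .Machine$integer.max) as.integer(cap) else cap
}

#' Enumerate the full nonzero code pool as a bit matrix
#'
#' Rows are ordered lexicographically by bit string (the global tie-break
#' order used throughout the package); columns are bits in fixed slot order.
#'
#' @param n_bits Number of bits (1..25).
#' @return Integer matrix of dim `code_capacity(n_bits)` x `n_bits`.
#' @export
enumerate_codes <- function(n_bits) {
  n_codes <- code_capacity(n_bits)
  if (n_bits > 25) stop("code pool too large to enumerate (n_bits > 25)", call. = FALSE)
  idx <- seq_len(n_codes)
  bits <- vapply(
    seq_len(n_bits),
    function(j) as.integer(bitwAnd(idx, bitwShiftL(1L, n_bits - j)) > 0L),
    integer(n_codes)
  )
  if (n_codes == 1L) bits <- matrix(bits, nrow = 1L)
  bits
}

#' Convert bit vectors to grouped code strings and back
#'
#' A code string shows the ON/OFF state of each fluorophore in fixed order
#' A, T, G, O, K as groups of five 0/1 digits, one group per subcellular
#' compartment (membrane, nucleus, golgi), joined by `-`; e.g.
#' `"01000-00000-00001"` is a 15-bit code with membrane-mTFP1 and
#' golgi-tdKatushka2 ON.
#'
#' @param bits Integer vector of 0/1, or a matrix with one code per row.
#' @param group_size Digits per group (the fluorophore count, default 5).
#' @return `bits_to_string()`: character vector of code strings.
#'   `codes_to_matrix()`: integer 0/1 matrix, one code per row.
#' @examples
#' bits_to_string(c(1, 0, 0, 0, 0))
#' codes_to_matrix("01000-00000-00001")
#' @export
bits_to_string <- function(bits, group_size = 5L) {
  if (is.null(dim(bits))) bits <- matrix(bits, nrow = 1L)
  n_bits <- ncol(bits)
  if (n_bits %% group_size != 0) {
    stop(sprintf("bit length %d is not a multiple of the group size %d",
                 n_bits, group_size), call. = FALSE)
  }
  if (!all(bits %in% c(0L, 1L))) stop("bits must be 0/1", call. = FALSE)
  n_groups <- n_bits %/% group_size
  groups <- lapply(seq_len(n_groups), function(g) {
    cols <- ((g - 1L) * group_size + 1L):(g * group_size)
    do.call(paste0, as.data.frame(bits[, cols, drop = FALSE]))
  })
  do.call(paste, c(groups, sep = "-"))
}

#' @rdname bits_to_string
#' @param codes Character vector of grouped 0/1 code strings.
#' @export
codes_to_matrix <- function(codes, group_size = 5L) {
  check_code_strings(codes, group_size)
  digits <- gsub("-", "", codes, fixed = TRUE)
  n_bits <- nchar(digits[1])
  m <- matrix(
    as.integer(unlist(strsplit(digits, "", fixed = TRUE), use.names = FALSE)),
    ncol = n_bits, byrow = TRUE
  )
  rownames(m) <- NULL
  m
}

# Validate grouped code strings; on failure, report the first offending
# character position within the offending string.
check_code_strings <- function(codes, group_size = 5L) {
  if (length(codes) == 0) stop("no code strings supplied", call. = FALSE)
  pat <- sprintf("^[01]{%d}(-[01]{%d})*$", group_size, group_size)
  ok <- grepl(pat, codes)
  if (!all(ok)) {
    bad <- codes[!ok][1]
    chars <- strsplit(bad, "")[[1]]
    pos <- which(!chars %in% c("0", "1", "-"))
    if (length(pos) > 0) {
      stop(sprintf("malformed code string '%s': invalid character '%s' at position %d",
                   bad, chars[pos[1]], pos[1]), call. = FALSE)
    }
    stop(sprintf(
      "malformed code string '%s': groups must each have %d binary digits separated by '-'",
      bad, group_size), call. = FALSE)
  }
  n <- nchar(gsub("-", "", codes, fixed = TRUE))
  if (length(unique(n)) > 1) {
    stop("code strings have inconsistent bit lengths", call. = FALSE)
  }
  invisible(codes)
}

#' Bitbow code objects
#'
#' A `bitbow_code` is an ordered 0/1 vector over (compartment, fluorophore)
#' slots, together with its fluorophore and compartment labels. The all-zero
#' vector is accepted but flagged as unlabeled: it represents a cell in which
#' no module recombined ON, which is invisible in imaging and never a member
#' of a code pool.
#'
#' @param bits Integer 0/1 vector whose length is a multiple of the
#'   fluorophore count.
#' @param fp_labels One-letter fluorophore labels in bit order.
#' @param compartment_labels Compartment names, one per group of
#'   `length(fp_labels)` bits; defaults to membrane/nucleus/golgi.
#' @return An object of class `bitbow_code`.
#' @examples
#' decode("10000")
#' encode(bitbow_code(c(0, 1, 0, 0, 0, rep(0, 5), 0, 0, 0, 0, 1)))
#' @export
bitbow_code <- function(bits, fp_labels = unname(BITBOW_FPS),
                        compartment_labels = NULL) {
  bits <- as.integer(bits)
  if (length(bits) == 0 || !all(bits %in% c(0L, 1L))) {
    stop("`bits` must be a nonempty 0/1 vector", call. = FALSE)
  }
  k <- length(fp_labels)
  if (length(bits) %% k != 0) {
    stop(sprintf("bit length %d is not a multiple of the fluorophore count %d",
                 length(bits), k), call. = FALSE)
  }
  n_groups <- length(bits) %/% k
  if (is.null(compartment_labels)) {
    compartment_labels <- bitbow_compartments(n_groups)
  }
  if (length(compartment_labels) != n_groups) {
    stop("`compartment_labels` must have one entry per 5-bit group", call. = FALSE)
  }
  structure(
    list(bits = bits, fp_labels = fp_labels,
         compartment_labels = compartment_labels),
    class = "bitbow_code"
  )
}

#' @rdname bitbow_code
#' @param code A `bitbow_code` object (or plain 0/1 vector) to encode.
#' @export
encode <- function(code) {
  if (inherits(code, "bitbow_code")) {
    bits_to_string(code$bits, group_size = length(code$fp_labels))
  } else {
    bits_to_string(as.integer(code))
  }
}

#' @rdname bitbow_code
#' @param s A grouped 0/1 code string such as `"01000-00000-00001"`.
#' @export
decode <- function(s) {
  if (length(s) != 1) stop("`s` must be a single code string", call. = FALSE)
  bits <- drop(codes_to_matrix(s))
  code <- bitbow_code(bits)
  if (all(bits == 0L)) attr(code, "unlabeled") <- TRUE
  code
}

#' @rdname bitbow_code
#' @export
is_unlabeled <- function(code) {
  stopifnot(inherits(code, "bitbow_code"))
  all(code$bits == 0L)
}

#' @export
print.bitbow_code <- function(x, ...) {
  cat("<bitbow_code> ", encode(x), if (is_unlabeled(x)) " (unlabeled)", "\n",
      sep = "")
  on <- which(x$bits == 1L)
  if (length(on) > 0) {
    k <- length(x$fp_labels)
    comp <- x$compartment_labels[(on - 1L) %/% k + 1L]
    fp <- x$fp_labels[(on - 1L) %% k + 1L]
    cat("  ON: ", paste(comp, fp, sep = ":", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Shannon entropy of observed code frequencies
#'
#' Summarizes the information-carrying ability of a labeling experiment as
#' `H = -sum(f_i * log2(f_i))` over observed codes, with `f_i` the fraction
#' of observations carrying code i. H is 0 for a single code and reaches
#' `log2(k)` bits when k distinct codes occur equally often.
#'
#' @param counts Observed code counts: a named numeric vector (names are code
#'   strings), a `table`, or a data frame with columns `code` and `count`.
#' @return Entropy in bits.
#' @examples
#' shannon_entropy(c("10000" = 5, "01000" = 5))  # 1 bit
#' @export
shannon_entropy <- function(counts) {
  counts <- as_code_counts(counts)
  if (length(counts) == 0) stop("empty code count table", call. = FALSE)
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  total <- sum(counts)
  if (total <= 0) stop("total code count must be positive", call. = FALSE)
  f <- counts / total
  f <- f[f > 0]
  -sum(f * log2(f))
}

as_code_counts <- function(counts) {
  if (is.data.frame(counts)) {
    if (!all(c("code", "count") %in% names(counts))) {
      stop("code count table needs columns `code` and `count`", call. = FALSE)
    }
    setNames(as.numeric(counts$count), counts$code)
  } else if (is.table(counts)) {
    setNames(as.numeric(counts), names(counts))
  } else if (is.numeric(counts)) {
    counts
  } else {
    stop("unsupported code count input", call. = FALSE)
  }
}
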