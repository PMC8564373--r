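# Plain-text interchange formats: cluster tables and code counts as TSV,
# module frequencies and mixing matrices as CSV, code distributions as TSV,
# neuron traces as 7-column SWC, volumes as multi-page TIFF (optional).

#' Read and write cluster tables
#'
#' Tab-separated, one row per labeled clone, with a header. Required
#' columns: `brain_id`, `cluster_id`, `code` (grouped 0/1 string); optional:
#' `is_neuroblast` (0/1), `cell_count`.
#'
#' @param path File path.
#' @param clusters A cluster table.
#' @return `read_cluster_table()`: a validated tibble.
#' @export
read_cluster_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(code = readr::col_character()))
  if (!"cluster_id" %in% names(tab)) {
    stop("cluster table file needs a `cluster_id` column", call. = FALSE)
  }
  validate_cluster_table(tab)
}

#' @rdname read_cluster_table
#' @export
write_cluster_table <- function(clusters, path) {
  clusters <- validate_cluster_table(clusters)
  readr::write_tsv(clusters, path)
  invisible(path)
}

#' Read and write code count tables
#'
#' Two-column TSV (`code`, `count`) with a header, as consumed by
#' [shannon_entropy()].
#'
#' @param path File path.
#' @param counts Named numeric vector or `code`/`count` data frame.
#' @export
read_code_counts <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(code = readr::col_character()))
  if (!all(c("code", "count") %in% names(tab))) {
    stop("code count file needs columns `code` and `count`", call. = FALSE)
  }
  check_code_strings(tab$code)
  setNames(as.numeric(tab$count), tab$code)
}

#' @rdname read_code_counts
#' @export
write_code_counts <- function(counts, path) {
  counts <- as_code_counts(counts)
  readr::write_tsv(tibble::tibble(code = names(counts), count = unname(counts)), path)
  invisible(path)
}

#' Read and write module frequency tables
#'
#' Comma-separated with columns `compartment`, `fluorophore`, `frequency`,
#' in bit order. Order is validated against the configured alphabet when the
#' bit count is a multiple of 5.
#'
#' @param path File path.
#' @param freqs A module frequency table (as from [gen_module_frequencies()]).
#' @export
read_module_frequencies <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("compartment", "fluorophore", "frequency")
  if (!all(need %in% names(tab))) {
    stop("module frequency file needs columns compartment, fluorophore, frequency",
         call. = FALSE)
  }
  p <- module_probs(tab$frequency)
  n_bits <- length(p)
  if (n_bits %% 5L == 0L) {
    expect_fp <- slot_fluorophores(n_bits)
    if (!identical(as.character(tab$fluorophore), expect_fp)) {
      stop(sprintf("fluorophore order must be %s within each compartment group",
                   paste(unname(BITBOW_FPS), collapse = ", ")), call. = FALSE)
    }
    expect_comp <- slot_compartments(n_bits)
    if (!identical(as.character(tab$compartment), expect_comp)) {
      stop("compartment order must be membrane, nucleus, golgi", call. = FALSE)
    }
  }
  tibble::as_tibble(tab)
}

#' @rdname read_module_frequencies
#' @export
write_module_frequencies <- function(freqs, path) {
  readr::write_csv(freqs, path)
  invisible(path)
}

#' Read and write code distributions
#'
#' Full enumeration as two-column TSV (`code`, `prob`); 32,767 rows for a
#' 15-bit pool.
#'
#' @param path File path.
#' @param dist A `code_distribution`.
#' @export
write_code_distribution <- function(dist, path) {
  stopifnot(inherits(dist, "code_distribution"))
  readr::write_tsv(tibble::tibble(code = dist$code, prob = dist$prob), path)
  invisible(path)
}

#' @rdname write_code_distribution
#' @export
read_code_distribution <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(code = readr::col_character()))
  if (!all(c("code", "prob") %in% names(tab))) {
    stop("code distribution file needs columns `code` and `prob`", call. = FALSE)
  }
  check_code_strings(tab$code)
  if (abs(sum(tab$prob) - 1) > 1e-6) {
    stop("code distribution probabilities do not sum to 1", call. = FALSE)
  }
  n_bits <- nchar(gsub("-", "", tab$code[1], fixed = TRUE))
  new_code_distribution(tab$code, tab$prob / sum(tab$prob), n_bits)
}

#' Read and write mixing matrices
#'
#' Comma-separated, one row per detection channel, one column per
#' fluorophore, header row of fluorophore names.
#'
#' @param path File path.
#' @param M A mixing matrix.
#' @export
read_mixing_matrix <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  validate_mixing_matrix(as.matrix(tab))
}

#' @rdname read_mixing_matrix
#' @export
write_mixing_matrix <- function(M, path) {
  readr::write_csv(tibble::as_tibble(as.data.frame(M)), path)
  invisible(path)
}

#' Read and write SWC neuron traces
#'
#' Standard 7-column SWC: `id`, `type`, `x`, `y`, `z`, `radius`, `parent`,
#' whitespace-separated, `#` comments allowed. Type 1 marks the soma;
#' other types are treated as neurite for provenance.
#'
#' @param path File path.
#' @param swc An SWC data frame.
#' @export
read_swc <- function(path) {
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("id", "type", "x", "y", "z", "radius", "parent"))
  tibble::as_tibble(tab)
}

#' @rdname read_swc
#' @export
write_swc <- function(swc, path) {
  need <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!all(need %in% names(swc))) {
    stop("SWC needs the 7 standard columns", call. = FALSE)
  }
  lines <- c("# id type x y z radius parent",
             do.call(sprintf, c(list("%d %d %g %g %g %g %d"),
                                lapply(need, function(cn) swc[[cn]]))))
  writeLines(lines, path)
  invisible(path)
}

#' Write a multichannel volume as a multi-page TIFF
#'
#' Pages are ordered z-major, channel-minor (page = (z - 1) * C + c), each a
#' 32-bit float X x Y plane. Requires the `tiff` package.
#'
#' @param volume X x Y x Z x C array.
#' @param path Output path.
#' @export
write_volume_tiff <- function(volume, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the `tiff` package is required to write TIFF volumes", call. = FALSE)
  }
  dims <- dim(volume)
  stopifnot(length(dims) == 4)
  pages <- list()
  for (z in seq_len(dims[3])) {
    for (ch in seq_len(dims[4])) {
      pages[[length(pages) + 1L]] <- volume[, , z, ch]
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_volume_tiff
#' @param n_channels Channel count C used to fold pages back into a volume.
#' @export
read_volume_tiff <- function(path, n_channels) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the `tiff` package is required to read TIFF volumes", call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  nz <- length(pages) / n_channels
  stopifnot(nz == floor(nz))
  d <- dim(pages[[1]])
  vol <- array(0, dim = c(d[1], d[2], nz, n_channels))
  k <- 1L
  for (z in seq_len(nz)) {
    for (ch in seq_len(n_channels)) {
      vol[, , z, ch] <- pages[[k]]
      k <- k + 1L
    }
  }
  vol
}
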