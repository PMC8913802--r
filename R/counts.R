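#' Nightly count matrices
#'
#' Detection data are a J x K matrix of non-negative integer counts: for
#' detector j on night k, the number of 10-minute periods with at least one
#' validated call. Failed sensors (or otherwise unobserved detector-nights)
#' are `NA`; missingness is part of the data, not a sentinel count.
#'
#' @param counts numeric J x K matrix; rows named by detector id. `NA`
#'   marks missing detector-nights.
#' @return A `nightly_counts` object (list with element `counts`).
#' @export
nightly_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    stop_invalid("count matrix must have detector ids as row names")
  }
  obs <- counts[!is.na(counts)]
  if (length(obs) && (any(obs < 0) || any(obs != floor(obs)))) {
    stop_invalid("counts must be non-negative integers")
  }
  storage.mode(counts) <- "double"
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("night_", seq_len(ncol(counts)))
  }
  structure(list(counts = counts), class = "nightly_counts")
}

#' @export
print.nightly_counts <- function(x, ...) {
  m <- x$counts
  failed <- sum(rowSums(!is.na(m)) == 0)
  cat(sprintf(
    "Nightly counts: %d detectors x %d nights, %d missing cells (%d dead detectors)\n",
    nrow(m), ncol(m), sum(is.na(m)), failed))
  invisible(x)
}

#' @export
dim.nightly_counts <- function(x) dim(x$counts)

# Per-detector sufficient statistics under a night-constant encounter rate:
# total observed count and number of observed nights.
count_sufficient_stats <- function(counts) {
  m <- counts$counts
  list(
    n_total = rowSums(m, na.rm = TRUE),
    k_obs = rowSums(!is.na(m))
  )
}
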