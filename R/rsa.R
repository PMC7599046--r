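#' Empirical Relative Species Abundance histogram
#'
#' Counts, for each abundance value n >= 1, the number of OTUs observed with
#' exactly n reads. This is the empirical RSA distribution the niche-neutral
#' model describes.
#'
#' @param av an [abundance_vector] or a vector of positive integer counts.
#' @return an object of class `rsa_histogram`: a list with integer vectors
#'   `abundance` (sorted, unique) and `phi` (number of OTUs at each
#'   abundance), plus `n_obs` and `total_reads`.
#' @export
rsa_histogram <- function(av) {
  counts <- if (inherits(av, "abundance_vector")) av$counts else as.numeric(av)
  if (length(counts) == 0 || any(counts < 1 | counts != round(counts)))
    stop_input("abundances must be positive integers")
  tab <- table(counts)
  abundance <- as.integer(names(tab))
  structure(list(abundance = abundance,
                 phi = as.integer(tab),
                 n_obs = length(counts),
                 total_reads = sum(counts)),
            class = "rsa_histogram")
}

#' Preston (log2 octave) histogram
#'
#' Bins an RSA into octaves: bin k counts the OTUs whose abundance lies in
#' the half-open interval `[2^k, 2^(k+1))`, with k starting at 0 (so
#' singletons fall in bin 0). No boundary splitting is applied; trailing
#' all-zero bins are trimmed. This binning is the comparison space of the
#' ABC acceptance test.
#'
#' @param x an `rsa_histogram`, an [abundance_vector], or a vector of
#'   positive integer abundances.
#' @return an object of class `preston_histogram`: a list with
#'   `bin_counts` (integer vector, bin 0 first) and `n_bins`.
#' @export
preston_histogram <- function(x) {
  if (inherits(x, "rsa_histogram")) {
    abundance <- rep(x$abundance, x$phi)
  } else if (inherits(x, "abundance_vector")) {
    abundance <- as.numeric(x$counts)
  } else {
    abundance <- as.numeric(x)
  }
  if (length(abundance) == 0 || any(abundance < 1))
    stop_input("abundances must be positive integers")
  bins <- preston_bin_index(abundance)
  bc <- tabulate(bins + 1L, nbins = max(bins) + 1L)
  structure(list(bin_counts = as.integer(bc), n_bins = length(bc)),
            class = "preston_histogram")
}

# octave index k = floor(log2(n)), computed exactly for integer n
preston_bin_index <- function(n) {
  k <- as.integer(floor(log2(n)))
  # guard against floating point at exact powers of two
  k[2^(k + 1) <= n] <- k[2^(k + 1) <= n] + 1L
  k[2^k > n] <- k[2^k > n] - 1L
  k
}

#' @export
print.preston_histogram <- function(x, ...) {
  labs <- sprintf("[%d,%d)", 2^(seq_len(x$n_bins) - 1), 2^seq_len(x$n_bins))
  cat("preston_histogram:\n")
  print(setNames(x$bin_counts, labs))
  invisible(x)
}
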