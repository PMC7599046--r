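#' Classical alpha-diversity indices of one sample
#'
#' Computes, from the relative abundances p_i of one sample, the Shannon
#' entropy H = -sum p_i ln p_i (nats), Pielou evenness J = H / ln(S), the
#' Simpson concentration lambda = sum p_i^2, and the Hill numbers of order 1
#' and 2 (Hill1 = exp(H), Hill2 = 1/lambda). For a single-species sample
#' J is undefined (returned as NA) while H = 0 and lambda = 1 are still
#' reported.
#'
#' @param av an [abundance_vector] or a vector of positive counts.
#' @return a one-row data.frame with columns `richness`, `shannon`,
#'   `pielou`, `simpson`, `hill1`, `hill2`.
#' @export
diversity_profile <- function(av) {
  counts <- if (inherits(av, "abundance_vector")) as.numeric(av$counts)
            else as.numeric(av)
  if (length(counts) == 0 || any(counts <= 0))
    stop_input("counts must be positive")
  p <- counts / sum(counts)
  H <- -sum(p * log(p))
  S <- length(p)
  lambda <- sum(p^2)
  data.frame(richness = S,
             shannon = H,
             pielou = if (S > 1) H / log(S) else NA_real_,
             simpson = lambda,
             hill1 = exp(H),
             hill2 = 1 / lambda)
}

#' Diversity indices for every sample of an OTU table
#'
#' @param table an [otu_table].
#' @return a data.frame with one row per sample (column `sample_id` first).
#' @export
diversity_table <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  rows <- lapply(table$sample_ids, function(sid) {
    cbind(data.frame(sample_id = sid),
          diversity_profile(abundance_vector(table, sid)))
  })
  do.call(rbind, rows)
}
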