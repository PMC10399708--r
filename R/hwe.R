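#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided conditional exact test: given the observed allele counts, the
#' probability of every possible heterozygote count is enumerated and the
#' p-value is the summed probability of all outcomes no more probable than
#' the observed one. This is the standard SNP-HWE exact test; it is the
#' "significant deviation from Hardy-Weinberg equilibrium" filter used in
#' panel design.
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts (each a non-negative
#'   scalar).
#' @return The exact two-sided p-value.
#' @examples
#' hwe_exact_test(50, 40, 10)     # close to HWE
#' hwe_exact_test(90, 0, 10)      # extreme heterozygote deficit
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  counts <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    abort("genotype counts must be non-negative integers.")
  }
  n <- sum(counts)
  if (n == 0) abort("genotype counts are all zero.")
  n_alt_alleles <- 2 * n_hom_alt + n_het
  rare <- min(n_alt_alleles, 2 * n - n_alt_alleles)
  if (rare == 0) return(1)

  # possible heterozygote counts share the parity of the rare-allele count
  h <- seq(rare %% 2, rare, by = 2)
  # log P(h) up to a constant: n! / (n_rr! n_ra! n_aa!) * 2^h with
  # n_rare_hom = (rare - h)/2, n_common_hom = n - h - (rare - h)/2
  n_rh <- (rare - h) / 2
  n_ch <- n - h - n_rh
  logp <- lgamma(n + 1) - lgamma(n_rh + 1) - lgamma(h + 1) - lgamma(n_ch + 1) +
    h * log(2)
  logp <- logp - max(logp)
  p <- exp(logp)
  p <- p / sum(p)
  obs <- min(n_het, rare)
  p_obs <- p[match(obs, h)]
  if (is.na(p_obs)) abort("inconsistent genotype counts.")
  min(1, sum(p[p <= p_obs * (1 + 1e-12)]))
}
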