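#' Genetic distances from one subject to the five reference populations
#'
#' The distance to population j is the mean negative log probability of the
#' subject's genotypes under Hardy-Weinberg equilibrium at population j's
#' allele frequencies, in nats per SNP:
#' \deqn{D_j = -\frac{1}{S'} \sum_l [g_l \ln p_{jl} + (2-g_l) \ln q_{jl}
#'   + g_l(2-g_l) \ln 2]}
#' where the sum runs over the subject's genotyped SNPs only. Missing
#' genotypes contribute nothing to the sum or to the count S'; they are never
#' imputed.
#'
#' @param g integer vector of reference-allele counts over the panel SNPs, in
#'   \{0, 1, 2\} with `NA` for missing.
#' @param panel a `triadmix_panel`.
#' @return list with `D` (named length-5 numeric, nats/SNP) and `S_prime`
#'   (number of genotyped SNPs used).
#' @export
subject_distances <- function(g, panel) {
  stopifnot(inherits(panel, "triadmix_panel"), length(g) == panel$S)
  res <- cohort_distance_matrix(matrix(as.integer(g), nrow = 1L), panel)
  if (res$S_prime[1L] == 0L) stop("subject has no genotyped SNPs")
  list(D = stats::setNames(res$D[1L, ], REF_POPS), S_prime = res$S_prime[1L])
}

# Distance engine: G is an n x S integer matrix (NA = missing). Returns D
# (n x 5) and S_prime (length n). Rows with S' = 0 get NA distances.
# Each subject's sums are accumulated over its own genotyped SNPs only, in
# panel order, so a subject's distances are bit-identical no matter which
# other subjects share the cohort (BLAS matrix products are not
# shape-reproducible, which would break that contract).
cohort_distance_matrix <- function(G, panel) {
  stopifnot(is.matrix(G), ncol(G) == panel$S)
  bad <- !is.na(G) & !(G %in% c(0L, 1L, 2L))
  if (any(bad)) stop("genotypes must be 0, 1, 2 or NA")
  LP <- log(panel$p)          # S x 5
  LQ <- log(1 - panel$p)
  n <- nrow(G)
  D <- matrix(NA_real_, n, 5L, dimnames = list(NULL, REF_POPS))
  S_prime <- integer(n)
  for (i in seq_len(n)) {
    idx <- which(!is.na(G[i, ]))
    S_prime[i] <- length(idx)
    if (length(idx) == 0L) next
    g <- as.numeric(G[i, idx])
    num <- colSums(g * LP[idx, , drop = FALSE] +
                     (2 - g) * LQ[idx, , drop = FALSE])
    num <- num + log(2) * sum(g == 1)
    D[i, ] <- -num / S_prime[i]
  }
  list(D = D, S_prime = S_prime)
}

#' Difference of genetic distances to two reference populations
#'
#' Computed directly from allele-frequency ratios:
#' \deqn{D_j - D_k = -\frac{1}{S'} \sum_l [g_l \ln(p_{jl}/p_{kl})
#'   + (2-g_l)\ln(q_{jl}/q_{kl})]}
#' The heterozygote ln 2 term of the distance cancels in the subtraction, so
#' the difference depends only on frequency ratios. This makes distance
#' differences robust to missing genotypes (their per-SNP expectation is
#' unchanged by any missingness pattern), which is why the South Asian vs
#' Latin American discriminator is reported without normalization.
#'
#' @param g integer genotype vector as in [subject_distances()].
#' @param panel a `triadmix_panel`.
#' @param j,k reference population indices in 1..5 (1 European, 2 African,
#'   3 East Asian, 4 South Asian, 5 Mexican/Latino).
#' @return scalar difference `D[j] - D[k]` in nats per SNP.
#' @export
distance_difference <- function(g, panel, j, k) {
  stopifnot(inherits(panel, "triadmix_panel"), length(g) == panel$S,
            j %in% 1:5, k %in% 1:5)
  ok <- !is.na(g)
  S_prime <- sum(ok)
  if (S_prime == 0L) stop("subject has no genotyped SNPs")
  if (j == k) return(0)
  gg <- as.numeric(g[ok])
  pj <- panel$p[ok, j]; pk <- panel$p[ok, k]
  qj <- 1 - pj; qk <- 1 - pk
  -(sum(gg * log(pj / pk) + (2 - gg) * log(qj / qk))) / S_prime
}
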