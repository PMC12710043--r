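#' Simulate a genotyped, phenotyped population
#'
#' Generates a panel of inbred-style genotypes with biallelic markers in
#' Hardy-Weinberg proportions at uniform-random minor allele frequencies,
#' and a phenotype built as genotypic value plus i.i.d. residual. The
#' genotypic value is the sum of the configured causal-marker contributions
#' and a polygenic genotype effect; each variance component is standardized
#' empirically so the realized ratio of genotypic to total variance equals
#' `h2_target` exactly, and the realized components are recorded as ground
#' truth (including the broad-sense heritability implied at `n = 2`
#' replicates, [broad_sense_H()]).
#'
#' @param n_geno number of genotypes.
#' @param reps plants per genotype.
#' @param n_markers marker count.
#' @param causal optional data frame with columns `marker` (index) and
#'   `frac` (fraction of total phenotypic variance explained); the summed
#'   fractions must not exceed `h2_target`.
#' @param h2_target per-observation genotypic variance fraction
#'   `sigma_G^2 / (sigma_G^2 + sigma_R^2)`, in `[0, 1)`.
#' @param maf_range range of minor allele frequencies.
#' @param inbreeding inbreeding coefficient F in `[0, 1]`: each call is
#'   homozygous (dosage `2 * Bernoulli(p)`) with probability F and drawn
#'   from Hardy-Weinberg proportions otherwise, so the expected
#'   heterozygote fraction is `(1 - F) * 2 p (1 - p)`. The default 0 is
#'   plain Hardy-Weinberg; association panels of inbred lines are emulated
#'   with F near 1 (which also keeps markers below the 10 percent
#'   heterozygosity QC filter).
#' @param seed RNG seed; the only source of randomness.
#' @return list of class `sim_population`: `genotypes` (markers x genotypes
#'   dosage matrix 0/1/2), `marker_info` (chrom, pos, id, maf), `phenotypes`
#'   (plant_id, genotype_id, value), `truth` (variance components,
#'   heritabilities, causal markers).
#' @export
make_population <- function(n_geno, reps = 2, n_markers = 1000,
                            causal = NULL, h2_target = 0.25,
                            maf_range = c(0.05, 0.5), inbreeding = 0,
                            seed = 1) {
  if (h2_target < 0 || h2_target >= 1)
    stop("h2_target must lie in [0, 1)")
  if (!is.null(causal)) {
    if (any(causal$marker > n_markers | causal$marker < 1))
      stop("causal marker indices must be within 1..n_markers")
    if (sum(causal$frac) > h2_target + 1e-12)
      stop("causal variance fractions cannot exceed h2_target")
  }
  if (inbreeding < 0 || inbreeding > 1)
    stop("inbreeding must lie in [0, 1]")
  set.seed(seed)
  maf <- stats::runif(n_markers, maf_range[1], maf_range[2])
  p <- rep(maf, n_geno)
  geno <- matrix(stats::rbinom(n_markers * n_geno, 2, p),
                 nrow = n_markers, ncol = n_geno)
  if (inbreeding > 0) {
    hom <- stats::runif(n_markers * n_geno) < inbreeding
    geno[hom] <- 2L * stats::rbinom(sum(hom), 1, p[hom])
  }
  rownames(geno) <- sprintf("m%04d", seq_len(n_markers))
  colnames(geno) <- sprintf("g%04d", seq_len(n_geno))
  marker_info <- data.frame(chrom = rep(1L, n_markers),
                            pos = seq_len(n_markers) * 100L,
                            id = rownames(geno), maf = maf)

  std <- function(v, target_var) {
    s <- stats::sd(v)
    if (s < 1e-12) {
      if (target_var > 0) stop("degenerate component: zero sampled variance")
      return(rep(0, length(v)))
    }
    (v - mean(v)) / s * sqrt(target_var)
  }
  sigma_g2 <- h2_target
  sigma_r2 <- 1 - h2_target
  gval <- rep(0, n_geno)
  causal_frac <- 0
  if (!is.null(causal) && nrow(causal)) {
    for (r in seq_len(nrow(causal))) {
      x <- geno[causal$marker[r], ]
      gval <- gval + std(x, causal$frac[r])
    }
    causal_frac <- sum(causal$frac)
  }
  poly_var <- sigma_g2 - causal_frac
  if (poly_var > 0) gval <- gval + std(stats::rnorm(n_geno), poly_var)
  # standardize the total genotypic value so the realized ratio is exact
  if (sigma_g2 > 0) gval <- std(gval, sigma_g2) else gval <- rep(0, n_geno)

  n_obs <- n_geno * reps
  gval_rep <- gval[rep(seq_len(n_geno), each = reps)]
  resid <- rep(0, n_obs)
  if (sigma_r2 > 0) {
    resid <- stats::rnorm(n_obs)
    # orthogonalize against the genotypic values so the realized variance
    # decomposition is exact by construction
    if (stats::sd(gval_rep) > 0)
      resid <- stats::resid(stats::lm(resid ~ gval_rep))
    resid <- std(resid, sigma_r2)
  }
  genotype_id <- rep(colnames(geno), each = reps)
  pheno <- data.frame(plant_id = sprintf("p%05d", seq_len(n_obs)),
                      genotype_id = genotype_id,
                      value = gval_rep + resid)
  truth <- list(sigma_g2 = sigma_g2, sigma_r2 = sigma_r2,
                h2_obs = h2_target,
                H_n2 = broad_sense_H(sigma_g2, sigma_r2, n = 2),
                causal = causal)
  structure(list(genotypes = geno, marker_info = marker_info,
                 phenotypes = pheno, truth = truth, seed = seed),
            class = "sim_population")
}

#' @export
print.sim_population <- function(x, ...) {
  cat("<sim_population>", ncol(x$genotypes), "genotypes x",
      length(unique(x$phenotypes$plant_id)) / ncol(x$genotypes),
      "reps;", nrow(x$genotypes), "markers\n")
  cat("  sigma_G2 =", round(x$truth$sigma_g2, 3),
      " sigma_R2 =", round(x$truth$sigma_r2, 3),
      " H(n=2) =", round(x$truth$H_n2, 3), "\n")
  invisible(x)
}

#' Per-observation variance ratio for a target broad-sense heritability
#'
#' Inverts Eq.-style broad-sense heritability at `n` replicates,
#' `H = s2g / (s2g + s2r / n)`, to the per-observation ratio
#' `h2 = s2g / (s2g + s2r)` used by [make_population()].
#'
#' @param H desired broad-sense heritability in `[0, 1)`.
#' @param n replication divisor.
#' @return per-observation variance ratio.
#' @export
h2_for_H <- function(H, n = 2) {
  H / (n - (n - 1) * H)
}
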