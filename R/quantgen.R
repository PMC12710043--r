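#' Summary metrics of lower-canopy phyllotaxy deviations
#'
#' Per-plant quantitative summaries of the deviation series over angle
#' indices (1..4 by default) and timepoints. The headline metric is the
#' median of the lower-four deviations across all timepoints
#' (`median_all`); per-angle-index and per-timepoint summaries, the
#' maximum, and single angle-by-timepoint values are also available.
#'
#' @param table data frame with columns `plant_id`, `genotype_id`,
#'   `timepoint`, `angle_index`, `Phi`.
#' @param metrics character vector from `"median_all"`, `"mean_all"`,
#'   `"max_all"`, `"median_by_angle"`, `"mean_by_angle"`,
#'   `"median_by_timepoint"`, `"single"` (one column per
#'   angle-by-timepoint cell).
#' @param max_angle restrict to angle indices at most this (default 4, the
#'   lower four phyllotaxic angles from five leaves).
#' @return data frame with one row per plant (`plant_id`, `genotype_id`,
#'   one column per requested metric).
#' @export
summary_metrics <- function(table,
                            metrics = c("median_all", "mean_all", "max_all",
                                        "median_by_angle", "mean_by_angle",
                                        "median_by_timepoint"),
                            max_angle = 4) {
  if (!length(metrics)) stop("at least one metric must be selected")
  known <- c("median_all", "mean_all", "max_all", "median_by_angle",
             "mean_by_angle", "median_by_timepoint", "single")
  bad <- setdiff(metrics, known)
  if (length(bad)) stop("unknown metrics: ", paste(bad, collapse = ", "))
  tb <- table[table$angle_index <= max_angle, , drop = FALSE]
  plants <- unique(tb[, c("plant_id", "genotype_id")])
  rownames(plants) <- NULL
  out <- plants
  grab <- function(pid) tb[tb$plant_id == pid, , drop = FALSE]
  per_plant <- lapply(plants$plant_id, grab)
  add <- function(name, vals) {
    out[[name]] <<- vals
  }
  if ("median_all" %in% metrics)
    add("median_all", vapply(per_plant, function(d)
      stats::median(d$Phi), numeric(1)))
  if ("mean_all" %in% metrics)
    add("mean_all", vapply(per_plant, function(d) mean(d$Phi), numeric(1)))
  if ("max_all" %in% metrics)
    add("max_all", vapply(per_plant, function(d)
      if (nrow(d)) max(d$Phi) else NA_real_, numeric(1)))
  if (any(c("median_by_angle", "mean_by_angle") %in% metrics)) {
    for (ai in sort(unique(tb$angle_index))) {
      if ("median_by_angle" %in% metrics)
        add(paste0("median_angle_", ai), vapply(per_plant, function(d)
          stats::median(d$Phi[d$angle_index == ai]), numeric(1)))
      if ("mean_by_angle" %in% metrics)
        add(paste0("mean_angle_", ai), vapply(per_plant, function(d) {
          v <- d$Phi[d$angle_index == ai]
          if (length(v)) mean(v) else NA_real_
        }, numeric(1)))
    }
  }
  if ("median_by_timepoint" %in% metrics) {
    for (tp in sort(unique(tb$timepoint)))
      add(paste0("median_tp_", tp), vapply(per_plant, function(d)
        stats::median(d$Phi[d$timepoint == tp]), numeric(1)))
  }
  if ("single" %in% metrics) {
    for (tp in sort(unique(tb$timepoint)))
      for (ai in sort(unique(tb$angle_index)))
        add(sprintf("Phi_%d_tp_%s", ai, tp), vapply(per_plant, function(d) {
          v <- d$Phi[d$timepoint == tp & d$angle_index == ai]
          if (length(v)) v[1] else NA_real_
        }, numeric(1)))
  }
  out
}

#' Flag outliers by the 1.5 x IQR rule
#'
#' A value is flagged iff it exceeds `Q3 + k * IQR` or falls below
#' `Q1 - k * IQR`. With constant input the IQR is zero and every value not
#' exactly equal to the quartiles is flagged.
#'
#' @param values numeric vector (>= 4 values).
#' @param k multiplier (default 1.5).
#' @return logical flags.
#' @export
iqr_outlier_flag <- function(values, k = 1.5) {
  if (length(values) < 4) stop("need at least four values")
  q <- stats::quantile(values, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
  iqr <- q[2] - q[1]
  values > q[2] + k * iqr | values < q[1] - k * iqr
}

#' Broad-sense heritability from variance components
#'
#' `H = sigma_G^2 / (sigma_G^2 + sigma_R^2 / n)` with `n` the replication
#' divisor (default 2, the minimum replication per genotype).
#'
#' @param sigma_g2,sigma_r2 non-negative variance components.
#' @param n replication divisor.
#' @return heritability in `[0, 1]`.
#' @export
broad_sense_H <- function(sigma_g2, sigma_r2, n = 2) {
  if (sigma_g2 < 0 || sigma_r2 < 0) stop("variance components must be >= 0")
  if (sigma_g2 + sigma_r2 == 0) return(0)
  sigma_g2 / (sigma_g2 + sigma_r2 / n)
}

#' Estimate broad-sense heritability from replicated phenotypes
#'
#' Fits the one-way random-effects model `Y = mu + delta_i + eps_ij` with
#' genotype as the random effect (REML via lme4; a method-of-moments
#' fallback with negative estimates truncated at zero is available and used
#' automatically if the REML fit fails), then plugs the variance components
#' into [broad_sense_H()]. Genotypes with more than `cap_replicates`
#' replicates contribute a seeded random subsample of that size.
#'
#' @param values phenotype per plant.
#' @param genotype genotype id per plant.
#' @param n replication divisor (default 2).
#' @param method `"reml"` or `"mom"`.
#' @param cap_replicates optional maximum replicates per genotype.
#' @param seed seed for the replicate subsampling.
#' @return object of class `heritability_fit` with `H`, `sigma_g2`,
#'   `sigma_r2`, `mu`, `n`, `method`, `n_geno`, `n_obs`.
#' @export
heritability <- function(values, genotype, n = 2,
                         method = c("reml", "mom"),
                         cap_replicates = NULL, seed = 1) {
  method <- match.arg(method)
  genotype <- as.character(genotype)
  ok <- !is.na(values) & !is.na(genotype)
  values <- values[ok]; genotype <- genotype[ok]
  if (length(unique(genotype)) < 2) stop("need at least two genotypes")
  if (!is.null(cap_replicates)) {
    set.seed(seed)
    keep <- unlist(lapply(split(seq_along(values), genotype), function(ix) {
      if (length(ix) > cap_replicates) sample(ix, cap_replicates) else ix
    }), use.names = FALSE)
    keep <- sort(keep)
    values <- values[keep]; genotype <- genotype[keep]
  }
  reps <- table(genotype)
  if (max(reps) < 2)
    stop("all genotypes unreplicated: genotypic variance unidentifiable")
  comp <- NULL
  if (method == "reml") {
    fit <- tryCatch(
      suppressMessages(suppressWarnings(
        lme4::lmer(values ~ 1 + (1 | genotype),
                   data = data.frame(values = values, genotype = genotype),
                   control = lme4::lmerControl(check.conv.singular =
                                                 "ignore")))),
      error = function(e) NULL)
    if (!is.null(fit)) {
      vc <- as.data.frame(lme4::VarCorr(fit))
      comp <- list(g = vc$vcov[vc$grp == "genotype"],
                   r = vc$vcov[vc$grp == "Residual"],
                   mu = unname(lme4::fixef(fit)[1]))
    } else method <- "mom"
  }
  if (is.null(comp)) {
    comp <- mom_components(values, genotype)
  }
  H <- broad_sense_H(max(comp$g, 0), max(comp$r, 0), n = n)
  structure(list(H = H, sigma_g2 = max(comp$g, 0),
                 sigma_r2 = max(comp$r, 0), mu = comp$mu, n = n,
                 method = method,
                 n_geno = length(unique(genotype)),
                 n_obs = length(values)),
            class = "heritability_fit")
}

# unbalanced one-way ANOVA method of moments
mom_components <- function(values, genotype) {
  k <- length(unique(genotype))
  N <- length(values)
  ni <- table(genotype)
  means <- tapply(values, genotype, mean)
  grand <- mean(values)
  ssb <- sum(ni * (means - grand)^2)
  ssw <- sum((values - means[genotype])^2)
  msb <- ssb / (k - 1)
  msw <- ssw / max(N - k, 1)
  n0 <- (N - sum(ni^2) / N) / (k - 1)
  list(g = max((msb - msw) / n0, 0), r = msw, mu = grand)
}

#' @export
print.heritability_fit <- function(x, ...) {
  cat("<heritability_fit> H =", round(x$H, 4), " (n =", x$n, ",",
      x$method, ")\n")
  cat("  sigma_G2 =", signif(x$sigma_g2, 4),
      " sigma_R2 =", signif(x$sigma_r2, 4),
      " genotypes:", x$n_geno, " plants:", x$n_obs, "\n")
  invisible(x)
}

#' @export
coef.heritability_fit <- function(object, ...) {
  c(H = object$H, sigma_g2 = object$sigma_g2, sigma_r2 = object$sigma_r2,
    mu = object$mu)
}

#' Marker quality control
#'
#' Keeps markers that are biallelic SNPs with missing-call fraction below
#' 0.30 (over all individuals), heterozygote fraction below 0.10 (over
#' non-missing calls), and minor allele frequency at least 0.05 (over
#' non-missing calls). Exclusion counts per filter are reported in the
#' order applied; each marker is attributed to the first filter it fails.
#'
#' @param geno genotype object: a list with `dosage` (markers x individuals,
#'   values 0/1/2/NA) and `info` (with `is_biallelic`, `is_indel`), or a
#'   bare dosage matrix (then all markers are assumed biallelic SNPs).
#' @param max_missing,max_het,min_maf filter thresholds.
#' @return list of class `marker_qc`: filtered `dosage`, `info`, `keep`
#'   flags, `exclusions` named counts.
#' @export
marker_qc <- function(geno, max_missing = 0.30, max_het = 0.10,
                      min_maf = 0.05) {
  if (is.matrix(geno)) {
    dosage <- geno
    info <- data.frame(id = rownames(geno) %||% as.character(seq_len(nrow(geno))),
                       is_biallelic = TRUE, is_indel = FALSE)
  } else {
    dosage <- geno$dosage
    info <- geno$info
  }
  m <- nrow(dosage)
  n <- ncol(dosage)
  miss <- rowSums(is.na(dosage)) / n
  nm <- n - rowSums(is.na(dosage))
  het <- rowSums(dosage == 1, na.rm = TRUE) / pmax(nm, 1)
  p_alt <- rowSums(dosage, na.rm = TRUE) / (2 * pmax(nm, 1))
  maf <- pmin(p_alt, 1 - p_alt)
  fail_biallelic <- !info$is_biallelic
  fail_indel <- info$is_indel & !fail_biallelic
  fail_missing <- miss >= max_missing & !fail_biallelic & !fail_indel
  fail_het <- het >= max_het & !(fail_biallelic | fail_indel | fail_missing)
  fail_maf <- maf < min_maf &
    !(fail_biallelic | fail_indel | fail_missing | fail_het)
  keep <- !(fail_biallelic | fail_indel | fail_missing | fail_het | fail_maf)
  if (!any(keep)) warning("no markers pass quality control")
  structure(list(dosage = dosage[keep, , drop = FALSE],
                 info = info[keep, , drop = FALSE],
                 keep = keep,
                 exclusions = c(not_biallelic = sum(fail_biallelic),
                                indel = sum(fail_indel),
                                missing = sum(fail_missing),
                                heterozygosity = sum(fail_het),
                                maf = sum(fail_maf))),
            class = "marker_qc")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.marker_qc <- function(x, ...) {
  cat("<marker_qc>", sum(x$keep), "of", length(x$keep), "markers kept\n")
  print(x$exclusions)
  invisible(x)
}

#' Bonferroni threshold over effective markers
#'
#' `alpha / Me` with `Me` the estimated number of effective independent
#' markers.
#'
#' @param alpha family-wise error rate.
#' @param me effective marker count (> 0).
#' @return p-value threshold.
#' @export
bonferroni_threshold <- function(alpha = 0.05, me) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (me <= 0) stop("effective marker count must be > 0")
  alpha / me
}

#' Engine iteration threshold
#'
#' `alpha` divided by the ratio of effective to total markers,
#' `alpha * M / Me`, used as the internal iteration threshold of
#' model-selection scan engines.
#'
#' @param alpha family-wise error rate.
#' @param me effective marker count.
#' @param m total marker count (>= me).
#' @return iteration threshold.
#' @export
iteration_threshold <- function(alpha = 0.05, me, m) {
  if (me <= 0 || me > m) stop("need 0 < me <= m")
  alpha * m / me
}

#' Single-marker association scan
#'
#' Per-marker two-sided p-value from a linear model of the phenotype on the
#' dosage, optionally adjusted for covariates (e.g. genotype-matrix
#' principal components) by residualizing both sides. Missing dosages are
#' dropped per marker; markers with fewer than three non-missing pairs or
#' zero dosage variance yield `NA`. A constant phenotype yields p = 1 for
#' every marker, with a warning.
#'
#' @param geno markers x individuals dosage matrix.
#' @param y phenotype vector aligned to the columns of `geno`.
#' @param covariates optional numeric matrix of per-individual covariates.
#' @param n_pc alternatively, use this many principal components of the
#'   dosage matrix as covariates.
#' @return numeric vector of p-values, one per marker.
#' @export
scan_markers <- function(geno, y, covariates = NULL, n_pc = 0) {
  if (ncol(geno) != length(y)) stop("phenotype length must match individuals")
  use <- !is.na(y)
  geno <- geno[, use, drop = FALSE]
  if (!is.null(covariates))
    covariates <- as.matrix(covariates)[use, , drop = FALSE]
  y <- y[use]
  n <- length(y)
  if (stats::sd(y) == 0) {
    warning("constant phenotype: all p-values set to 1")
    return(rep(1, nrow(geno)))
  }
  if (n_pc > 0 && is.null(covariates)) {
    gc <- t(geno)
    gc[is.na(gc)] <- mean(gc, na.rm = TRUE)
    covariates <- stats::prcomp(gc, center = TRUE, scale. = FALSE)$x[,
      seq_len(min(n_pc, n - 2)), drop = FALSE]
  }
  q <- 0
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    qrx <- qr(cbind(1, covariates))
    y <- qr.resid(qrx, y)
    q <- ncol(covariates)
  }
  p <- rep(NA_real_, nrow(geno))
  complete <- !apply(geno, 1, anyNA)
  if (any(complete)) {
    G <- geno[complete, , drop = FALSE]
    if (q > 0) G <- t(qr.resid(qrx, t(G)))
    gm <- rowMeans(G)
    gc <- G - gm
    gss <- rowSums(gc^2)
    yc <- y - mean(y)
    yss <- sum(yc^2)
    r <- as.numeric(gc %*% yc) / sqrt(pmax(gss * yss, 1e-300))
    df <- n - 2 - q
    ok <- gss > 1e-12 & df > 0
    tt <- r * sqrt(df / pmax(1 - r^2, 1e-300))
    pv <- 2 * stats::pt(-abs(tt), df)
    pv[r^2 >= 1] <- 0
    pv[!ok] <- NA_real_
    p[complete] <- pv
  }
  for (i in which(!complete)) {
    x <- geno[i, ]
    ok <- !is.na(x)
    if (sum(ok) < max(3, q + 3) || stats::sd(x[ok]) == 0) next
    xi <- x[ok]; yi <- y[ok]
    r <- stats::cor(xi, yi)
    df <- sum(ok) - 2 - q
    tt <- r * sqrt(df / max(1 - r^2, 1e-300))
    p[i] <- 2 * stats::pt(-abs(tt), df)
  }
  p
}

#' Resampling model inclusion probability (RMIP) association
#'
#' Runs the scan engine `n_iter` times, each time randomly masking
#' `mask_frac` of the phenotype records (plant-level records; masked plants
#' are dropped and the remaining records averaged per genotype), and counts
#' for each marker the iterations in which its p-value beats the Bonferroni
#' threshold `alpha / Me`. RMIP is that count divided by `n_iter`; markers
#' at or above `rmip_call` are flagged as called. Each iteration draws its
#' mask from a seeded per-iteration stream, so results are reproducible and
#' independent of engine internals.
#'
#' @param geno markers x genotypes dosage matrix.
#' @param pheno data frame with `genotype_id` and `value` columns (one row
#'   per plant), or a numeric vector aligned to genotype columns.
#' @param marker_info optional data frame (chrom, pos, id) aligned to
#'   markers.
#' @param alpha family-wise error rate (default 0.05).
#' @param me effective marker count (default: the number of markers).
#' @param n_iter iterations (default 100).
#' @param mask_frac fraction of phenotype records masked per iteration
#'   (default 0.10).
#' @param rmip_call calling threshold on RMIP (default 0.1; a secondary
#'   reporting threshold such as 0.02 can be applied to the returned
#'   table).
#' @param seed RNG seed.
#' @param engine scan function with the signature of [scan_markers()].
#' @param ... forwarded to the engine.
#' @return data frame of class `rmip_table`: `chrom`, `pos`, `id`, `hits`,
#'   `rmip`, `called`, with the configuration in attributes.
#' @export
rmip <- function(geno, pheno, marker_info = NULL, alpha = 0.05, me = NULL,
                 n_iter = 100, mask_frac = 0.10, rmip_call = 0.1, seed = 1,
                 engine = scan_markers, ...) {
  if (mask_frac <= 0 || mask_frac >= 1) stop("mask_frac must be in (0, 1)")
  if (is.null(me)) me <- nrow(geno)
  thr <- bonferroni_threshold(alpha, me)
  if (is.numeric(pheno) && is.null(dim(pheno))) {
    pheno <- data.frame(genotype_id = colnames(geno) %||%
                          as.character(seq_len(ncol(geno))),
                        value = pheno)
  }
  gids <- colnames(geno) %||% as.character(seq_len(ncol(geno)))
  if (!all(pheno$genotype_id %in% gids))
    stop("phenotype genotype ids missing from the genotype matrix")
  N <- nrow(pheno)
  n_mask <- round(mask_frac * N)
  if (N - n_mask < 10) stop("masking would leave fewer than 10 records")
  set.seed(seed)
  iter_seeds <- sample.int(.Machine$integer.max - 1L, n_iter)
  hits <- integer(nrow(geno))
  for (it in seq_len(n_iter)) {
    set.seed(iter_seeds[it])
    masked <- sample.int(N, n_mask)
    keep <- pheno[-masked, , drop = FALSE]
    means <- tapply(keep$value, keep$genotype_id, mean)
    y <- rep(NA_real_, ncol(geno))
    names(y) <- gids
    y[names(means)] <- as.numeric(means)
    p <- engine(geno, y, ...)
    hits <- hits + as.integer(!is.na(p) & p < thr)
  }
  info <- marker_info %||%
    data.frame(chrom = NA_integer_, pos = seq_len(nrow(geno)),
               id = rownames(geno) %||% as.character(seq_len(nrow(geno))))
  out <- data.frame(chrom = info$chrom, pos = info$pos, id = info$id,
                    hits = hits, rmip = hits / n_iter,
                    called = hits / n_iter >= rmip_call)
  attr(out, "config") <- list(alpha = alpha, me = me, threshold = thr,
                              n_iter = n_iter, mask_frac = mask_frac,
                              rmip_call = rmip_call, seed = seed)
  class(out) <- c("rmip_table", "data.frame")
  out
}

#' @export
print.rmip_table <- function(x, ...) {
  cfg <- attr(x, "config")
  cat("<rmip_table>", nrow(x), "markers,", cfg$n_iter, "iterations,",
      "p threshold", signif(cfg$threshold, 3), "\n")
  called <- x[x$called, , drop = FALSE]
  if (nrow(called)) {
    cat("called (RMIP >=", cfg$rmip_call, "):\n")
    print.data.frame(called[order(-called$rmip), ], row.names = FALSE)
  } else cat("no markers called at RMIP >=", cfg$rmip_call, "\n")
  invisible(x)
}

#' @export
plot.rmip_table <- function(x, ...) {
  cfg <- attr(x, "config")
  graphics::plot(seq_len(nrow(x)), x$rmip, type = "h", xlab = "marker",
                 ylab = "RMIP", ylim = c(0, 1), ...)
  graphics::abline(h = cfg$rmip_call, lty = 2)
  invisible(x)
}

#' Linkage disequilibrium between two markers
#'
#' Squared Pearson correlation of the dosage vectors over shared
#' non-missing individuals. Invariant to allele-coding complements
#' (`dosage -> 2 - dosage`). Undefined (NA) with zero variance or fewer
#' than three shared calls.
#'
#' @param geno markers x individuals dosage matrix.
#' @param i,j marker indices.
#' @return squared correlation in `[0, 1]`, or `NA`.
#' @export
ld_r2 <- function(geno, i, j) {
  a <- geno[i, ]; b <- geno[j, ]
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 3) return(NA_real_)
  if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) return(NA_real_)
  stats::cor(a[ok], b[ok])^2
}
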