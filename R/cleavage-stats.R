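#' Median-of-ratios size factors
#'
#' Per-sample scale factors computed from the upstream ("total RNA") window
#' counts only. Downstream counts are excluded by default because for
#' efficiently cleaved genes they sit near zero and, more importantly, they
#' carry the readthrough signal under test; normalizing on them would absorb
#' part of the effect. For each gene with an all-positive row, the ratio of
#' each sample's count to the gene's geometric mean is formed; the size
#' factor is the per-sample median of those ratios.
#'
#' @param x A [pas_counts()] matrix.
#' @param features `"upstream"` (default) or `"all"` (stack both regions).
#' @return Named numeric vector of positive size factors, one per sample.
#' @export
estimate_size_factors <- function(x, features = c("upstream", "all")) {
  features <- match.arg(features)
  m <- if (features == "upstream") x$up else rbind(x$up, x$down)
  log_m <- log(m)
  log_geo <- rowMeans(log_m)
  usable <- is.finite(log_geo)
  if (!any(usable)) {
    stop("no gene has positive upstream counts in every sample; ",
         "cannot form median-of-ratios size factors ",
         "(consider features = \"all\" or a pseudo-reference)")
  }
  sf <- apply(log_m[usable, , drop = FALSE], 2L,
              function(lc) exp(stats::median(lc - log_geo[usable])))
  sf
}

#' Per-gene negative-binomial dispersion
#'
#' Method-of-moments estimate from size-factor-normalized counts, pooled over
#' the four condition x region cells: `alpha = sum(var_c - mean_c) /
#' sum(mean_c^2)` across cells `c`, floored at `1e-8` (Poisson-like genes),
#' then shrunk toward a mean-dispersion trend `a0 + a1/mean` fitted across
#' genes. With few replicates the per-gene estimate is very noisy, so the
#' trend carries most of the weight by default. A single dispersion is shared
#' between a gene's two regions: two replicates per condition cannot support
#' region-specific dispersions.
#'
#' @param x A [pas_counts()] matrix.
#' @param sf Size factors from [estimate_size_factors()].
#' @param shrink_weight Weight on the fitted trend in the final estimate
#'   (default 0.8; 0 = raw method-of-moments, 1 = trend only).
#' @param fixed If non-`NULL`, a known dispersion (scalar or per-gene vector)
#'   returned as-is; used in calibration studies where truth is known.
#' @return Named numeric vector of per-gene dispersions.
#' @export
estimate_dispersion <- function(x, sf, shrink_weight = 0.8, fixed = NULL) {
  genes <- rownames(x$up)
  if (!is.null(fixed)) {
    a <- rep_len(fixed, length(genes))
    names(a) <- genes
    return(a)
  }
  if (ncol(x$up) < 2L) stop("dispersion estimation needs >= 2 samples")
  floor_a <- 1e-8
  conds <- unique(x$samples$condition)
  nup <- sweep(x$up, 2L, sf, "/")
  ndown <- sweep(x$down, 2L, sf, "/")
  num <- 0; den <- 0
  for (cc in conds) {
    j <- x$samples$condition == cc
    if (sum(j) < 2L) next
    for (m in list(nup[, j, drop = FALSE], ndown[, j, drop = FALSE])) {
      mu <- rowMeans(m)
      v <- apply(m, 1L, stats::var)
      num <- num + (v - mu)
      den <- den + mu^2
    }
  }
  raw <- pmax(num / pmax(den, .Machine$double.eps), floor_a)
  base_mean <- rowMeans(nup)
  # parametric trend alpha(mu) = a0 + a1/mu on informative genes
  ok <- base_mean > 0 & raw > floor_a & is.finite(raw)
  trend <- rep(stats::median(raw[is.finite(raw)]), length(raw))
  if (sum(ok) >= 10L) {
    fit <- stats::lm(raw[ok] ~ I(1 / base_mean[ok]))
    a0 <- max(unname(stats::coef(fit)[1L]), floor_a)
    a1 <- max(unname(stats::coef(fit)[2L]), 0)
    trend <- a0 + a1 / pmax(base_mean, 1e-8)
  }
  a <- pmax((1 - shrink_weight) * raw + shrink_weight * trend, floor_a)
  names(a) <- genes
  a
}

# IRLS fit of a NB GLM with log link, fixed dispersion and offsets.
# X: design matrix; y: counts; offset: log size factors; alpha: dispersion.
# Returns coefficients, their covariance from the Fisher information, and a
# convergence flag.
nb_glm_irls <- function(y, X, offset, alpha, max_iter = 100L, tol = 1e-10) {
  # init from regularized log of offset-corrected counts
  beta <- tryCatch(
    stats::lm.fit(X, log(y / exp(offset) + 0.5))$coefficients,
    error = function(e) rep(0, ncol(X)))
  beta[!is.finite(beta)] <- 0
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta) + offset
    eta <- pmin(pmax(eta, -30), 30)
    mu <- exp(eta)
    w <- mu / (1 + alpha * mu)          # Fisher weights, log link, NB2
    z <- (eta - offset) + (y - mu) / mu  # working response
    fit <- tryCatch(stats::lm.wfit(X, z, w), error = function(e) NULL)
    if (is.null(fit) || anyNA(fit$coefficients)) {
      return(list(beta = rep(NA_real_, ncol(X)), cov = NULL,
                  converged = FALSE))
    }
    new_beta <- fit$coefficients
    delta <- max(abs(new_beta - beta))
    beta <- new_beta
    if (delta < tol) { converged <- TRUE; break }
  }
  eta <- drop(X %*% beta) + offset
  mu <- exp(pmin(pmax(eta, -30), 30))
  w <- mu / (1 + alpha * mu)
  info <- crossprod(X * w, X)
  cov <- tryCatch(solve(info), error = function(e) NULL)
  list(beta = beta, cov = cov, converged = converged && !is.null(cov))
}

#' Per-gene interaction Wald test of differential PAS cleavage
#'
#' For each gene, the counts of the two regions across all samples are
#' modeled as negative binomial with a log-linear mean
#' `log mu = beta0 + beta1*condition + beta2*region +
#' beta3*condition*region + log(sf)`, where `region` is 1 for the downstream
#' (uncleaved) window and `condition` is 1 for the treated group. `beta3` is
#' the difference between the downstream and the upstream between-condition
#' fold regulation on the natural-log scale; `delta_log2 = beta3/ln 2` equals
#' `log2fc_down - log2fc_up`, the change in the uncleaved/total ratio. The
#' Wald statistic `beta3/se` is referred to a standard normal.
#'
#' Genes where an entire condition x region cell is zero cannot support the
#' saturated mean model without fabricating infinite fold changes; they are
#' reported with `converged = FALSE` and a missing p-value unless
#' `pseudo_count` is set, in which case that constant is added to every cell
#' of the offending genes.
#'
#' @param x A [pas_counts()] matrix (two conditions).
#' @param sf Size factors from [estimate_size_factors()].
#' @param dispersion Per-gene dispersions from [estimate_dispersion()]
#'   (scalar recycled).
#' @param pseudo_count Count added to every observation of genes with an
#'   all-zero cell (default 0 = disabled, such genes get `NA` p-values).
#' @return data.frame: `gene_id`, `baseMean_up`, `baseMean_down`,
#'   `log2fc_up`, `log2fc_down`, `delta_log2`, `se`, `wald_z`, `p_value`,
#'   `q_value` (Benjamini-Hochberg over the non-missing p-values),
#'   `converged`.
#' @export
test_differential_cleavage <- function(x, sf, dispersion,
                                       pseudo_count = 0) {
  samples <- x$samples
  conds <- unique(samples$condition)
  if (length(conds) != 2L)
    stop("expected exactly 2 conditions, got: ",
         paste(conds, collapse = ", "))
  ref <- if ("control" %in% conds) "control" else conds[1L]
  cond01 <- as.integer(samples$condition != ref)
  genes <- rownames(x$up)
  alpha_g <- rep_len(dispersion, length(genes))

  n <- nrow(samples)
  cond_v <- rep(cond01, 2L)
  region_v <- rep(c(0L, 1L), each = n)  # 0 upstream, 1 downstream
  X <- cbind(intercept = 1, condition = cond_v, region = region_v,
             interaction = cond_v * region_v)
  offset <- rep(log(sf), 2L)
  ln2 <- log(2)

  nup <- sweep(x$up, 2L, sf, "/")
  ndown <- sweep(x$down, 2L, sf, "/")

  out <- data.frame(gene_id = genes,
                    baseMean_up = rowMeans(nup),
                    baseMean_down = rowMeans(ndown),
                    log2fc_up = NA_real_, log2fc_down = NA_real_,
                    delta_log2 = NA_real_, se = NA_real_,
                    wald_z = NA_real_, p_value = NA_real_,
                    q_value = NA_real_, converged = FALSE)

  cell <- interaction(cond_v, region_v)
  for (g in seq_along(genes)) {
    y <- c(x$up[g, ], x$down[g, ])
    zero_cell <- any(tapply(y, cell, function(v) all(v == 0)))
    if (zero_cell) {
      if (pseudo_count > 0) y <- y + pseudo_count else next
    }
    fit <- nb_glm_irls(y, X, offset, alpha_g[g])
    if (!fit$converged) next
    b <- fit$beta
    se_int <- sqrt(fit$cov["interaction", "interaction"])
    out$log2fc_up[g] <- b["condition"] / ln2
    out$log2fc_down[g] <- (b["condition"] + b["interaction"]) / ln2
    out$delta_log2[g] <- b["interaction"] / ln2
    out$se[g] <- se_int / ln2
    out$wald_z[g] <- b["interaction"] / se_int
    out$p_value[g] <- 2 * stats::pnorm(-abs(out$wald_z[g]))
    out$converged[g] <- TRUE
  }
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}

#' Classify per-gene cleavage regulation at a significance threshold
#'
#' Positive `delta_log2` (downstream regulated up relative to upstream, i.e.
#' a larger uncleaved/total ratio in the treated condition) with `p < alpha`
#' is called `repressed_cleavage`; the mirror case `increased_cleavage`;
#' everything else, including missing p-values, `unchanged`.
#'
#' @param results Output of [test_differential_cleavage()].
#' @param alpha Raw p-value threshold (default 0.05).
#' @return `results` with an added `label` factor column.
#' @export
classify_regulation <- function(results, alpha = 0.05) {
  lab <- rep("unchanged", nrow(results))
  sig <- !is.na(results$p_value) & results$p_value < alpha
  lab[sig & results$delta_log2 > 0] <- "repressed_cleavage"
  lab[sig & results$delta_log2 < 0] <- "increased_cleavage"
  results$label <- factor(lab, levels = c("repressed_cleavage",
                                          "increased_cleavage", "unchanged"))
  results
}

#' Per-condition uncleaved/total ratio from window counts
#'
#' The plug-in estimate of the readthrough fraction: normalized downstream
#' counts summed over a condition's replicates, divided by the corresponding
#' upstream sum. A zero upstream sum yields `NA`.
#'
#' @param x A [pas_counts()] matrix.
#' @param sf Size factors.
#' @return data.frame with `gene_id` and one `ratio_<condition>` column per
#'   condition.
#' @export
uncleaved_total_ratio_from_counts <- function(x, sf) {
  nup <- sweep(x$up, 2L, sf, "/")
  ndown <- sweep(x$down, 2L, sf, "/")
  out <- data.frame(gene_id = rownames(x$up))
  for (cc in unique(x$samples$condition)) {
    j <- x$samples$condition == cc
    u <- rowSums(nup[, j, drop = FALSE])
    d <- rowSums(ndown[, j, drop = FALSE])
    out[[paste0("ratio_", cc)]] <- ifelse(u > 0, d / u, NA_real_)
  }
  out
}
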