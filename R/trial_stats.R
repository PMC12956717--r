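#' Per-group sample size for a two-sample comparison of means
#'
#' `n = 2 sigma^2 (Z_{1-alpha/2} + Z_{1-beta})^2 / delta^2`, rounded up.
#' The normal quantiles are derived from `alpha` and `power` unless supplied
#' directly (e.g. the conventionally rounded 1.96 and 0.84); with sigma = 5,
#' delta = 3 and the rounded quantiles the formula gives 43.56, hence 44 per
#' group.
#'
#' @param sigma outcome standard deviation (same units as `delta`), `> 0`.
#' @param delta between-group difference to detect, `> 0`.
#' @param alpha two-sided type-I error, default 0.05.
#' @param power target power `1 - beta`, default 0.8.
#' @param z_alpha,z_beta optional explicit quantiles overriding
#'   `alpha`/`power`.
#' @return list `n` (ceiled), `n_raw`, `z_alpha`, `z_beta`.
#' @export
sample_size_per_group <- function(sigma, delta, alpha = 0.05, power = 0.8,
                                  z_alpha = NULL, z_beta = NULL) {
  if (sigma <= 0) stop("sigma must be > 0")
  if (delta <= 0) stop("undefined for delta <= 0")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    stop("alpha and power must lie in (0, 1)")
  if (is.null(z_alpha)) z_alpha <- stats::qnorm(1 - alpha / 2)
  if (is.null(z_beta)) z_beta <- stats::qnorm(power)
  n_raw <- 2 * sigma^2 * (z_alpha + z_beta)^2 / delta^2
  list(n = as.integer(ceiling(n_raw)), n_raw = n_raw,
       z_alpha = z_alpha, z_beta = z_beta)
}

#' Enrollment plan: dropout inflation and per-stratum targets
#'
#' Reports the dropout-inflated per-group size `ceiling(n / (1 - dropout))`
#' and, when a fixed per-stratum target is supplied (e.g. 50 per subgroup),
#' the resulting total `target x strata x arms`. The fixed target is an
#' input, not derived: rounding a formula value to a recruitment-friendly
#' figure is a design choice of the trial, not arithmetic.
#'
#' @param n_per_group formula-based per-group size.
#' @param dropout_rate in `[0, 1)`, default 0.15.
#' @param n_strata number of strata (e.g. 4 GOLD grades).
#' @param arms number of arms, default 2.
#' @param per_stratum_target optional fixed per-stratum-per-arm target.
#' @return list `n_per_group`, `n_inflated`, and when a target is given,
#'   `per_stratum_target` and `total_enrollment`.
#' @export
inflate_for_design <- function(n_per_group, dropout_rate = 0.15,
                               n_strata = NULL, arms = 2,
                               per_stratum_target = NULL) {
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must be in [0, 1)")
  out <- list(n_per_group = n_per_group,
              n_inflated = as.integer(ceiling(n_per_group / (1 - dropout_rate))))
  if (!is.null(per_stratum_target)) {
    if (is.null(n_strata)) stop("n_strata required with a per-stratum target")
    out$per_stratum_target <- per_stratum_target
    out$total_enrollment <- per_stratum_target * n_strata * arms
  }
  out
}

#' GOLD grade from FEV1 percent predicted
#'
#' Grade I: FEV1 >= 80% predicted; II: 50 <= FEV1 < 80; III: 30 <= FEV1 < 50;
#' IV: FEV1 < 30 or respiratory failure (which forces grade IV regardless of
#' FEV1). Vectorized; inputs must lie in (0, 200).
#'
#' @param fev1_percent_predicted numeric vector, % predicted.
#' @param respiratory_failure logical, recycled.
#' @return factor with levels `I`, `II`, `III`, `IV`.
#' @export
gold_grade <- function(fev1_percent_predicted, respiratory_failure = FALSE) {
  if (any(fev1_percent_predicted <= 0 | fev1_percent_predicted >= 200))
    stop("FEV1 %% predicted must lie in (0, 200)")
  respiratory_failure <- rep_len(respiratory_failure, length(fev1_percent_predicted))
  g <- cut(fev1_percent_predicted, breaks = c(0, 30, 50, 80, 200),
           labels = c("IV", "III", "II", "I"), right = FALSE)
  g[respiratory_failure] <- "IV"
  factor(g, levels = c("I", "II", "III", "IV"))
}

#' Stratified 1:1 randomization
#'
#' Within each stratum a seeded permutation assigns half the subjects to
#' each arm. Odd strata get a documented +/-1 imbalance (flagged via the
#' `odd_strata` attribute). Deterministic under `seed`.
#'
#' @param strata vector of stratum labels, one per subject.
#' @param seed RNG seed.
#' @param arms length-2 arm labels, default `c("EG", "CG")`.
#' @return factor of arm assignments in input order, with attribute
#'   `odd_strata` naming any strata with odd size.
#' @export
stratified_randomize <- function(strata, seed = 1, arms = c("EG", "CG")) {
  if (length(arms) != 2L) stop("exactly two arms supported")
  if (!length(strata)) stop("no subjects")
  tab <- table(strata)
  if (any(tab == 0L)) stop("empty stratum")
  assign <- character(length(strata))
  with_seed(seed, {
    for (s in names(tab)) {
      idx <- which(strata == s)
      idx <- idx[sample.int(length(idx))]
      h <- length(idx) %/% 2
      extra <- length(idx) %% 2
      # the odd subject (if any) goes to a randomly chosen arm
      first <- h + (extra && stats::runif(1) < 0.5)
      assign[idx[seq_len(first)]] <- arms[1]
      assign[idx[-seq_len(first)]] <- arms[2]
    }
  })
  odd <- names(tab)[tab %% 2 == 1]
  structure(factor(assign, levels = arms),
            odd_strata = if (length(odd)) odd else NULL)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Sort the m p-values ascending, set `q_(i) = min_{j >= i} (m p_(j) / j)`
#' clipped at 1, and return in input order. Controls the false discovery
#' rate under the usual independence/PRDS conditions.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1 | !is.finite(p))) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0L) return(numeric())
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(m * p[o] / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

#' Imaging-function correlation matrix with FDR control
#'
#' Pairwise correlations between every imaging column and every functional
#' column, with pairwise-complete observations, p-values from
#' [stats::cor.test()], and Benjamini-Hochberg q-values computed across all
#' cells jointly. Constant columns yield flagged undefined cells (`NA` r).
#'
#' @param imaging,functional data.frames with aligned subject rows, numeric
#'   columns.
#' @param method `"pearson"` or `"spearman"`.
#' @param min_pairs minimum complete pairs per cell, default 3.
#' @return data.frame `imaging`, `functional`, `r`, `p`, `q`, `n`, `flag`.
#' @export
correlation_matrix <- function(imaging, functional,
                               method = c("pearson", "spearman"),
                               min_pairs = 3) {
  method <- match.arg(method)
  if (nrow(imaging) != nrow(functional)) stop("subject rows not aligned")
  cells <- expand.grid(imaging = names(imaging), functional = names(functional),
                       stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(cells)), function(i) {
    x <- imaging[[cells$imaging[i]]]
    y <- functional[[cells$functional[i]]]
    ok <- is.finite(x) & is.finite(y)
    n <- sum(ok)
    if (n < min_pairs)
      return(data.frame(r = NA_real_, p = NA_real_, n = n, flag = "too_few_pairs"))
    if (stats::var(x[ok]) == 0 || stats::var(y[ok]) == 0)
      return(data.frame(r = NA_real_, p = NA_real_, n = n, flag = "constant_column"))
    ct <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = method))
    data.frame(r = unname(ct$estimate), p = ct$p.value, n = n, flag = NA_character_)
  })
  out <- cbind(cells, do.call(rbind, res))
  out$q <- NA_real_
  usable <- !is.na(out$p)
  if (any(usable)) out$q[usable] <- bh_adjust(out$p[usable])
  out[c("imaging", "functional", "r", "p", "q", "n", "flag")]
}

#' Simulate a cohort with a known biomarker-function correlation
#'
#' Draws `n` subjects from a bivariate normal with correlation `r` between
#' one imaging column and one functional column (plus independent noise
#' columns), for calibrating [correlation_matrix()] recovery.
#'
#' @param n subjects.
#' @param r target correlation between `biomarker` and `outcome`.
#' @param seed RNG seed.
#' @return list of data.frames `imaging` (`biomarker`, `noise_img`) and
#'   `functional` (`outcome`, `noise_fun`).
#' @export
simulate_correlated_cohort <- function(n = 500, r = -0.6, seed = 1) {
  stopifnot(abs(r) < 1)
  with_seed(seed, {
    z <- stats::rnorm(n)
    y <- r * z + sqrt(1 - r^2) * stats::rnorm(n)
    list(imaging = data.frame(biomarker = z, noise_img = stats::rnorm(n)),
         functional = data.frame(outcome = y, noise_fun = stats::rnorm(n)))
  })
}
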