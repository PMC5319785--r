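hwe_geno_freqs <- function(maf) c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)

check_power_args <- function(maf, prevalence) {
  stopifnot(maf > 0, maf <= 0.5, prevalence > 0, prevalence < 1)
}

#' Calibrate genotype penetrances to a population prevalence
#'
#' Given a risk-allele frequency, a per-allele effect and a disease
#' prevalence K, solves for the genotype-specific disease probabilities
#' f0, f1, f2 such that the population prevalence under Hardy-Weinberg
#' genotype frequencies equals K.
#'
#' Two effect scales are supported. `"odds"`: per-genotype disease odds are
#' `baseline * effect^dosage` (the additive logistic model estimated by the
#' association engine); the baseline odds is found by a monotone
#' one-dimensional root search to tolerance 1e-12. `"risk"`: per-genotype
#' relative risks `effect^dosage` (the multiplicative model of the CaTS-style
#' power calculators); the baseline risk is `K / sum(g_i effect^i)` in
#' closed form.
#'
#' @param maf risk-allele frequency in (0, 0.5].
#' @param effect per-allele effect (> 0): odds ratio or relative risk
#'   depending on `effect_scale`.
#' @param prevalence population disease probability in (0, 1).
#' @param effect_scale `"odds"` or `"risk"`.
#' @return List with `baseline` (baseline odds or risk) and `penetrance`
#'   (numeric f0, f1, f2).
#' @export
calibrate_penetrance <- function(maf, effect, prevalence,
                                 effect_scale = c("odds", "risk")) {
  effect_scale <- match.arg(effect_scale)
  check_power_args(maf, prevalence)
  stopifnot(effect > 0)
  g <- hwe_geno_freqs(maf)
  rel <- effect^(0:2)
  if (effect_scale == "odds") {
    fn <- function(log_b) {
      b <- exp(log_b)
      sum(g * b * rel / (1 + b * rel)) - prevalence
    }
    root <- stats::uniroot(fn, c(-60, 60), tol = 1e-12)$root
    b <- exp(root)
    f <- b * rel / (1 + b * rel)
  } else {
    b <- prevalence / sum(g * rel)
    f <- b * rel
    if (any(f > 1)) stop2("relative-risk model yields penetrance > 1; ",
                          "reduce the effect or prevalence")
  }
  list(baseline = b, penetrance = f)
}

#' Genotype frequencies in cases and controls
#'
#' Bayes inversion of the calibrated penetrance model:
#' `P(g | case) = g_i f_i / K` and `P(g | control) = g_i (1 - f_i) / (1 - K)`.
#'
#' @inheritParams calibrate_penetrance
#' @return List with `case` and `control`, each a 3-vector over dosages
#'   0, 1, 2 summing to 1.
#' @export
case_control_freqs <- function(maf, effect, prevalence,
                               effect_scale = c("odds", "risk")) {
  f <- calibrate_penetrance(maf, effect, prevalence, effect_scale)$penetrance
  g <- hwe_geno_freqs(maf)
  list(case = g * f / sum(g * f),
       control = g * (1 - f) / sum(g * (1 - f)))
}

trend_power_from_freqs <- function(ca, co, n_cases, n_controls, alpha) {
  x <- 0:2
  m1 <- sum(x * ca); v1 <- sum(x^2 * ca) - m1^2
  m0 <- sum(x * co); v0 <- sum(x^2 * co) - m0^2
  pp <- (n_cases * ca + n_controls * co) / (n_cases + n_controls)
  vp <- sum(x^2 * pp) - sum(x * pp)^2
  delta <- m1 - m0
  se0 <- sqrt(vp * (1 / n_cases + 1 / n_controls))   # null (pooled) SE
  se1 <- sqrt(v1 / n_cases + v0 / n_controls)        # alternative SE
  z <- stats::qnorm(1 - alpha / 2)
  power <- stats::pnorm((-z * se0 - delta) / se1) +
    stats::pnorm((z * se0 - delta) / se1, lower.tail = FALSE)
  list(power = power, ncp = delta / se0)
}

#' Analytic power of the case-control additive trend test
#'
#' Power of the two-sided 1-df Cochran-Armitage trend test (allele-dosage
#' scores 0/1/2) under the shifted-normal approximation: the noncentrality
#' is computed from the case and control genotype-frequency vectors implied
#' by the calibrated penetrance model, with the pooled-frequency variance
#' under the null and the group-specific variance under the alternative.
#'
#' The default `effect_scale = "risk"` emulates the CaTS family of power
#' calculators, which parameterize the disease model with multiplicative
#' genotype relative risks; use `"odds"` for a per-allele odds-ratio model.
#'
#' @param n_cases,n_controls group sample sizes.
#' @param maf risk-allele population frequency in (0, 0.5].
#' @param effect per-allele effect (see [calibrate_penetrance()]).
#' @param prevalence population prevalence (default 0.10, the upper end of
#'   the 8-12% resistant-hypertension prevalence range among treated
#'   hypertensives).
#' @param alpha two-sided significance level.
#' @param effect_scale `"risk"` (CaTS-style, default) or `"odds"`.
#' @return List: `power`, `case_genotype_freqs`, `control_genotype_freqs`,
#'   `noncentrality`.
#' @export
power_additive <- function(n_cases, n_controls, maf, effect,
                           prevalence = 0.10, alpha = 5e-8,
                           effect_scale = c("risk", "odds")) {
  effect_scale <- match.arg(effect_scale)
  stopifnot(n_cases >= 1, n_controls >= 1, alpha > 0, alpha < 1)
  cc <- case_control_freqs(maf, effect, prevalence, effect_scale)
  tp <- trend_power_from_freqs(cc$case, cc$control, n_cases, n_controls, alpha)
  list(power = tp$power, case_genotype_freqs = cc$case,
       control_genotype_freqs = cc$control, noncentrality = tp$ncp)
}

#' Minimum detectable per-allele effect at a target power
#'
#' Smallest effect > 1 whose analytic power reaches `target_power`, found by
#' bisection on `[1, 20]` to an absolute tolerance of 1e-4 (power is
#' monotone in the effect size on this bracket).
#'
#' @inheritParams power_additive
#' @param target_power required power in (alpha, 1).
#' @param interval search bracket for the effect.
#' @param tol bisection tolerance on the effect size.
#' @return The minimum detectable effect (odds ratio or relative risk,
#'   per `effect_scale`).
#' @export
min_detectable_or <- function(n_cases, n_controls, maf, prevalence = 0.10,
                              alpha = 5e-8, target_power = 0.80,
                              effect_scale = c("risk", "odds"),
                              interval = c(1, 20), tol = 1e-4) {
  effect_scale <- match.arg(effect_scale)
  stopifnot(target_power > alpha, target_power < 1)
  pw <- function(e) power_additive(n_cases, n_controls, maf, e, prevalence,
                                   alpha, effect_scale)$power
  lo <- interval[1]; hi <- interval[2]
  if (effect_scale == "risk") {
    # the relative-risk model caps the effect where the homozygote
    # penetrance reaches 1: (K - g2) r^2 - g1 r - g0 = 0
    g <- hwe_geno_freqs(maf)
    if (prevalence > g[3L]) {
      a <- prevalence - g[3L]
      r_max <- (g[2L] + sqrt(g[2L]^2 + 4 * a * g[1L])) / (2 * a)
      hi <- min(hi, r_max * (1 - 1e-9))
    }
  }
  if (pw(hi) < target_power)
    stop2(sprintf("target power %.2f unreachable within effect <= %g",
                  target_power, hi))
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (pw(mid) >= target_power) hi <- mid else lo <- mid
  }
  # upper bracket endpoint: guarantees power(returned) >= target_power
  hi
}

#' Monte-Carlo power of the additive trend test
#'
#' Validation oracle for [power_additive()]: draws genotype counts for cases
#' and controls from the calibrated case/control genotype frequencies,
#' applies the two-sided Cochran-Armitage trend test to each replicate, and
#' reports the rejection fraction at `alpha`.
#'
#' @inheritParams power_additive
#' @param n_reps number of replicates (>= 100).
#' @param seed RNG seed (fixed seed gives identical estimates).
#' @return List: `power` (rejection fraction), `se` (binomial standard
#'   error), `n_reps`.
#' @export
power_by_simulation <- function(n_cases, n_controls, maf, effect,
                                prevalence = 0.10, alpha = 5e-8,
                                n_reps = 2000, seed = 1L,
                                effect_scale = c("risk", "odds")) {
  effect_scale <- match.arg(effect_scale)
  stopifnot(n_reps >= 100)
  cc <- case_control_freqs(maf, effect, prevalence, effect_scale)
  set.seed(seed)
  x <- 0:2
  ca_counts <- stats::rmultinom(n_reps, n_cases, cc$case)
  co_counts <- stats::rmultinom(n_reps, n_controls, cc$control)
  m1 <- colSums(ca_counts * x) / n_cases
  m0 <- colSums(co_counts * x) / n_controls
  pooled <- (ca_counts + co_counts) / (n_cases + n_controls)
  vp <- colSums(pooled * x^2) - colSums(pooled * x)^2
  z <- (m1 - m0) / sqrt(vp * (1 / n_cases + 1 / n_controls))
  p <- 2 * stats::pnorm(-abs(z))
  rej <- mean(p < alpha)
  list(power = rej, se = sqrt(rej * (1 - rej) / n_reps), n_reps = n_reps)
}
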