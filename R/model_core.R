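#' Model prior configuration
#'
#' Bundles the hyperparameters of the joint model at one locus: the somatic
#' mutation-rate pseudoprobability `mu`, the pseudocount weighting factor
#' `w = 10 * (n_tumors + 1)`, the four normal-prior category constants, and
#' the Dirichlet strengths used when estimating per-sample allele fractions.
#'
#' The allele-fraction prior strengths follow the coverage of the data:
#' `a_normal` defaults to five times the median normal coverage (biasing the
#' normal's allele fractions towards 1 and 0.5, i.e. a pure diploid sample)
#' and `a_tumor` to 20% of the median tumour coverage (a weaker pull, since
#' tumour samples are heterogeneous mixtures).  Both are clamped to be at
#' least 1 so the closed-form MAP allele-fraction estimate stays inside the
#' simplex.
#'
#' @param n_tumors Number of tumour samples (>= 1).
#' @param mu Somatic mutation-rate pseudoprobability (default `3e-7`, close
#'   to the genome-wide somatic mutation rate).
#' @param a_normal Dirichlet strength for the normal sample's allele
#'   fractions; scalar.
#' @param a_tumor Dirichlet strength for tumour allele fractions; scalar or
#'   one value per tumour sample.
#' @param alpha,beta,gamma,delta Pseudocount constants of the normal
#'   composition prior for, respectively, heterozygous-reference,
#'   heterozygous-variant, homozygous-variant and homozygous-reference
#'   compositions.  They are used exactly as given (their weighted sum need
#'   not be 1; the conditional distribution normalises).
#' @param w Pseudocount weighting factor; default `10 * (n_tumors + 1)`.
#' @return A `prior_config` list.
#' @export
prior_config <- function(n_tumors, mu = 3e-7, a_normal = 1, a_tumor = 1,
                         alpha = 3.34e-4, beta = 8.33e-8, gamma = 1.665e-4,
                         delta = 0.9985, w = 10 * (n_tumors + 1)) {
  stopifnot(n_tumors >= 1, mu > 0, mu < 1, w > 0)
  a_tumor <- rep_len(pmax(1, a_tumor), n_tumors)
  structure(list(n_tumors = as.integer(n_tumors), mu = mu, w = w,
                 a_normal = max(1, a_normal), a_tumor = a_tumor,
                 alpha = alpha, beta = beta, gamma = gamma, delta = delta),
            class = "prior_config")
}

#' Prior strengths from median coverage
#'
#' Convenience wrapper: converts per-sample median coverages into a
#' [prior_config()], using the default scalings (5x the normal median,
#' 0.2x each tumour median).
#'
#' @param med_cov Numeric vector of per-sample median coverages, normal
#'   first.
#' @param normal_scale,tumor_scale Multipliers applied to the medians.
#' @param ... Passed on to [prior_config()].
#' @export
prior_config_from_coverage <- function(med_cov, normal_scale = 5,
                                       tumor_scale = 0.2, ...) {
  prior_config(n_tumors = length(med_cov) - 1L,
               a_normal = normal_scale * med_cov[1],
               a_tumor = tumor_scale * med_cov[-1], ...)
}

#' Per-base likelihood
#'
#' Probability of observing called base `tau` given the sample's allele
#' fractions `f` and the read's miscall probability `e`, assuming the three
#' possible miscalls are equally likely:
#' `P(r = tau | S, f) = (1 - e) f_tau + (e/3) (1 - f_tau)`.
#'
#' @param allele_called Allele (label or index) reported by the read.
#' @param error_prob Miscall probability in (0, 1].
#' @param f Length-4 allele-fraction vector over A,C,G,T.
#' @return Probability in \[0, 1\].  Vectorised over reads when
#'   `allele_called` and `error_prob` are vectors.
#' @export
base_likelihood <- function(allele_called, error_prob, f) {
  a <- if (is.character(allele_called)) match(allele_called, ALLELES)
       else as.integer(allele_called)
  ft <- f[a]
  (1 - error_prob) * ft + (error_prob / 3) * (1 - ft)
}

#' Log-likelihood of one sample column
#'
#' Reads are conditionally independent given the allelic composition and
#' allele fractions, so the data likelihood is the product of per-base
#' likelihoods; an empty column has likelihood 1.
#'
#' @param col Sample column (decoded reads).
#' @param f Allele fractions estimated under the candidate composition.
#' @return Log-probability (0 for an empty column).
#' @export
log_data_likelihood <- function(col, f) {
  if (length(col$allele) == 0L) return(0)
  ft <- f[col$allele]
  e <- col$error_prob
  sum(log((1 - e) * ft + (e / 3) * (1 - ft)))
}

#' MAP allele fractions under a composition
#'
#' Maximum-a-posteriori estimate of the allele-fraction vector constrained to
#' a candidate composition `S`, under a symmetric Dirichlet prior of strength
#' `a_strength` on the member alleles and the error-free (`e -> 0`) limit of
#' the read likelihood.  In that limit the posterior is Dirichlet with
#' parameters `a_tau + v_tau`, giving the closed form
#' `f_tau = (v_tau + a - 1) / (sum_{tau in S} (v_tau + a) - M)` for member
#' alleles (`M = |S|`) and 0 otherwise.
#'
#' @param v Length-4 read counts over A,C,G,T.
#' @param S Candidate composition (label or index).
#' @param a_strength Dirichlet strength (>= 1; values below 1 are clamped so
#'   the mode stays inside the simplex).
#' @return Length-4 allele-fraction vector, zero off-composition, summing
#'   to 1.
#' @examples
#' map_allele_fractions(c(9, 1, 0, 0), "AC", 1)  # f_A = 0.9
#' @export
map_allele_fractions <- function(v, S, a_strength) {
  a_strength <- max(1, a_strength)
  m <- COMP_MEMBERS[[comp_index(S)]]
  f <- numeric(4)
  if (length(m) == 1L) {
    f[m] <- 1
    return(f)
  }
  denom <- sum(v[m] + a_strength) - length(m)
  f[m] <- (v[m] + a_strength - 1) / denom
  f
}

# --- composition priors -----------------------------------------------------

#' Dirichlet pseudocount of a tumour composition
#'
#' The tumour compositions are modelled as a multinomial sample from the
#' 14-member universe whose sampling probabilities carry a Dirichlet prior
#' with pseudocounts `delta_z` keyed to the distance from the current normal
#' composition `S_N`: `w * mu` when `z` gains exactly one allele relative to
#' `S_N` (a somatic SNV), `w * mu^2` for every other change (including
#' allele loss), and for `z = S_N` the remainder that makes the pseudocounts
#' sum exactly to `w`.
#'
#' @param z Tumour composition (label or index, 14-member universe).
#' @param S_N Normal composition (label or index, 10-member universe).
#' @param cfg A [prior_config()].
#' @return Nonnegative pseudocount.
#' @export
tumor_pseudocount <- function(z, S_N, cfg) {
  unname(tumor_pseudocounts(S_N, cfg)[comp_index(z)])
}

#' All 14 tumour pseudocounts for a given normal composition
#'
#' @inheritParams tumor_pseudocount
#' @return Named length-14 vector summing exactly to `cfg$w`.
#' @export
tumor_pseudocounts <- function(S_N, cfg) {
  sn <- comp_index(S_N)
  stopifnot(sn <= N_NORMAL_COMPS)
  sn_members <- COMP_MEMBERS[[sn]]
  one_extra <- vapply(seq_len(N_TUMOR_COMPS), function(z) {
    zm <- COMP_MEMBERS[[z]]
    length(zm) == length(sn_members) + 1L && all(sn_members %in% zm)
  }, logical(1))
  d <- ifelse(one_extra, cfg$w * cfg$mu, cfg$w * cfg$mu^2)
  d[sn] <- cfg$w - sum(d[-sn])
  setNames(d, COMP_LABELS)
}

#' Conditional prior of one tumour composition
#'
#' Integrating out the multinomial sampling probabilities gives a
#' Dirichlet-multinomial ("Chinese restaurant") form: the prior probability
#' that tumour sample i has composition `z` is
#' `(c_z + delta_z) / sum_z (c_z + delta_z)`, where `c_z` counts the other
#' tumour samples currently assigned composition `z`.  Because observed
#' compositions add to the numerator, a mutation already drawn in other
#' tumours raises the prior here — the borrowing mechanism that gives the
#' caller power on shared mutations.
#'
#' @param z Tumour composition (label or index).
#' @param c_counts Length-14 counts of the other tumour samples'
#'   compositions (sums to `n_tumors - 1`).
#' @param S_N Current normal composition.
#' @param cfg A [prior_config()].
#' @return Probability; over all 14 `z` these sum to 1 with denominator
#'   `(n_tumors - 1) + w`.
#' @export
tumor_conditional_prior <- function(z, c_counts, S_N, cfg) {
  d <- tumor_pseudocounts(S_N, cfg)
  zi <- comp_index(z)
  unname((c_counts[zi] + d[zi]) / sum(c_counts + d))
}

#' Dirichlet pseudocount of a normal composition
#'
#' The normal sample is assumed pure and diploid, so its composition lies in
#' the 10-member universe of one- and two-allele sets.  Pseudocounts depend
#' only on the relation to the reference base: `w*delta` for homozygous
#' reference, `w*alpha` for heterozygous reference, `w*gamma` for homozygous
#' variant and `w*beta` for heterozygous variant.
#'
#' @param z Normal composition (label or index <= 10).
#' @param ref Reference allele (label or index).
#' @param cfg A [prior_config()].
#' @return Nonnegative pseudocount.
#' @export
normal_pseudocount <- function(z, ref, cfg) {
  unname(normal_pseudocounts(ref, cfg)[comp_index(z)])
}

#' All 10 normal pseudocounts for a given reference base
#'
#' @inheritParams normal_pseudocount
#' @return Named length-10 vector.
#' @export
normal_pseudocounts <- function(ref, cfg) {
  ref_i <- allele_index(ref)
  d <- vapply(seq_len(N_NORMAL_COMPS), function(z) {
    m <- COMP_MEMBERS[[z]]
    if (length(m) == 1L) {
      if (m == ref_i) cfg$delta else cfg$gamma
    } else {
      if (ref_i %in% m) cfg$alpha else cfg$beta
    }
  }, numeric(1))
  setNames(cfg$w * d, COMP_LABELS[seq_len(N_NORMAL_COMPS)])
}

#' Conditional prior of the normal composition
#'
#' Same Dirichlet-multinomial form as the tumour prior, but over the
#' 10-member normal universe: `(n_z + delta^N_z) / sum_{z in N} (...)`,
#' where `n_z` counts tumour samples currently assigned composition `z`.
#' Tri-allelic tumour compositions lie outside the normal universe and
#' contribute to no `n_z`; tri-allelic `z` has probability 0.
#'
#' @param z Candidate normal composition (any of the 14 labels; tri-allelic
#'   ones return 0).
#' @param n_counts Length-10 counts of tumour samples whose composition
#'   equals each normal-universe composition.
#' @param ref Reference allele.
#' @param cfg A [prior_config()].
#' @return Probability; sums to 1 over the 10-member universe.
#' @export
normal_conditional_prior <- function(z, n_counts, ref, cfg) {
  zi <- comp_index(z)
  if (zi > N_NORMAL_COMPS) return(0)
  d <- normal_pseudocounts(ref, cfg)
  unname((n_counts[zi] + d[zi]) / sum(n_counts + d))
}

# --- full conditional -------------------------------------------------------

# Per-sample cached log-likelihoods: for each candidate composition, estimate
# f by its MAP closed form and evaluate the full-error-model log-likelihood.
# These do not depend on other samples' states, so they are computed once per
# locus and reused across Gibbs sweeps.
sample_loglik_cache <- function(col, a_strength, n_comps) {
  v <- tabulate(col$allele, nbins = 4L)
  vapply(seq_len(n_comps), function(z) {
    f <- map_allele_fractions(v, z, a_strength)
    log_data_likelihood(col, f)
  }, numeric(1))
}

#' Full conditional distribution of one sample's composition
#'
#' The Gibbs sampler redraws each sample's allelic composition from
#' `P(S^k | everything else) \propto P(D^k | S^k) * prior(S^k | others)`:
#' the per-sample read likelihood (full per-read error probabilities, with
#' allele fractions plugged in at their MAP estimate) times the
#' Dirichlet-multinomial conditional prior.  Normalisation uses log-sum-exp.
#'
#' @param sample_role `"normal"`, or a tumour index (1-based integer) naming
#'   which tumour sample to redraw.
#' @param locus A filtered `locus_pileup`.
#' @param others Current compositions of all other samples: a list with
#'   elements `normal` (label, ignored when redrawing the normal) and
#'   `tumors` (character vector of labels, the target tumour's entry ignored
#'   when redrawing a tumour).
#' @param cfg A [prior_config()].
#' @param cache Optional precomputed log-likelihood vector for the target
#'   sample (as built internally); supplied by the sampler to avoid
#'   recomputation.
#' @return Named probability vector over the role's composition universe
#'   (length 10 for the normal, 14 for a tumour), summing to 1.
#' @export
conditional_distribution <- function(sample_role, locus, others, cfg,
                                     cache = NULL) {
  if (identical(sample_role, "normal")) {
    ll <- if (is.null(cache)) {
      sample_loglik_cache(locus$normal, cfg$a_normal, N_NORMAL_COMPS)
    } else cache
    tum_idx <- vapply(others$tumors, comp_index, integer(1))
    n_counts <- tabulate(tum_idx[tum_idx <= N_NORMAL_COMPS],
                         nbins = N_NORMAL_COMPS)
    d <- normal_pseudocounts(locus$ref, cfg)
    logp <- ll + log(n_counts + d)
    labels <- COMP_LABELS[seq_len(N_NORMAL_COMPS)]
  } else {
    i <- as.integer(sample_role)
    ll <- if (is.null(cache)) {
      sample_loglik_cache(locus$tumors[[i]], cfg$a_tumor[i], N_TUMOR_COMPS)
    } else cache
    other_idx <- vapply(others$tumors[-i], comp_index, integer(1))
    c_counts <- tabulate(other_idx, nbins = N_TUMOR_COMPS)
    d <- tumor_pseudocounts(others$normal, cfg)
    logp <- ll + log(c_counts + d)
    labels <- COMP_LABELS
  }
  m <- max(logp)
  if (!is.finite(m)) stop("all candidate compositions have zero posterior mass")
  p <- exp(logp - m)
  setNames(p / sum(p), labels)
}
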