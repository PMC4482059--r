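#' Gibbs sampler configuration
#'
#' Controls the per-locus Markov chain.  The chain is capped at `max_cycles`
#' sweeps (default 3000); convergence is declared when, in two consecutive
#' post-burn-in windows of `window` sweeps, every sample has the same modal
#' composition and that mode's within-window frequency is at least
#' `mode_freq_threshold`.  Loci that never satisfy this are still reported,
#' flagged as non-converged.
#'
#' @param burn_in Untallied initial sweeps (default 100).
#' @param window Sweeps per convergence-check window (default 300).
#' @param max_cycles Total sweep cap (default 3000).
#' @param mode_freq_threshold Minimum within-window modal frequency
#'   (default 0.5).
#' @param seed Optional RNG seed; when `NULL` the caller manages seeding
#'   (the pipeline derives one seed per locus from its base seed and the
#'   locus coordinates).
#' @return A `gibbs_config` list.
#' @export
gibbs_config <- function(burn_in = 100L, window = 300L, max_cycles = 3000L,
                         mode_freq_threshold = 0.5, seed = NULL) {
  stopifnot(burn_in < max_cycles, window >= 1,
            mode_freq_threshold > 0, mode_freq_threshold <= 1)
  structure(list(burn_in = as.integer(burn_in), window = as.integer(window),
                 max_cycles = as.integer(max_cycles),
                 mode_freq_threshold = mode_freq_threshold, seed = seed),
            class = "gibbs_config")
}

#' Per-locus seed derivation
#'
#' Loci are analysed independently, so the pipeline runs one chain per locus
#' with a seed derived deterministically from the base seed and the locus
#' coordinates.  This makes results invariant to the order (or parallel
#' partitioning) in which loci are processed.
#'
#' @param seed Base integer seed.
#' @param chrom Chromosome name.
#' @param pos 1-based position.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_locus_seed <- function(seed, chrom, pos) {
  h <- 0
  for (v in utf8ToInt(chrom)) h <- (h * 31 + v) %% 2147483647
  as.integer((as.numeric(seed) * 48271 + h * 1299721 +
                as.numeric(pos) * 104729) %% 2147483647)
}

#' Random initial chain state
#'
#' Each sample's composition is drawn uniformly from its universe (10 states
#' for the normal, 14 per tumour), consuming one uniform variate per sample
#' in the order normal, tumours.
#'
#' @param n_tumors Number of tumour samples.
#' @return A `chain_state`: list with `normal` (label) and `tumors`
#'   (character vector of labels).
#' @export
initialize_state <- function(n_tumors) {
  sN <- min(floor(runif(1) * N_NORMAL_COMPS) + 1, N_NORMAL_COMPS)
  sT <- pmin(floor(runif(n_tumors) * N_TUMOR_COMPS) + 1, N_TUMOR_COMPS)
  structure(list(normal = COMP_LABELS[sN], tumors = COMP_LABELS[sT]),
            class = "chain_state")
}

#' One systematic Gibbs sweep (reference implementation)
#'
#' Redraws every sample's composition from its full conditional in a fixed
#' scan order — normal first, then tumours in input order — with each new
#' draw immediately visible to the following conditionals.  Draws are
#' inverse-CDF over the canonical composition order, consuming one uniform
#' per sample.  This pure-R sweep mirrors the compiled chain draw-for-draw
#' and is the reference against which the compiled trajectory is validated.
#'
#' @param state A `chain_state`.
#' @param locus A filtered `locus_pileup`.
#' @param cfg A [prior_config()].
#' @param caches Optional list of per-sample log-likelihood caches (normal
#'   first), as used by the compiled sampler.
#' @return The updated `chain_state`.
#' @export
gibbs_sweep <- function(state, locus, cfg, caches = NULL) {
  draw <- function(p) {
    u <- runif(1)
    names(p)[which(cumsum(p) >= u * sum(p))[1]]
  }
  p <- conditional_distribution("normal", locus, state, cfg,
                                cache = caches[["normal"]])
  state$normal <- draw(p)
  for (i in seq_along(state$tumors)) {
    p <- conditional_distribution(i, locus, state, cfg,
                                  cache = caches[["tumors"]][[i]])
    state$tumors[i] <- draw(p)
  }
  state
}

# Build the per-sample log-likelihood caches used by gibbs_sweep (the
# compiled sampler builds its own internally).
locus_likelihood_caches <- function(locus, cfg) {
  list(normal = sample_loglik_cache(locus$normal, cfg$a_normal,
                                    N_NORMAL_COMPS),
       tumors = lapply(seq_along(locus$tumors), function(i) {
         sample_loglik_cache(locus$tumors[[i]], cfg$a_tumor[i],
                             N_TUMOR_COMPS)
       }))
}

#' Run the per-locus Gibbs chain
#'
#' Initialises the chain at a uniform random state, runs `burn_in` untallied
#' sweeps, then tallies compositions until convergence (windowed modal
#' stability, see [gibbs_config()]) or the `max_cycles` cap.  The heavy
#' lifting happens in compiled code; per-sample candidate log-likelihoods
#' are computed once and cached, so each sweep costs only the prior updates
#' and draws.
#'
#' @param locus A filtered `locus_pileup`.
#' @param cfg A [prior_config()].
#' @param gibbs A [gibbs_config()]; if its `seed` is non-`NULL` the RNG is
#'   seeded before the chain starts.
#' @param record If `TRUE`, keep the full state trajectory (one row per
#'   sweep, including burn-in) and disable early stopping — used by the
#'   exact-oracle diagnostics.
#' @return A `posterior_summary`: per-sample tallies (rows: normal, then
#'   tumours; columns: the 14 compositions), modal composition labels and
#'   frequencies, `sweeps_run`, `converged`, and optionally `trajectory`.
#' @examples
#' loc <- parse_mpileup_line(
#'   "chr1\t1\tA\t6\t..,,..\tIIIIII\t6\t.CcC,.\tIIIIII", n_samples = 2)
#' cfg <- prior_config(n_tumors = 1, a_normal = 30, a_tumor = 1.2)
#' run_chain(loc, cfg, gibbs_config(seed = 7))
#' @export
run_chain <- function(locus, cfg, gibbs = gibbs_config(), record = FALSE) {
  if (!is.null(gibbs$seed)) set.seed(gibbs$seed)
  cols <- c(list(locus$normal), locus$tumors)
  res <- run_locus_chain_cpp(
    alleles = lapply(cols, `[[`, "allele"),
    errors = lapply(cols, `[[`, "error_prob"),
    ref = match(locus$ref, ALLELES),
    a_strengths = c(cfg$a_normal, cfg$a_tumor),
    mu = cfg$mu, w = cfg$w, alpha = cfg$alpha, beta = cfg$beta,
    gamma_ = cfg$gamma, delta = cfg$delta,
    burn_in = gibbs$burn_in, window = gibbs$window,
    max_cycles = gibbs$max_cycles,
    mode_thresh = gibbs$mode_freq_threshold, record = record)
  dimnames(res$tallies) <- list(
    c("normal", paste0("tumor", seq_along(locus$tumors))), COMP_LABELS)
  out <- list(tallies = res$tallies, modes = COMP_LABELS[res$modes],
              mode_freq = res$mode_freq, sweeps_run = res$sweeps_run,
              converged = res$converged)
  if (record) out$trajectory <- res$trajectory
  structure(out, class = "posterior_summary")
}

#' Point estimates from a chain summary
#'
#' The point estimate of each sample's allelic composition is its most
#' frequently drawn state; exact ties break to the earlier composition in
#' canonical order (deterministic).
#'
#' @param summary A `posterior_summary` from [run_chain()].
#' @return Character vector of composition labels, normal first.
#' @export
point_estimates <- function(summary) {
  COMP_LABELS[apply(summary$tallies, 1, which.max)]
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat("<posterior_summary> sweeps:", x$sweeps_run,
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  est <- point_estimates(x)
  for (k in seq_along(est)) {
    cat(sprintf("  %-8s mode %-4s freq %.3f\n", rownames(x$tallies)[k],
                est[k], x$mode_freq[k]))
  }
  invisible(x)
}
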