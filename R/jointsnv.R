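#' Joint somatic SNV calling across same-patient samples
#'
#' The main fitting function.  Each locus of a multi-sample pileup (one
#' matched normal plus `n` tumour samples) is analysed independently: after
#' base-quality and depth filtering, a Gibbs sampler explores the joint
#' posterior of the per-sample allelic compositions, the modal composition
#' of each sample is taken as its point estimate, and tumours whose
#' composition gains or loses alleles relative to the normal yield somatic
#' SNV / LOH calls.  A pooled strand-bias Fisher test and configurable
#' high-confidence filters annotate each somatic site.
#'
#' Per-locus chain seeds are derived from `seed` and the locus coordinates,
#' so results do not depend on the order in which loci are processed.
#'
#' @param pileup Input loci: a path to a samtools-mpileup text file, a
#'   character vector of mpileup lines (both require `n_samples`), or a
#'   list of `locus_pileup` objects (e.g. from [simulate_pileup()]).
#' @param n_samples Total number of sample columns (normal + tumours);
#'   required when `pileup` is text.
#' @param normal_index Which sample column is the matched normal
#'   (default 1).
#' @param min_base_q,min_depth Passed to [apply_quality_filters()].
#' @param med_cov Optional per-sample median coverages (normal first) used
#'   to scale the allele-fraction prior strengths; computed from the
#'   filtered loci when `NULL`.
#' @param mu Somatic mutation-rate pseudoprobability (default `3e-7`).
#' @param gibbs A [gibbs_config()].
#' @param filters A [filter_config()].
#' @param seed Base integer seed (default 1).
#' @param sample_names Optional sample names, normal first.
#' @return An object of class `jointsnv`: list with `calls` (one record per
#'   somatic site), `loci` (per-locus data frame of inferred compositions),
#'   run counters (`n_loci`, `n_skipped`, `n_somatic`, `n_nonconverged`),
#'   and the configurations used.  Methods: `print`, `summary`,
#'   `as.data.frame`; export with [write_vcf()] via [vcf_lines()].
#' @examples
#' cfg <- simulation_config(n_tumors = 2, depth = 40, vaf = 0.4,
#'                          base_q = 30, n_loci = 3, seed = 42)
#' sim <- simulate_pileup(cfg)
#' fit <- jointsnv(sim$loci, seed = 1)
#' fit
#' @export
jointsnv <- function(pileup, n_samples = NULL, normal_index = 1L,
                     min_base_q = 20, min_depth = 1L, med_cov = NULL,
                     mu = 3e-7, gibbs = gibbs_config(),
                     filters = filter_config(), seed = 1L,
                     sample_names = NULL) {
  loci <- if (is.character(pileup)) {
    if (is.null(n_samples)) {
      stop("n_samples is required when reading mpileup text")
    }
    read_mpileup(pileup, n_samples, normal_index)
  } else pileup
  n_input <- length(loci)
  kept <- lapply(loci, apply_quality_filters, min_base_q = min_base_q,
                 min_depth = min_depth)
  skip <- vapply(kept, is.null, logical(1))
  kept <- kept[!skip]
  if (length(kept) == 0L) {
    stop("no loci survive filtering; nothing to call")
  }
  n_tumors <- length(kept[[1]]$tumors)
  if (is.null(med_cov)) med_cov <- median_coverage(kept)
  cfg <- prior_config_from_coverage(med_cov, mu = mu)
  res <- call_loci(kept, cfg, gibbs, filters, seed)
  if (is.null(sample_names)) {
    sample_names <- c("NORMAL", paste0("TUMOR", seq_len(n_tumors)))
  }
  structure(c(res, list(n_loci = n_input, n_skipped = sum(skip),
                        med_cov = med_cov, prior = cfg, gibbs = gibbs,
                        filters = filters, seed = seed,
                        sample_names = sample_names)),
            class = "jointsnv")
}

# Workhorse: run the chain on each (already filtered) locus, classify, and
# annotate somatic sites.  keep_table=FALSE skips the per-locus data frame
# (used by the large simulation experiments).
call_loci <- function(loci, cfg, gibbs, filters, seed, keep_table = TRUE) {
  n <- length(loci)
  n_tumors <- cfg$n_tumors
  calls <- list()
  n_somatic <- 0L; n_nonconv <- 0L
  if (keep_table) {
    t_chrom <- character(n); t_pos <- integer(n); t_ref <- character(n)
    t_norm <- character(n); t_tum <- character(n)
    t_som <- logical(n); t_conv <- logical(n); t_sweeps <- integer(n)
  }
  for (j in seq_len(n)) {
    locus <- loci[[j]]
    gibbs$seed <- derive_locus_seed(seed, locus$chrom, locus$pos)
    summ <- run_chain(locus, cfg, gibbs)
    est <- summ$modes
    if (!summ$converged) n_nonconv <- n_nonconv + 1L
    somatic <- FALSE
    if (any(est[-1] != est[1])) {
      cls <- classify(est[1], est[-1], locus$ref)
      somatic <- cls$somatic
    }
    if (somatic) {
      n_somatic <- n_somatic + 1L
      calls[[length(calls) + 1L]] <-
        annotate_call(locus, est, cls, summ, filters)
    }
    if (keep_table) {
      t_chrom[j] <- locus$chrom; t_pos[j] <- locus$pos
      t_ref[j] <- locus$ref; t_norm[j] <- est[1]
      t_tum[j] <- paste(est[-1], collapse = ",")
      t_som[j] <- somatic; t_conv[j] <- summ$converged
      t_sweeps[j] <- summ$sweeps_run
    }
  }
  out <- list(calls = calls, n_called = n, n_somatic = n_somatic,
              n_nonconverged = n_nonconv)
  if (keep_table) {
    out$loci <- data.frame(chrom = t_chrom, pos = t_pos, ref = t_ref,
                           normal = t_norm, tumors = t_tum, somatic = t_som,
                           converged = t_conv, sweeps = t_sweeps)
  }
  out
}

# Build the full record for a somatic site: allele depths, pooled
# strand-bias test over the gained alleles, filter flags.
annotate_call <- function(locus, est, cls, summ, filters) {
  cols <- c(list(locus$normal), locus$tumors)
  ad <- t(vapply(cols, allele_counts, integer(4)))
  colnames(ad) <- ALLELES
  union_g <- sort(unique(unlist(cls$gained)))
  sb_p <- NA_real_; sb_a <- NA_character_
  if (length(union_g)) {
    for (b in union_g) {
      gaining <- vapply(cls$gained, function(g) b %in% g, logical(1))
      p <- suppressWarnings(
        strand_bias_pvalue(locus$tumors[gaining], b, est[1]))
      if (is.na(sb_p) || p < sb_p) { sb_p <- as.numeric(p); sb_a <- b }
    }
  }
  variant_reads <- sum(vapply(seq_along(cls$gained), function(i) {
    sum(ad[i + 1L, cls$gained[[i]]])
  }, numeric(1)))
  call <- list(chrom = locus$chrom, pos = locus$pos, ref = locus$ref,
               somatic = TRUE, sample_comps = est,
               sample_status = c(".", cls$status), gained = cls$gained,
               lost = cls$lost, allele_depths = ad,
               variant_reads = variant_reads,
               normal_depth = length(locus$normal$allele),
               strand_bias_p = sb_p, strand_bias_allele = sb_a,
               sweeps_run = summ$sweeps_run, converged = summ$converged)
  call$filter_flags <- apply_filters(call, filters)
  call
}

#' VCF lines for a fitted call set
#'
#' @param fit A `jointsnv` object.
#' @param path Optional output path.
#' @return See [write_vcf()].
#' @export
vcf_lines <- function(fit, path = NULL) {
  write_vcf(fit$calls, fit$sample_names, path)
}

#' @export
print.jointsnv <- function(x, ...) {
  cat("Joint multisample somatic SNV calls\n")
  cat(sprintf("  loci: %d processed, %d skipped (depth), %d somatic, %d non-converged\n",
              x$n_loci, x$n_skipped, x$n_somatic, x$n_nonconverged))
  cat(sprintf("  samples: %s\n", paste(x$sample_names, collapse = ", ")))
  if (x$n_somatic > 0) {
    hc <- sum(vapply(x$calls, function(cl) length(cl$filter_flags) == 0L,
                     logical(1)))
    cat(sprintf("  high-confidence (no filter flags): %d of %d\n",
                hc, x$n_somatic))
  }
  invisible(x)
}

#' @export
summary.jointsnv <- function(object, ...) {
  statuses <- unlist(lapply(object$calls, function(cl) cl$sample_status[-1]))
  out <- list(n_loci = object$n_loci, n_skipped = object$n_skipped,
              n_somatic = object$n_somatic,
              n_nonconverged = object$n_nonconverged,
              status_table = if (length(statuses)) table(statuses) else NULL,
              med_cov = object$med_cov)
  class(out) <- "summary.jointsnv"
  out
}

#' @export
print.summary.jointsnv <- function(x, ...) {
  cat(sprintf("loci processed: %d (skipped %d)\nsomatic sites: %d\nnon-converged: %d\n",
              x$n_loci, x$n_skipped, x$n_somatic, x$n_nonconverged))
  cat("median coverage:", paste(x$med_cov, collapse = ", "), "\n")
  if (!is.null(x$status_table)) {
    cat("per-tumour statuses at somatic sites:\n")
    print(x$status_table)
  }
  invisible(x)
}

#' @export
as.data.frame.jointsnv <- function(x, ...) x$loci
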