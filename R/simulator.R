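#' Simulation configuration
#'
#' Parameters of the pileup simulator used for benchmarking: uniform
#' sequencing depth, perfectly aligned reads, and independent sequencing
#' error introduced at a constant base-quality rate.  At each locus a
#' reference and a distinct variant allele are drawn uniformly; every
#' tumour read supports the variant with probability `vaf` (else the
#' reference), every normal read with probability `contamination * vaf`
#' (tumour cells contaminating the normal carry the variant at rate
#' `vaf`); each read is then independently miscalled with probability
#' `10^(-base_q/10)`, substituting uniformly among the other three bases.
#' Strands are assigned forward/reverse with probability 1/2 and qualities
#' are constant at `base_q`.
#'
#' @param n_tumors Number of tumour samples (default 4, the benchmark
#'   design).
#' @param depth Uniform per-sample read depth.
#' @param vaf Variant allele frequency in the tumour samples, in \[0, 1\].
#' @param base_q Constant Phred base quality (benchmarks use 15, 20, 30).
#' @param contamination Fraction of tumour cells in the normal sample
#'   (default 0).
#' @param n_loci Number of independent loci to simulate.
#' @param seed RNG seed.
#' @param chrom Name of the synthetic contig; positions are consecutive
#'   integers (no reference genome is involved).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_tumors = 4L, depth = 30L, vaf = 0.5,
                              base_q = 30, contamination = 0,
                              n_loci = 1000L, seed = 1L, chrom = "sim1") {
  stopifnot(depth >= 1, vaf >= 0, vaf <= 1,
            contamination >= 0, contamination <= 1, n_loci >= 0)
  structure(list(n_tumors = as.integer(n_tumors),
                 depth = as.integer(depth), vaf = vaf, base_q = base_q,
                 contamination = contamination, n_loci = as.integer(n_loci),
                 seed = as.integer(seed), chrom = chrom),
            class = "simulation_config")
}

# One sample column: true allele is alt with probability p_alt, then an
# independent miscall with probability e replaces the call uniformly by one
# of the other three bases.
sim_sample_col <- function(depth, p_alt, ref_i, alt_i, e) {
  allele <- ifelse(runif(depth) < p_alt, alt_i, ref_i)
  mis <- runif(depth) < e
  if (any(mis)) {
    off <- floor(runif(sum(mis)) * 3) + 1
    allele[mis] <- (allele[mis] - 1L + as.integer(off)) %% 4L + 1L
  }
  list(depth_raw = depth, allele = as.integer(allele),
       forward = runif(depth) < 0.5, error_prob = rep(e, depth))
}

#' Simulate one locus
#'
#' @param cfg A [simulation_config()].
#' @param pos Position on the synthetic contig.
#' @return List with `locus` (a `locus_pileup`) and `truth` (a one-row data
#'   frame: chrom, pos, ref, alt, per-sample true VAF).
#' @seealso [simulate_pileup()] for many loci at once.
#' @export
simulate_locus <- function(cfg, pos = 1L) {
  e <- 10^(-cfg$base_q / 10)
  ref_i <- sample.int(4L, 1L)
  alt_i <- sample.int(3L, 1L)
  alt_i <- if (alt_i >= ref_i) alt_i + 1L else alt_i  # uniform, alt != ref
  p_norm <- cfg$contamination * cfg$vaf
  samples <- c(list(sim_sample_col(cfg$depth, p_norm, ref_i, alt_i, e)),
               lapply(seq_len(cfg$n_tumors), function(i) {
                 sim_sample_col(cfg$depth, cfg$vaf, ref_i, alt_i, e)
               }))
  locus <- new_locus_pileup(chrom = cfg$chrom, pos = as.integer(pos),
                            ref = ALLELES[ref_i], samples = samples)
  truth <- data.frame(chrom = cfg$chrom, pos = as.integer(pos),
                      ref = ALLELES[ref_i], alt = ALLELES[alt_i],
                      vaf_normal = p_norm, vaf_tumor = cfg$vaf)
  list(locus = locus, truth = truth)
}

#' Simulate a multi-sample pileup
#'
#' @param cfg A [simulation_config()]; its `seed` seeds the RNG.
#' @param start_pos Position of the first locus (consecutive after that).
#' @return List with `loci` (list of `locus_pileup`) and `truth` (data
#'   frame, one row per locus).
#' @export
simulate_pileup <- function(cfg, start_pos = 1L) {
  set.seed(cfg$seed)
  out <- lapply(seq_len(cfg$n_loci), function(j) {
    simulate_locus(cfg, pos = start_pos + j - 1L)
  })
  list(loci = lapply(out, `[[`, "locus"),
       truth = do.call(rbind, lapply(out, `[[`, "truth")))
}

#' Write simulated loci as fixture files
#'
#' Emits a valid mpileup file plus a tab-separated truth table, suitable as
#' plain-text test fixtures; parsing the mpileup back recovers identical
#' allele counts.
#'
#' @param loci List of `locus_pileup` objects.
#' @param truth Matching truth data frame.
#' @param mpileup_path,truth_path Output paths.
#' @export
write_fixture_mpileup <- function(loci, truth, mpileup_path, truth_path) {
  write_mpileup(loci, mpileup_path)
  write.table(truth, truth_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(NULL)
}

#' Sensitivity benchmark on shared SNVs
#'
#' Plants the same SNV in every tumour sample (at identical frequency) and
#' measures, per (vaf, depth) grid cell, the fraction of simulated SNVs the
#' caller recovers.  A true positive requires the site to be called somatic
#' with the planted allele gained in every tumour sample; a looser
#' definition (gained in at least one tumour) is available via
#' `per_site = TRUE`.
#'
#' @param vafs Variant allele frequencies to test (must all be > 0).
#' @param depths Sequencing depths to test.
#' @param base_q Constant base quality (default 30, the benchmark setting).
#' @param n_tumors Number of tumour samples (default 4).
#' @param n_loci Simulated SNVs per grid cell.
#' @param seed Base seed.
#' @param per_site If `TRUE`, count a true positive whenever the site is
#'   called somatic with the planted allele gained in at least one tumour.
#' @param gibbs,filters Passed to the caller.
#' @return Data frame: vaf, depth, base_q, n_loci, tp, sensitivity, se
#'   (binomial standard error).
#' @export
run_sensitivity_experiment <- function(vafs = c(0.1, 0.2, 0.3, 0.4, 0.5),
                                       depths = c(15L, 30L, 60L),
                                       base_q = 30, n_tumors = 4L,
                                       n_loci = 300L, seed = 1L,
                                       per_site = FALSE,
                                       gibbs = gibbs_config(),
                                       filters = filter_config()) {
  if (any(vafs <= 0)) {
    stop("sensitivity is undefined at vaf = 0; use run_fpr_experiment")
  }
  grid <- expand.grid(vaf = vafs, depth = depths)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    vaf <- grid$vaf[g]; depth <- grid$depth[g]
    cfg <- simulation_config(n_tumors = n_tumors, depth = depth, vaf = vaf,
                             base_q = base_q, n_loci = n_loci,
                             seed = seed + 1000L * g,
                             chrom = sprintf("sens_v%g_d%d", vaf, depth))
    sim <- simulate_pileup(cfg)
    tp <- count_true_positives(sim, cfg, seed, per_site, gibbs, filters)
    s <- tp / n_loci
    data.frame(vaf = vaf, depth = depth, base_q = base_q, n_loci = n_loci,
               tp = tp, sensitivity = s,
               se = sqrt(s * (1 - s) / n_loci))
  })
  do.call(rbind, rows)
}

count_true_positives <- function(sim, cfg, seed, per_site, gibbs, filters) {
  # benchmarks analyse the reads at their simulated quality, so only the
  # nonzero-depth rule is applied (min_base_q = 0 keeps every read)
  kept_idx <- which(!vapply(
    lapply(sim$loci, apply_quality_filters, min_base_q = 0),
    is.null, logical(1)))
  loci <- sim$loci[kept_idx]
  if (length(loci) == 0L) return(0L)
  pc <- prior_config_from_coverage(rep(cfg$depth, cfg$n_tumors + 1L))
  res <- call_loci(loci, pc, gibbs, filters, seed, keep_table = FALSE)
  tp <- 0L
  alt_by_pos <- setNames(sim$truth$alt, sim$truth$pos)
  for (cl in res$calls) {
    alt <- alt_by_pos[[as.character(cl$pos)]]
    hit <- vapply(cl$gained, function(g) alt %in% g, logical(1))
    if ((per_site && any(hit)) || (!per_site && all(hit))) tp <- tp + 1L
  }
  tp
}

#' False-positive-rate benchmark
#'
#' Simulates loci with no somatic variant (`vaf = 0`) — every non-reference
#' read is pure sequencing error — and reports the rate of loci called
#' somatic, scaled to false positives per megabase (one locus = one base).
#' With `contamination > 0` the tumour samples carry a true shared SNV
#' (`vaf` then defaults to 0.5) and a fraction of normal reads show it; a
#' false positive is then any locus where some sample's call is wrong
#' (normal not homozygous reference, or a tumour composition other than
#' \{ref\} / \{ref, alt\}); missing the planted SNV entirely is a false
#' negative, not counted here.
#'
#' @param base_qs Constant base qualities to test.
#' @param depths Sequencing depths to test.
#' @param vaf Tumour variant allele frequency (0 for the pure-noise arm).
#' @param contamination Fraction of tumour cells in the normal.
#' @param n_loci Simulated loci per configuration.
#' @param n_tumors Number of tumour samples.
#' @param seed Base seed.
#' @param chunk Loci are simulated and called in chunks of this size to
#'   bound memory.
#' @param gibbs,filters Passed to the caller.
#' @return Data frame: base_q, depth, vaf, contamination, n_loci, fp,
#'   fpr_per_mb, se (binomial SE on the per-Mb scale).
#' @export
run_fpr_experiment <- function(base_qs = c(15, 20, 30),
                               depths = c(10L, 30L, 60L), vaf = 0,
                               contamination = 0, n_loci = 10000L,
                               n_tumors = 4L, seed = 1L, chunk = 5000L,
                               gibbs = gibbs_config(),
                               filters = filter_config()) {
  if (n_loci <= 0) stop("n_loci must be positive")
  if (contamination > 0 && vaf == 0) vaf <- 0.5
  grid <- expand.grid(base_q = base_qs, depth = depths)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    bq <- grid$base_q[g]; depth <- grid$depth[g]
    fp <- 0L
    done <- 0L; chunk_i <- 0L
    while (done < n_loci) {
      m <- min(chunk, n_loci - done)
      chunk_i <- chunk_i + 1L
      cfg <- simulation_config(n_tumors = n_tumors, depth = depth,
                               vaf = vaf, base_q = bq,
                               contamination = contamination, n_loci = m,
                               seed = seed + 10000L * g + chunk_i,
                               chrom = sprintf("fpr_q%g_d%d", bq, depth))
      sim <- simulate_pileup(cfg, start_pos = done + 1L)
      fp <- fp + count_false_positives(sim, cfg, seed, gibbs, filters)
      done <- done + m
    }
    rate <- fp / n_loci
    data.frame(base_q = bq, depth = depth, vaf = vaf,
               contamination = contamination, n_loci = n_loci, fp = fp,
               fpr_per_mb = rate * 1e6,
               se = sqrt(rate * (1 - rate) / n_loci) * 1e6)
  })
  do.call(rbind, rows)
}

count_false_positives <- function(sim, cfg, seed, gibbs, filters) {
  kept <- lapply(sim$loci, apply_quality_filters, min_base_q = 0)
  idx <- which(!vapply(kept, is.null, logical(1)))
  if (length(idx) == 0L) return(0L)
  pc <- prior_config_from_coverage(rep(cfg$depth, cfg$n_tumors + 1L))
  res <- call_loci(kept[idx], pc, gibbs, filters, seed,
                   keep_table = cfg$contamination > 0)
  if (cfg$contamination == 0) return(res$n_somatic)
  # contamination arm: wrong-call definition against the planted truth
  tab <- res$loci
  truth <- sim$truth[match(tab$pos, sim$truth$pos), ]
  ok_tum <- mapply(function(tums, ref, alt) {
    comps <- strsplit(tums, ",", fixed = TRUE)[[1]]
    all(comps %in% c(ref, paste0(min(ref, alt), max(ref, alt))))
  }, tab$tumors, truth$ref, truth$alt)
  sum(tab$normal != truth$ref | !ok_tum)
}
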