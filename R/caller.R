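#' Classify per-tumour somatic status
#'
#' Compares each tumour's inferred allelic composition with the normal's.
#' Alleles in the tumour but not the normal are "gained" (somatic SNV
#' candidates); alleles in the normal but not the tumour are "lost"
#' (loss of heterozygosity).  Statuses:
#' \describe{
#'   \item{REF_LIKE}{tumour = normal = \{ref\}}
#'   \item{GERMLINE_ONLY}{tumour = normal, but not \{ref\} (a germline
#'     variant, not somatic)}
#'   \item{SOMATIC_SNV}{gained non-empty, lost empty}
#'   \item{LOH}{lost non-empty, gained empty}
#'   \item{SOMATIC_SNV_AND_LOH}{both non-empty}
#' }
#' A site is somatic when any tumour status is SOMATIC_SNV, LOH or
#' SOMATIC_SNV_AND_LOH.  Unlike strictly pairwise callers this also calls
#' SNVs on germline-heterozygous sites and sites where no allele matches
#' the reference.
#'
#' @param S_N Normal composition label.
#' @param S_Ts Character vector of tumour composition labels.
#' @param ref Reference allele.
#' @return List with per-tumour `status`, `gained`, `lost` (lists of allele
#'   vectors), and a scalar `somatic` flag.
#' @export
classify <- function(S_N, S_Ts, ref) {
  nm <- composition_alleles(S_N)
  gained <- vector("list", length(S_Ts))
  lost <- vector("list", length(S_Ts))
  status <- character(length(S_Ts))
  for (i in seq_along(S_Ts)) {
    tm <- composition_alleles(S_Ts[i])
    g <- setdiff(tm, nm); l <- setdiff(nm, tm)
    gained[[i]] <- g; lost[[i]] <- l
    status[i] <- if (length(g) && length(l)) "SOMATIC_SNV_AND_LOH"
      else if (length(g)) "SOMATIC_SNV"
      else if (length(l)) "LOH"
      else if (identical(sort(nm), ref)) "REF_LIKE"
      else "GERMLINE_ONLY"
  }
  list(status = status, gained = gained, lost = lost,
       somatic = any(!status %in% c("REF_LIKE", "GERMLINE_ONLY")))
}

# Two-sided Fisher exact p for a 2x2 table, computed as the sum of
# conditional hypergeometric probabilities not exceeding the observed one
# (the same definition stats::fisher.test uses, with its relative tolerance
# of 1e-7).  Vector-friendly over the table support, hence fast enough for
# exhaustive enumeration checks.
fisher2x2_p <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  if (m + n == 0L) return(1)
  x <- max(0L, k - n):min(k, m)
  logp <- lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)
  p <- exp(logp)
  obs <- p[x == a]
  min(1, sum(p[p <= obs * (1 + 1e-7)]))
}

#' Pooled strand-bias test
#'
#' Fisher's exact test for strand bias, pooling reads across all tumour
#' samples whose call gains the tested allele — pooling first increases the
#' read count and hence power compared with per-sample testing.  The 2x2
#' table counts forward/reverse reads supporting the gained allele versus
#' reads supporting any allele of the normal composition.  With several
#' gained alleles, one test is run per allele and the minimum p is
#' reported, tagged with its allele.
#'
#' @param tumor_cols Sample columns of the tumours whose call gains the
#'   allele(s) under test.
#' @param gained Character vector of gained alleles to test.
#' @param S_N Normal composition label (its alleles form the comparison
#'   row).
#' @return Numeric p-value with attributes `allele` (which gained allele
#'   attained it) and, when the pooled table was empty, `empty = TRUE`
#'   (p = 1 with a warning).
#' @examples
#' # perfectly balanced table -> p = 1
#' col <- list(allele = rep(c(2L, 1L), each = 4),
#'             forward = rep(c(TRUE, FALSE), 4),
#'             error_prob = rep(1e-3, 8))
#' strand_bias_pvalue(list(col), "C", "A")
#' @export
strand_bias_pvalue <- function(tumor_cols, gained, S_N) {
  norm_idx <- match(composition_alleles(S_N), ALLELES)
  best <- 1; best_allele <- NA_character_; any_reads <- FALSE
  for (b in gained) {
    bi <- match(b, ALLELES)
    bf <- br <- nf <- nr <- 0L
    for (col in tumor_cols) {
      bf <- bf + sum(col$allele == bi & col$forward)
      br <- br + sum(col$allele == bi & !col$forward)
      nf <- nf + sum(col$allele %in% norm_idx & col$forward)
      nr <- nr + sum(col$allele %in% norm_idx & !col$forward)
    }
    if (bf + br + nf + nr > 0L) any_reads <- TRUE
    p <- fisher2x2_p(bf, br, nf, nr)
    if (p <= best) { best <- p; best_allele <- b }
  }
  if (!any_reads) {
    warning("empty pooled strand-bias table; p set to 1")
    return(structure(1, allele = NA_character_, empty = TRUE))
  }
  structure(best, allele = best_allele)
}

#' High-confidence filter configuration
#'
#' Post-hoc filters marking calls that look artefactual: strand-biased
#' variant support, too few variant reads, shallow normal coverage, or a
#' non-converged chain.  A call with an empty flag set is "high
#' confidence".  This filter set is deliberately simple and fully
#' configurable; thresholds default to conservative values that prune
#' weakly supported sites without touching strong calls.
#'
#' @param strand_bias_alpha Flag when the pooled strand-bias p falls below
#'   this (default 0.01).
#' @param min_variant_reads Minimum pooled reads supporting a gained allele
#'   (default 2).
#' @param min_normal_depth Minimum post-filter normal depth (default 10).
#' @param require_converged Flag non-converged loci (default TRUE).
#' @return A `filter_config` list.
#' @export
filter_config <- function(strand_bias_alpha = 0.01, min_variant_reads = 2L,
                          min_normal_depth = 10L, require_converged = TRUE) {
  stopifnot(strand_bias_alpha >= 0, min_variant_reads >= 0,
            min_normal_depth >= 0)
  structure(list(strand_bias_alpha = strand_bias_alpha,
                 min_variant_reads = as.integer(min_variant_reads),
                 min_normal_depth = as.integer(min_normal_depth),
                 require_converged = isTRUE(require_converged)),
            class = "filter_config")
}

#' Apply high-confidence filters to a somatic call
#'
#' @param call A single-call record as produced by the pipeline (list with
#'   `strand_bias_p`, `variant_reads`, `normal_depth`, `converged`).
#' @param cfg A [filter_config()].
#' @return Character vector of flags (possibly empty): `STRAND_BIAS`,
#'   `LOW_VARIANT_READS`, `LOW_NORMAL_DEPTH`, `NO_CONVERGENCE`.
#' @export
apply_filters <- function(call, cfg = filter_config()) {
  flags <- character(0)
  if (!is.null(call$strand_bias_p) && !is.na(call$strand_bias_p) &&
      call$strand_bias_p < cfg$strand_bias_alpha) {
    flags <- c(flags, "STRAND_BIAS")
  }
  if (call$variant_reads < cfg$min_variant_reads) {
    flags <- c(flags, "LOW_VARIANT_READS")
  }
  if (call$normal_depth < cfg$min_normal_depth) {
    flags <- c(flags, "LOW_NORMAL_DEPTH")
  }
  if (cfg$require_converged && !call$converged) {
    flags <- c(flags, "NO_CONVERGENCE")
  }
  flags
}

#' Write somatic calls as VCF 4.2
#'
#' One record per somatic site.  ALT lists the union of gained alleles over
#' tumours; INFO carries the pooled strand-bias p (`SBP`, with `SBA` its
#' allele), sweeps run (`SWEEPS`) and convergence (`CONV`); FORMAT fields
#' give each sample's inferred composition (`CMP`), status (`SST`), depth
#' (`DP`), per-base allele depths (`ADS`, A/C/G/T order) and variant allele
#' fraction over gained alleles (`VF`).  FILTER is `PASS` or the
#' semicolon-joined flag set.
#'
#' @param calls List of call records (as built by [jointsnv()]), sorted by
#'   (chrom, pos); unsorted input is an error.
#' @param sample_names Character names, normal first.
#' @param path Optional file path; when `NULL` the VCF lines are returned.
#' @return Character vector of VCF lines (invisibly when written to file).
#' @export
write_vcf <- function(calls, sample_names, path = NULL) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=jointsnv",
    "##INFO=<ID=SBP,Number=1,Type=Float,Description=\"Pooled strand-bias Fisher exact p-value\">",
    "##INFO=<ID=SBA,Number=1,Type=String,Description=\"Gained allele attaining the strand-bias p\">",
    "##INFO=<ID=SWEEPS,Number=1,Type=Integer,Description=\"Gibbs sweeps run\">",
    "##INFO=<ID=CONV,Number=0,Type=Flag,Description=\"Chain converged\">",
    "##FILTER=<ID=STRAND_BIAS,Description=\"Strand-bias p below threshold\">",
    "##FILTER=<ID=LOW_VARIANT_READS,Description=\"Too few pooled variant reads\">",
    "##FILTER=<ID=LOW_NORMAL_DEPTH,Description=\"Normal depth below threshold\">",
    "##FILTER=<ID=NO_CONVERGENCE,Description=\"Gibbs chain did not converge\">",
    "##FORMAT=<ID=CMP,Number=1,Type=String,Description=\"Inferred allelic composition\">",
    "##FORMAT=<ID=SST,Number=1,Type=String,Description=\"Somatic status\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Post-filter depth\">",
    "##FORMAT=<ID=ADS,Number=4,Type=Integer,Description=\"Read depth per allele (A,C,G,T)\">",
    "##FORMAT=<ID=VF,Number=1,Type=Float,Description=\"Variant allele fraction over gained alleles\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_names), collapse = "\t"))
  somatic <- Filter(function(cl) isTRUE(cl$somatic), calls)
  if (length(somatic) >= 2L) {
    key_chrom <- vapply(somatic, `[[`, character(1), "chrom")
    key_pos <- vapply(somatic, `[[`, numeric(1), "pos")
    if (is.unsorted(order(key_chrom, key_pos))) {
      # order() of a sorted stream is 1..n; anything else means unsorted
      stop("calls must be sorted by (chrom, pos)")
    }
  }
  recs <- vapply(somatic, function(cl) {
    alt <- sort(unique(unlist(cl$gained)))
    info <- paste0(
      if (!is.na(cl$strand_bias_p))
        sprintf("SBP=%.6g;SBA=%s;", cl$strand_bias_p, cl$strand_bias_allele)
      else "",
      "SWEEPS=", cl$sweeps_run, if (cl$converged) ";CONV" else "")
    fmt <- vapply(seq_along(cl$sample_comps), function(k) {
      ads <- cl$allele_depths[k, ]
      vf <- if (length(alt)) sum(ads[alt]) / max(1, sum(ads)) else 0
      paste(cl$sample_comps[k], cl$sample_status[k], sum(ads),
            paste(ads, collapse = ","), sprintf("%.4g", vf), sep = ":")
    }, character(1))
    filt <- if (length(cl$filter_flags)) paste(cl$filter_flags,
                                               collapse = ";") else "PASS"
    paste(c(cl$chrom, cl$pos, ".", cl$ref, paste(alt, collapse = ","), ".",
            filt, info, "CMP:SST:DP:ADS:VF", fmt), collapse = "\t")
  }, character(1))
  lines <- c(hdr, recs)
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
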