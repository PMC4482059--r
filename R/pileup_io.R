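#' Parse one samtools mpileup line
#'
#' Decodes a multi-sample `samtools mpileup` text line (Phred+33 qualities)
#' into a locus pileup: reference base plus, per sample, the called allele,
#' strand and error probability of every read.  The mpileup base-string
#' dialect is handled as follows: `.`/`,` resolve to the reference allele on
#' the forward/reverse strand; upper/lower case letters to that allele on the
#' forward/reverse strand; `^` consumes the following mapping-quality
#' character; `$` is consumed; `+k<seq>`/`-k<seq>` indel descriptors are
#' consumed without emitting reads; `*`, `>`, `<` and `N`/`n` are consumed
#' without emitting reads (they also consume their quality character).
#'
#' @param line A single mpileup text line with `3 + 3 * n_samples`
#'   tab-separated fields (chrom, pos, ref, then depth/bases/quals per
#'   sample).
#' @param n_samples Total number of sample columns expected (normal +
#'   tumours).
#' @param normal_index Which sample column holds the matched normal
#'   (default 1, the first column after the reference).
#' @param line_num Optional line number used in error messages.
#' @return A `locus_pileup`: list with `chrom`, `pos` (1-based), `ref`, a
#'   `normal` sample column and a list `tumors` of the remaining columns.
#'   Each sample column holds `depth_raw` (depth as reported by mpileup),
#'   and parallel vectors `allele` (indices into A,C,G,T), `forward`
#'   (logical strand) and `error_prob` (`10^(-Q/10)`).
#' @examples
#' parse_mpileup_line("chr1\t100\tA\t4\t..,,\tIIII", n_samples = 1)
#' @export
parse_mpileup_line <- function(line, n_samples, normal_index = 1L,
                               line_num = NA_integer_) {
  fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
  where <- if (is.na(line_num)) "" else paste0(" at line ", line_num)
  if (length(fields) != 3L + 3L * n_samples) {
    stop("malformed mpileup line", where, ": expected ", 3L + 3L * n_samples,
         " fields, found ", length(fields))
  }
  ref <- toupper(fields[3L])
  if (!ref %in% ALLELES) {
    stop("reference base must be one of A,C,G,T", where, " (got '",
         fields[3L], "')")
  }
  ref_i <- match(ref, ALLELES)
  cols <- vector("list", n_samples)
  for (k in seq_len(n_samples)) {
    depth <- as.integer(fields[3L + 3L * (k - 1L) + 1L])
    bases <- fields[3L + 3L * (k - 1L) + 2L]
    quals <- fields[3L + 3L * (k - 1L) + 3L]
    cols[[k]] <- decode_base_string(bases, quals, ref_i, where)
    cols[[k]]$depth_raw <- depth
  }
  new_locus_pileup(chrom = fields[1L], pos = as.integer(fields[2L]), ref = ref,
                   samples = cols, normal_index = normal_index)
}

new_locus_pileup <- function(chrom, pos, ref, samples, normal_index = 1L) {
  structure(list(chrom = chrom, pos = pos, ref = ref,
                 normal = samples[[normal_index]],
                 tumors = samples[-normal_index]),
            class = "locus_pileup")
}

# Walk an mpileup base string together with its quality string.  Reads are
# emitted for . , and letters; *, >, < and N consume a quality character but
# emit nothing; ^X, $ and indel descriptors consume no quality character.
decode_base_string <- function(bases, quals, ref_i, where = "") {
  if (bases == "*" && quals == "*") {           # samtools placeholder, depth 0
    return(list(allele = integer(0), forward = logical(0),
                error_prob = numeric(0)))
  }
  bc <- strsplit(bases, "", fixed = TRUE)[[1]]
  err <- 10^(-(utf8ToInt(quals) - 33L) / 10)
  n <- length(bc)
  allele <- integer(n); forward <- logical(n); epos <- integer(n)
  i <- 1L; q <- 1L; out <- 0L
  while (i <= n) {
    ch <- bc[i]
    if (ch == "^") {                 # start-of-read marker + mapping quality
      i <- i + 2L
    } else if (ch == "$") {
      i <- i + 1L
    } else if (ch == "+" || ch == "-") {       # indel descriptor: +k<seq>
      j <- i + 1L
      while (j <= n && bc[j] >= "0" && bc[j] <= "9") j <- j + 1L
      len <- as.integer(paste(bc[(i + 1L):(j - 1L)], collapse = ""))
      i <- j + len
    } else if (ch == "*" || ch == ">" || ch == "<" || ch == "N" || ch == "n") {
      q <- q + 1L                    # placeholder: consumes a quality, no read
      i <- i + 1L
    } else {
      if (ch == "." ) { a <- ref_i; fwd <- TRUE }
      else if (ch == ",") { a <- ref_i; fwd <- FALSE }
      else {
        a <- match(toupper(ch), ALLELES)
        if (is.na(a)) stop("unexpected mpileup base symbol '", ch, "'", where)
        fwd <- ch %in% ALLELES       # upper case = forward strand
      }
      out <- out + 1L
      allele[out] <- a; forward[out] <- fwd; epos[out] <- q
      q <- q + 1L
      i <- i + 1L
    }
  }
  if (q - 1L != length(err)) {
    stop("base and quality strings disagree in length after decoding", where,
         ": consumed ", q - 1L, " qualities, have ", length(err))
  }
  keep <- seq_len(out)
  list(allele = allele[keep], forward = forward[keep],
       error_prob = err[epos[keep]])
}

#' Read a whole mpileup file
#'
#' @param path Path to an mpileup text file, or a character vector of lines.
#' @inheritParams parse_mpileup_line
#' @return List of [parse_mpileup_line()] results, one per input line.
#' @export
read_mpileup <- function(path, n_samples, normal_index = 1L) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  lines <- lines[nzchar(lines)]
  lapply(seq_along(lines), function(i) {
    parse_mpileup_line(lines[i], n_samples, normal_index, line_num = i)
  })
}

#' Base-quality and depth filtering
#'
#' Removes reads whose error probability exceeds the Phred threshold
#' (`error_prob > 10^(-min_base_q/10)`), then checks that every sample keeps
#' at least `min_depth` reads.  The default `min_depth = 1` implements the
#' rule that only sites with nonzero depth in all samples are analysed.
#' Mapping-quality filtering is expected to have happened upstream when the
#' mpileup was generated (e.g. `samtools mpileup -q 30`); mpileup text does
#' not carry per-read mapping qualities.
#'
#' @param locus A `locus_pileup`.
#' @param min_base_q Minimum base quality (Phred) for a read to be kept.
#' @param min_depth Minimum surviving depth required in every sample.
#' @return The filtered `locus_pileup`, or `NULL` (a skip signal) if any
#'   sample drops below `min_depth`.
#' @export
apply_quality_filters <- function(locus, min_base_q = 20, min_depth = 1L) {
  thresh <- 10^(-min_base_q / 10)
  filt <- function(col) {
    keep <- col$error_prob <= thresh
    col$allele <- col$allele[keep]
    col$forward <- col$forward[keep]
    col$error_prob <- col$error_prob[keep]
    col
  }
  locus$normal <- filt(locus$normal)
  locus$tumors <- lapply(locus$tumors, filt)
  depths <- c(length(locus$normal$allele),
              vapply(locus$tumors, function(t) length(t$allele), integer(1)))
  if (any(depths < min_depth)) return(NULL)
  locus
}

#' Allele counts for one sample column
#'
#' @param col A sample column from a `locus_pileup`.
#' @param by_strand If `TRUE`, return a 2 x 4 matrix of forward/reverse
#'   counts (used by the pooled strand-bias test); otherwise a length-4
#'   named count vector over A,C,G,T.
#' @return Integer counts; they sum to the number of decoded reads.
#' @export
allele_counts <- function(col, by_strand = FALSE) {
  if (!by_strand) {
    return(setNames(tabulate(col$allele, nbins = 4L), ALLELES))
  }
  m <- rbind(forward = tabulate(col$allele[col$forward], nbins = 4L),
             reverse = tabulate(col$allele[!col$forward], nbins = 4L))
  colnames(m) <- ALLELES
  m
}

#' Per-sample median coverage
#'
#' Median of post-filter depths across loci, per sample (normal first, then
#' tumours in input order).  Used to scale the Dirichlet prior strengths on
#' allele fractions; may alternatively be supplied directly.
#'
#' @param loci Non-empty list of (filtered) `locus_pileup` objects.
#' @return Numeric vector of length `n_tumors + 1`.
#' @export
median_coverage <- function(loci) {
  loci <- loci[!vapply(loci, is.null, logical(1))]
  if (length(loci) == 0L) stop("no loci available to compute median coverage")
  depths <- vapply(loci, function(l) {
    c(length(l$normal$allele),
      vapply(l$tumors, function(t) length(t$allele), integer(1)))
  }, numeric(1L + length(loci[[1]]$tumors)))
  if (is.null(dim(depths))) depths <- matrix(depths, nrow = 1)
  apply(depths, 1, median)
}

#' Serialise loci back to mpileup text
#'
#' Inverse of [parse_mpileup_line()] for decoded reads (no indels, carets or
#' placeholders survive decoding, so the output uses only `.`/`,`, letters
#' and Phred+33 qualities).  Used for fixtures and round-trip checks.
#'
#' @param loci List of `locus_pileup` objects.
#' @param path Optional output path; if `NULL` the lines are returned.
#' @return Character vector of mpileup lines (invisibly, if written).
#' @export
write_mpileup <- function(loci, path = NULL) {
  enc <- function(col, ref_i) {
    if (length(col$allele) == 0L) return(c("0", "*", "*"))
    ch <- ifelse(col$allele == ref_i,
                 ifelse(col$forward, ".", ","),
                 ifelse(col$forward, ALLELES[col$allele],
                        tolower(ALLELES[col$allele])))
    q <- intToUtf8(as.integer(round(-10 * log10(col$error_prob))) + 33L,
                   multiple = FALSE)
    c(as.character(length(col$allele)), paste(ch, collapse = ""), q)
  }
  lines <- vapply(loci, function(l) {
    ref_i <- match(l$ref, ALLELES)
    cols <- c(list(l$normal), l$tumors)
    paste(c(l$chrom, l$pos, l$ref,
            unlist(lapply(cols, enc, ref_i = ref_i))), collapse = "\t")
  }, character(1))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' @export
print.locus_pileup <- function(x, ...) {
  depths <- c(length(x$normal$allele),
              vapply(x$tumors, function(t) length(t$allele), integer(1)))
  cat("<locus_pileup> ", x$chrom, ":", x$pos, " ref=", x$ref,
      "  depths: N=", depths[1],
      if (length(depths) > 1)
        paste0(" T=", paste(depths[-1], collapse = ",")) else "",
      "\n", sep = "")
  invisible(x)
}
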