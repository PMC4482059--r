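# In-code fixtures and independent oracles shared across the suite.

ALL4 <- c("A", "C", "G", "T")

# Build a sample column directly (alleles as letters; constant or per-read
# Phred quality; strands default to alternating forward/reverse).
make_col <- function(alleles, q = 30, forward = NULL) {
  a <- match(alleles, ALL4)
  stopifnot(!anyNA(a))
  if (is.null(forward)) forward <- rep(c(TRUE, FALSE), length.out = length(a))
  list(depth_raw = length(a), allele = a, forward = forward,
       error_prob = rep(10^(-q / 10), length.out = length(a)))
}

make_locus <- function(ref, normal, tumors, chrom = "chr1", pos = 1L) {
  structure(list(chrom = chrom, pos = as.integer(pos), ref = ref,
                 normal = normal, tumors = tumors),
            class = "locus_pileup")
}

# Independent mpileup base-string decoder: regex-strips structural symbols,
# then zips the remaining per-read symbols with the quality string.  A
# deliberately different strategy from the package's stateful walker.
ref_decode <- function(bases, quals, ref) {
  b <- gsub("\\^.", "", bases)
  b <- gsub("$", "", b, fixed = TRUE)
  repeat {
    m <- regexpr("[+-][0-9]+", b)
    if (m == -1L) break
    digits <- substr(b, m + 1L, m + attr(m, "match.length") - 1L)
    skip <- attr(m, "match.length") + as.integer(digits)
    b <- paste0(substr(b, 1L, m - 1L), substr(b, m + skip, nchar(b)))
  }
  ch <- strsplit(b, "", fixed = TRUE)[[1]]
  q <- 10^(-(utf8ToInt(quals) - 33L) / 10)
  stopifnot(length(ch) == length(q))
  keep <- !(ch %in% c("*", ">", "<", "N", "n"))
  ch <- ch[keep]; q <- q[keep]
  allele <- ifelse(ch %in% c(".", ","), ref, toupper(ch))
  forward <- ch %in% c(".", ALL4)
  list(allele = match(allele, ALL4), forward = forward, error_prob = q)
}

# Random legal mpileup base/quality strings with a known read count.
rand_base_string <- function() {
  n_tok <- sample(0:12, 1)
  bases <- character(0); n_q <- 0L; n_reads <- 0L
  for (t in seq_len(n_tok)) {
    kind <- sample(c("read", "placeholder"), 1, prob = c(0.85, 0.15))
    if (kind == "read") {
      sym <- sample(c(".", ",", ALL4, tolower(ALL4)), 1)
      if (runif(1) < 0.15) sym <- paste0("^", intToUtf8(sample(33:90, 1)), sym)
      if (runif(1) < 0.15) sym <- paste0(sym, "$")
      if (runif(1) < 0.15) {
        k <- sample(c(1:4, 12), 1)
        sym <- paste0(sym, sample(c("+", "-"), 1), k,
                      paste(sample(ALL4, k, replace = TRUE), collapse = ""))
      }
      n_reads <- n_reads + 1L
    } else {
      sym <- sample(c("*", ">", "<", "N", "n"), 1)
    }
    n_q <- n_q + 1L
    bases <- c(bases, sym)
  }
  list(bases = paste(bases, collapse = ""),
       quals = intToUtf8(sample(33:73, n_q, replace = TRUE), multiple = FALSE),
       n_reads = n_reads, n_quals = n_q)
}

# Chi-square goodness-of-fit p-value with small-expectation cells pooled.
pool_chisq <- function(obs, p) {
  n <- sum(obs); e <- n * p
  o <- order(e); obs <- obs[o]; e <- e[o]
  while (length(e) > 1 && e[1] < 5) {
    e[2] <- e[2] + e[1]; obs[2] <- obs[2] + obs[1]
    e <- e[-1]; obs <- obs[-1]
    o2 <- order(e); e <- e[o2]; obs <- obs[o2]
  }
  if (length(e) < 2) return(1)
  stats::pchisq(sum((obs - e)^2 / e), df = length(e) - 1, lower.tail = FALSE)
}

# Grid-search maximiser of the Dirichlet posterior density over the simplex
# restricted to composition S (coarse pass at 1e-2, refined at 1e-4).
grid_map_oracle <- function(v, S, a) {
  m <- match(strsplit(S, "")[[1]], ALL4); M <- length(m)
  f <- numeric(4)
  if (M == 1) { f[m] <- 1; return(f) }
  logpost <- function(x) sum((v[m] + a - 1) * log(x))
  best <- NULL; bv <- -Inf
  scan <- function(lo, hi, step) {
    for (x in seq(max(0, lo[1]), min(1, hi[1]), by = step)) {
      if (M == 2) {
        val <- logpost(c(x, 1 - x))
        if (is.finite(val) && val > bv) { bv <<- val; best <<- c(x, 1 - x) }
      } else {
        for (y in seq(max(0, lo[2]), min(1 - x, hi[2]), by = step)) {
          val <- logpost(c(x, y, 1 - x - y))
          if (is.finite(val) && val > bv) { bv <<- val; best <<- c(x, y, 1 - x - y) }
        }
      }
    }
  }
  scan(rep(0, M - 1), rep(1, M - 1), 1e-2)
  b <- best[seq_len(M - 1)]
  scan(b - 0.02, b + 0.02, 1e-4)
  f[m] <- best
  f
}

# Exact scan-kernel machinery for a one-tumour locus: stationary
# distribution of the 140 x 140 systematic-scan transition matrix.
scan_kernel_stationary <- function(locus, cfg) {
  labels <- enumerate_compositions(3)
  condN <- sapply(1:14, function(t) {
    conditional_distribution("normal", locus,
                             list(normal = NA, tumors = labels[t]), cfg)
  })
  condT <- sapply(1:10, function(nn) {
    conditional_distribution(1, locus,
                             list(normal = labels[nn], tumors = "A"), cfg)
  })
  P <- matrix(0, 140, 140)
  for (N in 1:10) for (T in 1:14) {
    for (N2 in 1:10) {
      P[(N - 1) * 14 + T, (N2 - 1) * 14 + seq_len(14)] <-
        condN[N2, T] * condT[, N2]
    }
  }
  pi <- rep(1 / 140, 140)
  repeat {
    pi2 <- as.numeric(pi %*% P)
    if (sum(abs(pi2 - pi)) < 1e-13) break
    pi <- pi2
  }
  pi2 / sum(pi2)
}

# Two-sided Fisher p by sorted-cumulative enumeration of the conditional
# hypergeometric pmf (independent of the package's lchoose-based sum).
enum_fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m + n == 0) return(1)
  x <- max(0, k - n):min(k, m)
  pr <- stats::dhyper(x, m, n, k)
  o <- order(pr)
  cum <- cumsum(pr[o])
  pa <- pr[x == a]
  min(1, cum[max(which(pr[o] <= pa * (1 + 1e-7)))])
}
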