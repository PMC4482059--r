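test_that("classification follows the gained/lost set definitions", {
  cl <- classify("A", c("AC"), "A")
  expect_equal(cl$status, "SOMATIC_SNV")
  expect_equal(cl$gained[[1]], "C")
  expect_length(cl$lost[[1]], 0)
  expect_true(cl$somatic)

  cl <- classify("AC", c("A"), "A")
  expect_equal(cl$status, "LOH")
  expect_equal(cl$lost[[1]], "C")

  cl <- classify("AC", c("AG"), "A")
  expect_equal(cl$status, "SOMATIC_SNV_AND_LOH")
  expect_equal(cl$gained[[1]], "G")
  expect_equal(cl$lost[[1]], "C")

  expect_equal(classify("A", "A", "A")$status, "REF_LIKE")
  expect_equal(classify("AC", "AC", "A")$status, "GERMLINE_ONLY")
  expect_false(classify("AC", c("AC", "AC"), "A")$somatic)
})

test_that("classification is exhaustively consistent over all state pairs", {
  # independent recomputation from the set-difference definition
  for (sn in enumerate_compositions(2)) {
    for (st in enumerate_compositions(3)) {
      cl <- classify(sn, st, "G")
      g <- setdiff(strsplit(st, "")[[1]], strsplit(sn, "")[[1]])
      l <- setdiff(strsplit(sn, "")[[1]], strsplit(st, "")[[1]])
      want <- if (length(g) && length(l)) "SOMATIC_SNV_AND_LOH"
        else if (length(g)) "SOMATIC_SNV"
        else if (length(l)) "LOH"
        else if (sn == "G") "REF_LIKE" else "GERMLINE_ONLY"
      expect_equal(cl$status, want)
      expect_equal(cl$somatic, length(g) + length(l) > 0)
    }
  }
})

test_that("strand-bias p matches Fisher's exact test and pools correctly", {
  # perfectly balanced table -> 1
  bal <- make_col(c(rep("C", 10), rep("A", 10)),
                  forward = rep(c(TRUE, FALSE), 10))
  expect_equal(as.numeric(strand_bias_pvalue(list(bal), "C", "A")), 1)
  # fully unbalanced 10/0 vs 0/10: p = 2 / choose(20, 10)
  unb <- make_col(c(rep("C", 10), rep("A", 10)),
                  forward = c(rep(TRUE, 10), rep(FALSE, 10)))
  expect_equal(as.numeric(strand_bias_pvalue(list(unb), "C", "A")),
               2 / choose(20, 10), tolerance = 1e-12)
  # pooling two samples of [[5,0],[0,5]] equals one [[10,0],[0,10]] table
  half <- make_col(c(rep("C", 5), rep("A", 5)),
                   forward = c(rep(TRUE, 5), rep(FALSE, 5)))
  expect_equal(as.numeric(strand_bias_pvalue(list(half, half), "C", "A")),
               as.numeric(strand_bias_pvalue(list(unb), "C", "A")))
  # agreement with stats::fisher.test on random tables
  set.seed(14)
  for (i in 1:200) {
    tab <- matrix(rpois(4, 6), 2)
    want <- stats::fisher.test(tab)$p.value
    got <- jointsnv:::fisher2x2_p(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    expect_equal(got, want, tolerance = 1e-9)
  }
  # empty pooled table warns and returns 1
  none <- make_col(rep("G", 4))
  expect_warning(p <- strand_bias_pvalue(list(none), "C", "A"), "empty")
  expect_equal(as.numeric(p), 1)
  # multiallelic: minimum p across gained alleles, tagged with its allele
  two <- make_col(c(rep("C", 8), rep("T", 4), rep("A", 8)),
                  forward = c(rep(TRUE, 8), rep(c(TRUE, FALSE), 2),
                              rep(FALSE, 8)))
  p <- strand_bias_pvalue(list(two), c("C", "T"), "A")
  expect_equal(attr(p, "allele"), "C")
  expect_lt(as.numeric(p), 0.01)
})

test_that("filter flags fire on their thresholds", {
  base <- list(strand_bias_p = 0.5, variant_reads = 10L, normal_depth = 30L,
               converged = TRUE)
  expect_length(apply_filters(base), 0)
  expect_equal(apply_filters(modifyList(base, list(strand_bias_p = 1e-6))),
               "STRAND_BIAS")
  expect_equal(apply_filters(modifyList(base, list(variant_reads = 1L))),
               "LOW_VARIANT_READS")
  expect_equal(apply_filters(modifyList(base, list(normal_depth = 3L))),
               "LOW_NORMAL_DEPTH")
  expect_equal(apply_filters(modifyList(base, list(converged = FALSE))),
               "NO_CONVERGENCE")
  expect_length(
    apply_filters(modifyList(base, list(converged = FALSE)),
                  filter_config(require_converged = FALSE)), 0)
})

test_that("VCF output is well-formed and parses back", {
  # no somatic site -> header-only
  lines <- write_vcf(list(), c("NORMAL", "TUMOR1"))
  expect_true(all(grepl("^#", lines)))
  expect_match(lines[length(lines)], "^#CHROM\t.*NORMAL\tTUMOR1$")

  cfg <- simulation_config(n_tumors = 2, depth = 50, vaf = 0.5, base_q = 30,
                           n_loci = 4, seed = 19)
  sim <- simulate_pileup(cfg)
  fit <- jointsnv(sim$loci, seed = 4)
  expect_equal(fit$n_somatic, 4L)
  lines <- vcf_lines(fit)
  recs <- lines[!grepl("^#", lines)]
  expect_length(recs, 4)
  parts <- strsplit(recs, "\t", fixed = TRUE)
  for (j in seq_along(parts)) {
    p <- parts[[j]]
    truth <- sim$truth[sim$truth$pos == as.integer(p[2]), ]
    expect_equal(p[4], truth$ref)
    expect_equal(p[5], truth$alt)
    # parse back FORMAT per sample and recover compositions and statuses
    fmt <- strsplit(p[9], ":", fixed = TRUE)[[1]]
    smp <- strsplit(p[10:12], ":", fixed = TRUE)
    cmp <- vapply(smp, `[`, character(1), which(fmt == "CMP"))
    sst <- vapply(smp, `[`, character(1), which(fmt == "SST"))
    cl <- fit$calls[[j]]
    expect_equal(cmp, unname(cl$sample_comps))
    expect_equal(sst, cl$sample_status)
    expect_equal(p[7], if (length(cl$filter_flags))
      paste(cl$filter_flags, collapse = ";") else "PASS")
  }
  # unsorted input is rejected
  expect_error(write_vcf(rev(fit$calls), fit$sample_names), "sorted")
})

test_that("cli produces deterministic VCF end-to-end", {
  skip_if_not_installed("optparse")
  cfg <- simulation_config(n_tumors = 2, depth = 50, vaf = 0.5, base_q = 30,
                           n_loci = 1, seed = 33)
  sim <- simulate_pileup(cfg)
  noise <- simulate_pileup(simulation_config(n_tumors = 2, depth = 50,
                                             vaf = 0, base_q = 30,
                                             n_loci = 5, seed = 34),
                           start_pos = 2)
  mp <- tempfile(fileext = ".pileup")
  write_mpileup(c(sim$loci, noise$loci), mp)
  out1 <- tempfile(fileext = ".vcf"); out2 <- tempfile(fileext = ".vcf")
  code <- cli_main(c("-i", mp, "-n", "3", "-o", out1, "--seed", "5",
                     "--log-level", "quiet"))
  expect_equal(code, 0L)
  recs <- grep("^#", readLines(out1), invert = TRUE, value = TRUE)
  expect_length(recs, 1)                      # exactly the planted site
  expect_equal(strsplit(recs, "\t")[[1]][2], "1")
  expect_equal(strsplit(recs, "\t")[[1]][5], sim$truth$alt)
  cli_main(c("-i", mp, "-n", "3", "-o", out2, "--seed", "5",
             "--log-level", "quiet"))
  expect_identical(readLines(out1), readLines(out2))  # byte-identical

  # empty input -> header-only VCF, zero exit
  empty <- tempfile(); file.create(empty)
  out3 <- tempfile(fileext = ".vcf")
  expect_equal(cli_main(c("-i", empty, "-n", "3", "-o", out3,
                          "--log-level", "quiet")), 0L)
  expect_true(all(grepl("^#", readLines(out3))))

  # bad arguments -> usage exit code; missing file -> I/O exit code
  expect_equal(suppressMessages(cli_main(c("-n", "3"))), 2L)
  expect_equal(suppressMessages(cli_main(c("-i", "/nonexistent", "-n", "3"))),
               3L)
})
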