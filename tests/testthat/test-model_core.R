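test_that("composition universes have the right size, order and contents", {
  n10 <- enumerate_compositions(2)
  n14 <- enumerate_compositions(3)
  expect_length(n10, 10)
  expect_length(n14, 14)
  expect_identical(n10, n14[1:10])
  expect_identical(n14[1:4], ALL4)                  # singletons first
  expect_true(all(nchar(n14) >= 1 & nchar(n14) <= 3))
  # canonical order: sizes non-decreasing, lexicographic within size
  expect_true(!is.unsorted(nchar(n14)))
  expect_error(enumerate_compositions(4))
  expect_equal(composition_alleles("ACT"), c("A", "C", "T"))
})

test_that("per-base likelihood follows the miscall mixture formula", {
  f <- c(1, 0, 0, 0)
  expect_equal(base_likelihood("A", 0, f), 1)
  expect_equal(base_likelihood("A", 0.03, f), 0.97)
  expect_equal(base_likelihood("C", 0.001, f), 0.001 / 3)
  # error branch at Q30, f_tau = 0: e/3 ~ 3.3333e-4
  expect_equal(base_likelihood("G", 1e-3, f), 1e-3 / 3)
  # e -> 0 limit: likelihood tends to f_tau
  f2 <- c(0.7, 0.3, 0, 0)
  expect_equal(base_likelihood("C", 1e-12, f2), 0.3, tolerance = 1e-9)
})

test_that("column log-likelihood is the product of per-read likelihoods", {
  expect_equal(log_data_likelihood(make_col(character(0)), c(1, 0, 0, 0)), 0)
  col <- make_col(c("A", "A"), q = 300)  # e ~ 1e-30
  expect_equal(log_data_likelihood(col, c(1, 0, 0, 0)), 0, tolerance = 1e-12)
  # brute-force oracle, reads A,A,C at e = 0.01 under f = (0.9, 0.1, 0, 0)
  col <- list(allele = c(1L, 1L, 2L), forward = rep(TRUE, 3),
              error_prob = rep(0.01, 3))
  f <- c(0.9, 0.1, 0, 0)
  per_read <- c((1 - 0.01) * 0.9 + (0.01 / 3) * 0.1,
                (1 - 0.01) * 0.9 + (0.01 / 3) * 0.1,
                (1 - 0.01) * 0.1 + (0.01 / 3) * 0.9)
  expect_equal(log_data_likelihood(col, f), sum(log(per_read)))
  # e -> 0 limit: multinomial log-likelihood
  col$error_prob <- rep(1e-12, 3)
  expect_equal(log_data_likelihood(col, f), 2 * log(0.9) + log(0.1),
               tolerance = 1e-9)
})

test_that("MAP allele fractions match the closed form and a grid search", {
  expect_equal(map_allele_fractions(c(5, 3, 2, 0), "A", 10), c(1, 0, 0, 0))
  expect_equal(map_allele_fractions(c(30, 30, 0, 0), "AC", 10),
               c(0.5, 0.5, 0, 0))
  expect_equal(map_allele_fractions(c(9, 1, 0, 0), "AC", 1),
               c(0.9, 0.1, 0, 0))
  f <- map_allele_fractions(c(4, 0, 7, 1), "AGT", 3)
  expect_equal(sum(f), 1)
  expect_equal(f[2], 0)          # off-composition alleles are zero
  set.seed(31)
  for (i in 1:40) {
    M <- sample(1:3, 1)
    S <- paste(sort(sample(ALL4, M)), collapse = "")
    v <- rpois(4, 8)
    a <- runif(1, 1, 20)
    expect_equal(map_allele_fractions(v, S, a), grid_map_oracle(v, S, a),
                 tolerance = 2e-4)
  }
})

test_that("tumour pseudocounts encode one-mutation-away structure", {
  cfg <- prior_config(n_tumors = 4)            # w = 50
  expect_equal(cfg$w, 50)
  d <- tumor_pseudocounts("A", cfg)
  expect_equal(unname(d["AC"]), 50 * 3e-7)     # gain of one allele
  expect_equal(unname(d["CG"]), 50 * (3e-7)^2) # any other transition
  expect_equal(unname(d["ACG"]), 50 * (3e-7)^2) # two gains is not "one away"
  expect_equal(tumor_pseudocount("A", "A", cfg),
               50 * (1 - 3 * 3e-7 - 10 * (3e-7)^2))
})

test_that("tumour pseudocounts sum exactly to w for every normal state", {
  cfg <- prior_config(n_tumors = 4)
  for (sn in enumerate_compositions(2)) {
    expect_identical(sum(tumor_pseudocounts(sn, cfg)), cfg$w)
  }
  # allele-loss transitions get the w*mu^2 (not w*mu) branch
  d <- tumor_pseudocounts("AC", cfg)
  expect_equal(unname(d["A"]), 50 * (3e-7)^2)
  expect_equal(unname(d["ACG"]), 50 * 3e-7)
})

test_that("tumour conditional prior normalises and rewards shared states", {
  cfg <- prior_config(n_tumors = 4)
  cc <- integer(14); cc[match("AC", enumerate_compositions(3))] <- 2
  cc[1] <- 1                                    # third other tumour at {A}
  cc_spec <- integer(14); cc_spec[match("AC", enumerate_compositions(3))] <- 2
  # direct-evaluation example: c_AC = 2 of n-1 = 3 others (denominator 3 + w)
  p <- tumor_conditional_prior("AC", cc_spec + c(1, rep(0, 13)), "A", cfg)
  expect_equal(p, (2 + 1.5e-5) / (3 + 50), tolerance = 1e-9)
  all_p <- vapply(1:14, tumor_conditional_prior, numeric(1),
                  c_counts = cc, S_N = "A", cfg = cfg)
  expect_equal(sum(all_p), 1, tolerance = 1e-12)
  # with no observed tumours the prior is delta_z / w, dominated by S_N
  p0 <- vapply(1:14, tumor_conditional_prior, numeric(1),
               c_counts = integer(14), S_N = "A", cfg = cfg)
  expect_equal(p0, unname(tumor_pseudocounts("A", cfg)) / 50)
  expect_gt(p0[1], 0.999999)
  # monotone coupling: one more observed copy strictly raises the prior
  for (z in c("AC", "A", "CGT")) {
    cc2 <- cc; cc2[match(z, enumerate_compositions(3))] <-
      cc2[match(z, enumerate_compositions(3))] + 1L
    expect_gt(tumor_conditional_prior(z, cc2, "A", cfg),
              tumor_conditional_prior(z, cc, "A", cfg))
  }
})

test_that("normal pseudocounts follow the four diploid categories", {
  cfg <- prior_config(n_tumors = 4)
  expect_equal(unname(normal_pseudocount("A", "A", cfg)), 49.925)
  expect_equal(unname(normal_pseudocount("AC", "A", cfg)), 50 * 3.34e-4)
  expect_equal(unname(normal_pseudocount("CG", "A", cfg)), 50 * 8.33e-8)
  expect_equal(unname(normal_pseudocount("C", "A", cfg)), 50 * 1.665e-4)
})

test_that("normal conditional prior excludes tri-allelic states and sums to 1", {
  cfg <- prior_config(n_tumors = 4)
  nz <- integer(10); nz[1] <- 4          # all four tumours currently {A}
  denom <- 4 + 50 * (0.9985 + 3 * 3.34e-4 + 3 * 8.33e-8 + 3 * 1.665e-4)
  expect_equal(normal_conditional_prior("A", nz, "A", cfg),
               (4 + 49.925) / denom, tolerance = 1e-12)
  expect_equal(normal_conditional_prior("ACG", nz, "A", cfg), 0)
  all_p <- vapply(1:10, normal_conditional_prior, numeric(1),
                  n_counts = nz, ref = "A", cfg = cfg)
  expect_equal(sum(all_p), 1, tolerance = 1e-12)
})

test_that("full conditionals are proper and recover obvious states", {
  cfg <- prior_config(n_tumors = 4, a_normal = 250, a_tumor = 12)
  # homozygous-reference normal: 50 reads A at Q30
  loc <- make_locus("A", make_col(rep("A", 50)),
                    replicate(4, make_col(c(rep("A", 30), rep("C", 30))),
                              simplify = FALSE))
  pN <- conditional_distribution("normal", loc,
                                 list(normal = "A", tumors = rep("A", 4)), cfg)
  expect_equal(names(which.max(pN)), "A")
  expect_gt(pN["A"], 0.999)
  # tumour with 30A/30C while the others sit at {A,C}
  pT <- conditional_distribution(1, loc,
                                 list(normal = "A", tumors = rep("AC", 4)),
                                 cfg)
  expect_equal(names(which.max(pT)), "AC")
  # empty column: conditional equals the prior exactly
  loc0 <- make_locus("A", make_col(character(0)),
                     list(make_col(character(0)), make_col(character(0))))
  cfg2 <- prior_config(n_tumors = 2)
  others <- list(normal = "A", tumors = c("AC", "AG"))
  pT0 <- conditional_distribution(1, loc0, others, cfg2)
  cc <- integer(14); cc[match("AG", enumerate_compositions(3))] <- 1
  prior <- vapply(1:14, tumor_conditional_prior, numeric(1),
                  c_counts = cc, S_N = "A", cfg = cfg2)
  expect_equal(unname(pT0), prior, tolerance = 1e-12)
  # every conditional is a probability vector
  set.seed(77)
  for (i in 1:20) {
    cfgs <- simulation_config(n_tumors = 3, depth = 12, vaf = runif(1),
                              base_q = 20, n_loci = 1, seed = 900 + i)
    l <- simulate_pileup(cfgs)$loci[[1]]
    pc <- prior_config(3, a_normal = 60, a_tumor = 2.4)
    p <- conditional_distribution(sample(c(list("normal"), as.list(1:3)), 1)[[1]],
                                  l, list(normal = "AC",
                                          tumors = c("A", "ACG", "T")), pc)
    expect_true(all(p >= 0))
    expect_equal(sum(p), 1, tolerance = 1e-10)
  }
})
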