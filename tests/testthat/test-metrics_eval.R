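test_that("info score matches hand evaluation of the formula", {
  # certainty: one-hot triples at a polymorphic site
  calls <- data.frame(p0 = c(1, 0, 0), p1 = c(0, 1, 0), p2 = c(0, 0, 1))
  expect_equal(info_score(calls), 1)

  # maximal uncertainty at theta = 1/2
  calls <- data.frame(p0 = rep(0.25, 4), p1 = rep(0.5, 4),
                      p2 = rep(0.25, 4))
  expect_equal(info_score(calls), 0)

  # independent hand evaluation on a 3-sample instance
  calls <- data.frame(p0 = c(0.9, 0.2, 0.6), p1 = c(0.1, 0.5, 0.3),
                      p2 = c(0.0, 0.3, 0.1))
  e <- calls$p1 + 2 * calls$p2
  f <- calls$p1 + 4 * calls$p2
  th <- sum(e) / 6
  expect_equal(info_score(calls),
               1 - sum(f - e^2) / (6 * th * (1 - th)))

  # allele-label symmetry: reversing each triple leaves info unchanged
  rev_calls <- data.frame(p0 = calls$p2, p1 = calls$p1, p2 = calls$p0)
  expect_equal(info_score(rev_calls), info_score(calls))

  # degenerate frequency
  expect_equal(info_score(data.frame(p0 = c(1, 1), p1 = c(0, 0),
                                     p2 = c(0, 0))), 1)
  expect_error(info_score(data.frame(p0 = c(0.5), p1 = c(0.1),
                                     p2 = c(0.1))), "malformed")

  # matrix backend agrees with the scalar function per site
  set.seed(61)
  a <- matrix(runif(40), 8, 5); b <- matrix(runif(40), 8, 5)
  p2 <- a * b; p0 <- (1 - a) * (1 - b); p1 <- 1 - p0 - p2
  im <- hapimpute:::info_score_matrix(p0, p1, p2)
  for (j in 1:5)
    expect_equal(im[j], info_score(data.frame(p0 = p0[, j], p1 = p1[, j],
                                              p2 = p2[, j])))
})

test_that("true r2 is the squared Pearson correlation with NA degeneracy", {
  truth <- c(0L, 1L, 2L, 1L)
  expect_equal(true_r2(as.numeric(truth), truth), 1)
  expect_equal(true_r2(2 - truth, truth), 1)  # sign-invariant
  dos <- c(0.1, 0.9, 1.8, 1.2)
  # independent covariance-formula evaluation
  cv <- mean((dos - mean(dos)) * (truth - mean(truth)))
  want <- cv^2 / (mean((dos - mean(dos))^2) * mean((truth - mean(truth))^2))
  expect_equal(true_r2(dos, truth), want)
  expect_true(is.na(true_r2(rep(1, 4), truth)))
  expect_true(is.na(true_r2(dos, rep(2L, 4))))
  expect_error(true_r2(dos, truth[1:3]), "mismatch")
})

test_that("minor allele frequency folds at one half", {
  expect_equal(maf_of(c(rep(1, 7), rep(0, 3))), 0.3)
  expect_equal(maf_of(rep(0, 5)), 0)
  expect_equal(maf_of(c(1L, rep(0L, 199))), 0.005)
  expect_equal(maf_of(c(2L, 1L, 0L, 1L), ploidy = 2), 0.5)
  expect_error(maf_of(integer(0)), "empty")
})

test_that("eval reports conserve counts across bins", {
  set.seed(71)
  n <- 300
  sites <- data.frame(pos = seq_len(n),
                      maf = runif(n, 0, 0.5),
                      info = runif(n),
                      true_r2 = ifelse(runif(n) < 0.1, NA, runif(n)))
  r <- eval_report(sites)
  expect_equal(sum(r$n_sites), n)
  expect_equal(sum(r$counts), n)
  expect_equal(rowSums(r$counts), as.vector(r$n_sites),
               ignore_attr = TRUE)
  expect_equal(sum(r$n_high_confidence), sum(sites$info > 0.8))
  expect_equal(sum(r$n_undefined_r2), sum(is.na(sites$true_r2)))
})

test_that("leave-one-out on a panel of duplicated samples is near perfect", {
  # every sample has an identical twin in the panel, so the held-out truth
  # is always recoverable from the twin
  f <- simulate_founders(10, 200, 2e5, seed = 81)
  base <- simulate_mosaic(f, 8, switch_rate = 1, mut_rate = 0, seed = 82)
  dup <- rbind(base$alleles, base$alleles)
  panel <- haplotype_panel(base$legend, dup)
  maf <- panel_maf(panel)
  typed <- which(maf >= 0.2)
  r <- leave_one_out_eval(panel, seq_len(n_site(panel)) %in% typed,
                          uniform_map(1, 2e5),
                          hmm_params(epsilon = 1e-6),
                          selection_spec("all"))
  expect_gt(min(r$mean_true_r2[r$n_sites > 0], na.rm = TRUE), 0.99)
  expect_error(leave_one_out_eval(panel, rep(FALSE, n_site(panel)),
                                  uniform_map(1, 2e5)), "empty")
  expect_error(leave_one_out_eval(panel, typed, uniform_map(1, 2e5),
                                  n_samples = 0), "at least one")
})

test_that("pseudo-GWAS with everything typed recovers the truth", {
  # study haplotypes that the reference panel can represent exactly: with
  # every site typed, the typed-site posterior mixture reproduces each
  # observed genotype and true r2 is 1 wherever it is defined
  sc <- quick_scenario(seed = 16)
  ref <- sc$ref_a
  study <- keep_haplotypes(ref, 1:8)
  r <- pseudo_gwas_eval(study, rep(TRUE, n_site(study)), ref, sc$map,
                        hmm_params(epsilon = 1e-6),
                        selection_spec("all"))
  s <- r$sites
  typed_r2 <- s$true_r2[!is.na(s$true_r2)]
  expect_gt(length(typed_r2), 100)
  expect_true(all(typed_r2 > 1 - 1e-6))
})

test_that("the generating panel imputes no worse than a subset of it", {
  wins <- 0
  for (s in 1:5) {
    sc <- quick_scenario(seed = 300 + s)
    full <- pseudo_gwas_eval(sc$study_truth, sc$typed_mask, sc$ref_a,
                             sc$map, spec = selection_spec("all"))
    sub <- pseudo_gwas_eval(sc$study_truth, sc$typed_mask,
                            keep_haplotypes(sc$ref_a, 1:16), sc$map,
                            spec = selection_spec("all"))
    wins <- wins + (mean_metric_below(full, 0.5) >=
                      mean_metric_below(sub, 0.5))
  }
  expect_gte(wins, 4)
})

test_that("config comparisons run on identical inputs and are deterministic", {
  sc <- quick_scenario(seed = 17)
  cmp1 <- compare_configs(sc, list(
    a_all = list(ref = sc$ref_a, spec = selection_spec("all")),
    a_ham = list(ref = sc$ref_a, spec = selection_spec("hamming", k = 20))))
  cmp2 <- compare_configs(sc, list(
    a_all = list(ref = sc$ref_a, spec = selection_spec("all")),
    a_ham = list(ref = sc$ref_a, spec = selection_spec("hamming", k = 20))))
  expect_identical(cmp1$r2_table, cmp2$r2_table)
  expect_equal(dim(cmp1$r2_table), c(6L, 2L))
  expect_error(compare_configs(sc, list(x = list(ref = sc$ref_a,
                                                 spec = selection_spec()))),
               "at least two")
})
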