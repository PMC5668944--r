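# Joint two-eQTL fitting, prediction, and independence-vs-relaxed comparison.

test_that("noiseless independence data is recovered exactly", {
  d <- simulate_two_eqtl_dataset(300, s_v1 = 1, s_v2 = -0.5,
                                 interaction_offset = 0,
                                 noise_sigma_log10 = 0, seed = 1)
  fit <- fit_independent_two_eqtl(log2(d$expression), d$diplotypes)
  expect_equal(unname(fit$s), c(1, -0.5), tolerance = 1e-5)
  expect_equal(2^fit$log2_e0, d$truth$e0, tolerance = 1e-4)
  expect_lt(fit$rss, 1e-8)
})

test_that("a monomorphic variant makes the independence fit unidentifiable", {
  set.seed(2)
  hap_a <- cbind(rbinom(100, 1, 0.5), 0L)     # v2 never varies
  hap_b <- cbind(rbinom(100, 1, 0.5), 0L)
  diplos <- phased_diplotypes(hap_a, hap_b)
  z <- rnorm(100)
  expect_afc_error(fit_independent_two_eqtl(z, diplos), "identifiability")
  expect_afc_error(fit_relaxed_two_eqtl(z, diplos), "identifiability")
})

test_that("the relaxed model nests independence and measures the interaction", {
  d0 <- simulate_two_eqtl_dataset(400, 0.8, -0.3, interaction_offset = 0,
                                  noise_sigma_log10 = 0, seed = 3)
  fr0 <- fit_relaxed_two_eqtl(log2(d0$expression), d0$diplotypes)
  expect_equal(fr0$s[["s_11"]], fr0$s[["s_10"]] + fr0$s[["s_01"]],
               tolerance = 1e-4)

  d1 <- simulate_two_eqtl_dataset(400, 0.8, -0.3, interaction_offset = 1,
                                  noise_sigma_log10 = 0, seed = 4)
  fr1 <- fit_relaxed_two_eqtl(log2(d1$expression), d1$diplotypes)
  expect_equal(fr1$s[["s_11"]] - (fr1$s[["s_10"]] + fr1$s[["s_01"]]), 1,
               tolerance = 1e-4)
  expect_lt(fr1$rss, 1e-8)
})

test_that("relaxed RSS never exceeds independence RSS", {
  set.seed(6)
  for (i in 1:15) {
    d <- simulate_two_eqtl_dataset(150, runif(1, -1.5, 1.5), runif(1, -1.5, 1.5),
                                   interaction_offset = runif(1, -1, 1),
                                   noise_sigma_log10 = 0.17)
    z <- log2(d$expression)
    fi <- fit_independent_two_eqtl(z, d$diplotypes)
    fr <- fit_relaxed_two_eqtl(z, d$diplotypes)
    expect_lte(fr$rss, fi$rss + 1e-8)
  }
})

test_that("parameters are recovered under realistic noise", {
  # generating effects match a strong/weak eQTL pair; 200 replicates
  set.seed(7)
  est <- t(replicate(200, {
    d <- simulate_two_eqtl_dataset(300, -0.77, -0.14, interaction_offset = 0,
                                   noise_sigma_log10 = 0.17)
    fit <- fit_independent_two_eqtl(log2(d$expression), d$diplotypes)
    fit$s
  }))
  expect_lt(abs(mean(est[, 1]) - (-0.77)), 0.05)
  expect_lt(abs(mean(est[, 2]) - (-0.14)), 0.05)
  expect_lt(sqrt(mean((est[, 1] + 0.77)^2)), 0.15)
  expect_lt(sqrt(mean((est[, 2] + 0.14)^2)), 0.15)
})

test_that("relaxed parameters are recovered under realistic noise", {
  set.seed(8)
  est <- t(replicate(200, {
    d <- simulate_two_eqtl_dataset(300, 0.6, -0.4, interaction_offset = 0.8,
                                   noise_sigma_log10 = 0.17)
    fit_relaxed_two_eqtl(log2(d$expression), d$diplotypes)$s
  }))
  truth <- c(0.6, -0.4, 0.6 - 0.4 + 0.8)
  for (j in 1:3) {
    expect_lt(abs(mean(est[, j]) - truth[j]), 0.06)
    expect_lt(sqrt(mean((est[, j] - truth[j])^2)), 0.2)
  }
})

test_that("haplotype log-ratio predictions follow the additive model", {
  d <- simulate_two_eqtl_dataset(300, -0.77, -0.14, interaction_offset = 0,
                                 noise_sigma_log10 = 0, seed = 9)
  fit <- fit_independent_two_eqtl(log2(d$expression), d$diplotypes)
  # double-alternative vs all-reference haplotype: effects add
  expect_equal(predict_haplotype_log_ratio(fit, c(1, 1, 0, 0)), -0.91,
               tolerance = 1e-4)
  # identical haplotypes predict no imbalance
  expect_equal(predict_haplotype_log_ratio(fit, c(1, 0, 1, 0)), 0)
  expect_equal(predict_haplotype_log_ratio(fit, c(0, 1, 0, 1)), 0)
  # opposing alleles: difference of the effects
  expect_equal(predict_haplotype_log_ratio(fit, c(1, 0, 0, 1)),
               fit$s[["s_v1"]] - fit$s[["s_v2"]], tolerance = 1e-10)
})

test_that("log aFC between haplotypes is additive, antisymmetric and a pseudometric", {
  d <- simulate_two_eqtl_dataset(250, 1.2, -0.7, interaction_offset = 0.5,
                                 noise_sigma_log10 = 0, seed = 10)
  fits <- list(fit_independent_two_eqtl(log2(d$expression), d$diplotypes),
               fit_relaxed_two_eqtl(log2(d$expression), d$diplotypes))
  haps <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  for (fit in fits) {
    s_of <- function(i, j) predict_haplotype_log_ratio(
      fit, c(haps[i, ], haps[j, ]))
    for (i in 1:4) {
      expect_equal(s_of(i, i), 0)                        # s_ii = 0
      for (j in 1:4) {
        expect_equal(s_of(i, j), -s_of(j, i), tolerance = 1e-12)  # sign swap
        for (k in 1:4) {
          # additivity s_ik = s_ij + s_jk, hence delta_i0 = delta_ij delta_j0
          expect_equal(s_of(i, k), s_of(i, j) + s_of(j, k), tolerance = 1e-12)
          # |s| satisfies the triangle inequality
          expect_lte(abs(s_of(i, k)), abs(s_of(i, j)) + abs(s_of(j, k)) + 1e-12)
        }
      }
    }
  }
})

test_that("predicted totals add the two haplotype expressions", {
  d <- simulate_two_eqtl_dataset(300, 1, 0, interaction_offset = 0,
                                 noise_sigma_log10 = 0, seed = 11)
  fit <- fit_independent_two_eqtl(log2(d$expression), d$diplotypes)
  e0 <- 2^fit$log2_e0
  expect_equal(predict_total_expression(fit, c(0, 0, 0, 0)), 2 * e0,
               tolerance = 1e-6)
  expect_equal(predict_total_expression(fit, c(1, 1, 0, 1)), 3 * e0,
               tolerance = 1e-4)
  # Eq.-30-style additivity for arbitrary diplotypes
  for (dip in list(c(1, 0, 0, 1), c(1, 1, 1, 0), c(0, 1, 0, 0))) {
    eA <- predict_total_expression(fit, c(dip[1:2], dip[1:2])) / 2
    eB <- predict_total_expression(fit, c(dip[3:4], dip[3:4])) / 2
    expect_equal(predict_total_expression(fit, dip), eA + eB,
                 tolerance = 1e-8)
  }
})

test_that("cis arrangement outexpresses trans iff the effects are sign-concordant", {
  for (s1 in c(-1.5, -0.4, 0.3, 2)) {
    for (s2 in c(-2, -0.1, 0.6, 1.1)) {
      fit <- structure(list(model = "independent", log2_e0 = 0,
                            s = c(s_v1 = s1, s_v2 = s2)),
                       class = "afc_two_eqtl_fit")
      cis <- predict_total_expression(fit, c(1, 1, 0, 0))
      trans <- predict_total_expression(fit, c(1, 0, 0, 1))
      if (sign(s1) == sign(s2) && s1 != 0 && s2 != 0) {
        expect_gt(cis, trans)
      } else {
        expect_lte(cis, trans + 1e-12)
      }
    }
  }
})

test_that("pinning the second effect to zero reduces to the single-eQTL fit", {
  set.seed(12)
  d <- simulate_two_eqtl_dataset(250, 1.1, 0, interaction_offset = 0,
                                 noise_sigma_log10 = 0.17)
  z <- log2(d$expression)
  fit2 <- fit_independent_two_eqtl(z, d$diplotypes, s_v2_fixed = 0)
  t1 <- d$diplotypes[, "a1"] + d$diplotypes[, "b1"]
  m2 <- suppressWarnings(fit_nonlinear_afc(z, t1))
  expect_equal(fit2$s[["s_v1"]], m2$log2_afc, tolerance = 1e-6)
})

test_that("identical fits differ in BIC exactly by the parameter penalty", {
  d <- simulate_two_eqtl_dataset(200, 0.9, -0.6, interaction_offset = 0,
                                 noise_sigma_log10 = 0, seed = 13)
  cmp <- compare_models(log2(d$expression), d$diplotypes, n_boot = 50, seed = 1)
  # noiseless independence data: both models fit perfectly up to optimizer
  # tolerance, so Delta BIC is the one-parameter penalty log N
  expect_equal(cmp$delta_bic, log(200), tolerance = 1e-4)
  expect_equal(cmp$selected, "independent")
})

test_that("model comparison fits with covariates and counts their parameters", {
  set.seed(14)
  n <- 200
  d <- simulate_two_eqtl_dataset(n, 0.8, -0.5, interaction_offset = 0,
                                 noise_sigma_log10 = 0.1)
  C <- matrix(rnorm(n), 1, n, dimnames = list("pc1", NULL))
  z <- log2(d$expression) + 0.6 * C[1, ]
  fi <- fit_independent_two_eqtl(z, d$diplotypes, C)
  expect_equal(fi$n_params, 4L)           # 1 covariate + 3
  expect_lt(abs(fi$alpha[["pc1"]] - 0.6), 0.05)
  expect_lt(abs(fi$s[["s_v1"]] - 0.8), 0.1)
  fr <- fit_relaxed_two_eqtl(z, d$diplotypes, C)
  expect_equal(fr$n_params, 5L)
  expect_lte(fr$rss, fi$rss + 1e-8)
})

test_that("a strong interaction is detected and selected", {
  d <- simulate_two_eqtl_dataset(200, 1, -0.5, interaction_offset = 1,
                                 noise_sigma_log10 = 0.05, seed = 15)
  cmp <- compare_models(log2(d$expression), d$diplotypes, n_boot = 200, seed = 2)
  expect_lt(cmp$delta_bic, 0)
  expect_equal(cmp$selected, "relaxed")
  expect_lt(cmp$delta_bic_ci[2], 0)
})
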