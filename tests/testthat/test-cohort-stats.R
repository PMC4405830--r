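test_that("logit/expit percent transforms are exact inverses", {
  p <- c(0.01, 0.5, 7, 25, 50, 71, 99.99)
  expect_equal(expit_percent(logit_percent(p)), p, tolerance = 1e-12)
  expect_equal(expit_percent(0), 50)
  expect_error(logit_percent(0), "percent")
})

test_that("lower-allele / lower-assay selection", {
  fits <- data.frame(sample_id = c("s1", "s2", "s2", "s3"),
                     assay = c("4qA", "4qA", "4qA-L", "4qA"),
                     y = c(logit_percent(7), logit_percent(12),
                           logit_percent(20), logit_percent(40)),
                     stringsAsFactors = FALSE)
  sel <- select_lower_allele(fits)
  expect_equal(nrow(sel), 3)
  expect_equal(sel$percent[sel$sample_id == "s1"], 7, tolerance = 1e-9)
  # two assays: the one with the smaller y wins and is recorded
  expect_equal(sel$chosen_assay[sel$sample_id == "s2"], "4qA")
  expect_equal(sel$percent[sel$sample_id == "s2"], 12, tolerance = 1e-9)
  # single-assay sample passes through
  expect_equal(sel$percent[sel$sample_id == "s3"], 40, tolerance = 1e-9)
  expect_error(select_lower_allele(fits[0, ]), "no per-assay fits")
})

test_that("LME recovers exact cell means on noise-free data", {
  grid <- expand.grid(disease_class = c("Control", "FSHD_a"),
                      cell_type = c("myocyte", "blood"),
                      rep = 1:2, family = 1:3,
                      stringsAsFactors = FALSE)
  truth <- c(Control.myocyte = 1, FSHD_a.myocyte = -2.5,
             Control.blood = 0.6, FSHD_a.blood = -2.1)
  df <- data.frame(sample_id = paste0("s", seq_len(nrow(grid))),
                   family_id = paste0("F", grid$family),
                   disease_class = grid$disease_class,
                   cell_type = grid$cell_type,
                   assay = "4qA",
                   y = truth[paste(grid$disease_class, grid$cell_type,
                                   sep = ".")],
                   stringsAsFactors = FALSE)
  # zero-variance data trip lme4's convergence heuristics; harmless here
  fit <- suppressWarnings(fit_lme(df))
  got <- fit$fixef[paste0("cell", paste(rep(c("myocyte", "blood"), each = 2),
                                        rep(c("Control", "FSHD_a"), 2),
                                        sep = "."))]
  want <- truth[paste(rep(c("Control", "FSHD_a"), 2),
                      rep(c("myocyte", "blood"), each = 2), sep = ".")]
  expect_equal(unname(got), unname(want), tolerance = 1e-6)
  expect_lt(fit$var_family + fit$var_resid, 1e-6)

  # permuting sample order leaves a (noisy-data) fit unchanged
  noisy <- simulate_cohort(seed = 88)
  fitn <- fit_lme(noisy)
  fitp <- fit_lme(noisy[rev(seq_len(nrow(noisy))), ])
  expect_equal(fitn$fixef, fitp$fixef, tolerance = 1e-6)
  expect_equal(fitn$loglik, fitp$loglik, tolerance = 1e-6)
})

test_that("likelihood-ratio test mechanics", {
  set.seed(77)
  df <- simulate_cohort(seed = 77)
  full <- fit_lme(df)
  same <- lrt(full, full)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  red <- fit_lme(df, collapse_classes = c("NonMfst", "FSHD_b"))
  out <- lrt(full, red)
  expect_gte(out$statistic, 0)
  expect_equal(out$df, full$n_par - red$n_par)
  expect_equal(out$p,
               stats::pchisq(out$statistic, out$df, lower.tail = FALSE))
  expect_error(lrt(red, full), "not nested")
})

test_that("exact paired sign test on the packaged cohort fixture", {
  tab <- read_cohort_table()
  st <- sign_test(tab)
  expect_equal(st$n, 9)
  expect_equal(st$n_positive, 9)
  expect_equal(st$p, 0.00390625)
  expect_true(st$consistent)
  # four duplicate-subject choice combinations (2 x 2), all the same
  expect_equal(nrow(st$choices), 4)
  expect_true(all(st$choices$p == 0.00390625))
})

test_that("sign test small cases and tie handling", {
  mk <- function(man, non) {
    do.call(rbind, lapply(seq_along(man), function(i)
      data.frame(cohort = i,
                 status = c("manifesting", "nonmanifesting"),
                 percent = c(man[i], non[i]))))
  }
  expect_equal(sign_test(mk(c(10, 20), c(15, 18)))$p, 1.0)
  expect_equal(sign_test(mk(c(10, 20, 30), c(15, 25, 35)))$p, 0.25)
  tied <- sign_test(mk(c(10, 20, 30), c(15, 25, 30)))
  expect_equal(tied$n, 2)  # the tie is excluded
  expect_error(sign_test(data.frame(cohort = 1, status = "manifesting",
                                    percent = 5)), "lacks one side")
})

test_that("repeat-unit calculation reproduces the cohort genotyping table", {
  tab <- unique(read_cohort_table()[, c("cohort", "kb", "ru")])
  expect_equal(ru_from_fragment(tab$kb), tab$ru)
  expect_equal(ru_from_fragment(5.3), 1)  # (5.3-2)/3.3 is exactly 1
  expect_equal(ru_from_fragment(29), 8)   # 8.18 rounds down
  expect_equal(ru_from_fragment(30), 8.5) # 8.48 rounds up to the half
  expect_error(ru_from_fragment(1.5), "invalid fragment")
})

test_that("group report back-transforms with asymmetric intervals", {
  set.seed(17)
  df <- simulate_cohort(seed = 17)
  fit <- fit_lme(df)
  rep_ <- group_report(fit)
  expect_true(all(rep_$lower_percent < rep_$percent))
  expect_true(all(rep_$percent < rep_$upper_percent))
  # hand-computed back-transform for one cell
  expect_equal(rep_$percent, expit_percent(rep_$estimate_logit))
  expect_equal(rep_$lower_percent,
               expit_percent(rep_$estimate_logit - rep_$se))
  # interval asymmetric away from 0, symmetric at 0
  up <- expit_percent(-2 + 0.5) - expit_percent(-2)
  dn <- expit_percent(-2) - expit_percent(-2 - 0.5)
  expect_gt(up, dn)
  expect_equal(expit_percent(0.5) - 50, 50 - expit_percent(-0.5))
})
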