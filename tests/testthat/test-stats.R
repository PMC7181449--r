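# extract F values for a 2x2 within design from stats::aov (independent route)
aov_2x2 <- function(d) {
  d$participant <- factor(d$participant)
  d$A <- factor(d$A); d$B <- factor(d$B)
  fit <- summary(stats::aov(y ~ A * B + Error(participant / (A * B)), data = d))
  get_f <- function(stratum, term) {
    tab <- fit[[stratum]][[1]]
    tab[trimws(rownames(tab)) == term, "F value"]
  }
  c(A = get_f("Error: participant:A", "A"),
    B = get_f("Error: participant:B", "B"),
    AB = get_f("Error: participant:A:B", "A:B"))
}

test_that("within-subject ANOVA matches stats::aov on random 2x2 tables", {
  set.seed(19)
  for (i in 1:20) {
    d <- table_2x2(matrix(rnorm(6 * 4, mean = 5), nrow = 6))
    mine <- rm_anova(d, "y", within = c("A", "B"))
    ref <- aov_2x2(d)
    expect_equal(mine$F, unname(ref[c("A", "B", "AB")]), tolerance = 1e-9)
    expect_equal(mine$df_num, c(1, 1, 1))
    expect_equal(mine$df_den, c(5, 5, 5))
  }
})

test_that("ANOVA sums of squares are conserved and F degenerates sensibly", {
  set.seed(23)
  d <- table_2x2(matrix(rnorm(8 * 4), nrow = 8))
  res <- rm_anova(d, "y", within = c("A", "B"))
  # conservation: effect + error SS together with subject SS give the total
  m_s <- tapply(d$y, d$participant, mean)
  ss_subject <- 4 * sum((m_s - mean(d$y))^2)
  expect_equal(sum(res$ss_effect) + sum(res$ss_error) + ss_subject,
               sum((d$y - mean(d$y))^2), tolerance = 1e-9)
  # all cells equal: F = 0 for every effect
  flat <- table_2x2(matrix(2.5, nrow = 4, ncol = 4))
  expect_equal(rm_anova(flat, "y", within = c("A", "B"))$F, c(0, 0, 0))
  # constant nonzero effect with zero participant-by-effect variance
  cells <- cbind(1, 1, 2, 2)[rep(1, 4), ]
  degenerate <- table_2x2(cells)
  expect_error(rm_anova(degenerate, "y", within = c("A", "B")),
               "zero error variance")
  # missing cell names the participant
  d_miss <- d[-1, ]
  expect_error(rm_anova(d_miss, "y", within = c("A", "B")), "S01")
})

test_that("relabelling factor levels leaves the 2x2 F values unchanged", {
  set.seed(29)
  d <- table_2x2(matrix(rnorm(7 * 4, 3), nrow = 7))
  rel <- d
  rel$A <- ifelse(d$A == "a1", "zz", "aa")
  rel$B <- ifelse(d$B == "b1", "q2", "q1")
  expect_equal(sort(rm_anova(rel, "y", within = c("A", "B"))$F),
               sort(rm_anova(d, "y", within = c("A", "B"))$F),
               tolerance = 1e-12)
})

test_that("4-level factors get a Greenhouse-Geisser epsilon in (1/(k-1), 1]", {
  set.seed(31)
  d <- expand.grid(participant = sprintf("S%02d", 1:10),
                   size = c("s1", "s2", "s3", "s4"),
                   cfgn = c("c1", "c2"), stringsAsFactors = FALSE)
  d$y <- rnorm(nrow(d)) + as.integer(factor(d$size)) * 0.2
  res <- rm_anova(d, "y", within = c("size", "cfgn"))
  eps <- res$gg_epsilon[res$effect == "size"]
  expect_gt(eps, 1 / 3)
  expect_lte(eps, 1 + 1e-12)
  expect_true(is.na(res$gg_epsilon[res$effect == "cfgn"]))
  expect_equal(res$df_num, c(3, 1, 3))
  expect_equal(res$df_den, c(27, 9, 27))
})

test_that("squared Pearson correlation and its p value behave canonically", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_r2(x, 2 * x + 1)$r2, 1)
  expect_equal(pearson_r2(x, c(1, 3, 2, 4))$r2, 0.64)
  # orthogonal-by-construction
  expect_equal(pearson_r2(c(-1, 0, 1, 0), c(0, 1, 0, -1))$r2, 0)
  res <- pearson_r2(x, c(1, 3, 2, 4))
  expect_equal(res$p, cor.test(x, c(1, 3, 2, 4))$p.value)
  expect_error(pearson_r2(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_r2(c(1, 2), c(1, 2)), "at least 3")
})

test_that("Weber fit recovers proportional noise and is scale-equivariant", {
  m <- c(1.2, 2.3, 4.0, 5.1)
  expect_equal(weber_fit(m, 0.08 * m)$fraction, 0.08)
  expect_equal(weber_fit(3.7 * m, 3.7 * 0.08 * m)$fraction, 0.08)
  # constant SD with varying means: slope bounded, poor proportional fit
  w <- weber_fit(m, rep(0.3, 4))
  expect_lt(w$fraction, 0.3 / min(m))
  # constant SD: proportionality explains none of the (zero) SD variation
  expect_true(is.na(w$r_squared) || w$r_squared < 0.5)
  # affine option exposes a noise floor
  wa <- weber_fit(m, 0.1 + 0.05 * m, origin = FALSE)
  expect_equal(wa$fraction, 0.05, tolerance = 1e-9)
  expect_equal(wa$intercept, 0.1, tolerance = 1e-9)
  expect_error(weber_fit(c(0, 0), c(1, 2)), "zero")
  # Monte-Carlo recovery from generator matching data is checked in
  # test-acceptance.R at the study scale
})

test_that("noncentral-t power matches power.t.test and its limits", {
  ref <- stats::power.t.test(n = 19, delta = 1.5, sd = 1.8,
                             type = "one.sample")$power
  mine <- power_one_sample_t(1.5, 1.8, 19)
  expect_equal(mine$power_two_sided, ref, tolerance = 1e-6)
  expect_gt(mine$power_one_sided, mine$power_two_sided)
  # no effect: rejection rate equals alpha
  expect_equal(power_one_sample_t(0, 1.8, 19)$power_two_sided, 0.05)
  # large n: power approaches 1
  expect_gt(power_one_sample_t(1.5, 1.8, 500)$power_two_sided, 0.9999)
  expect_error(power_one_sample_t(1, 0, 10), "positive")
})
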