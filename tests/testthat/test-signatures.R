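test_that("variance shrinkage agrees with the empirical-Bayes oracle", {
  set.seed(42)
  d0_true <- 8; s02_true <- 0.5; d <- 2
  s2 <- s02_true * d0_true / rchisq(500, d0_true) * rchisq(500, d) / d
  ours <- squeeze_variances(s2, d)
  oracle <- limma::squeezeVar(s2, df = d)
  expect_equal(ours$d0, oracle$df.prior, tolerance = 1e-6)
  expect_equal(ours$s02, oracle$var.prior, tolerance = 1e-6)
  expect_equal(ours$s2_shrunk, oracle$var.post, tolerance = 1e-6)
})

test_that("moderated one-sample test handles degenerate and limit cases", {
  set.seed(7)
  a <- array(rnorm(50 * 2 * 3, 0, 0.3), dim = c(50, 2, 3))
  a[1, 1, ] <- 0                         # all-zero fold changes
  fc <- toy_fc(a)
  res <- moderated_paired_test(fc, "F001", 1)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  # fully pooled limit: identical sample variances leave no between-feature
  # spread, so d0 = Inf and every shrunken variance equals the prior s0^2
  sq <- squeeze_variances(rep(0.25, 100), 2)
  expect_identical(sq$d0, Inf)
  expect_true(all(sq$s2_shrunk == sq$s02))
})

test_that("null fold changes give approximately uniform p-values", {
  set.seed(11)
  a <- array(rnorm(200 * 1 * 3), dim = c(200, 1, 3))
  res <- temporal_tests(toy_fc(a))
  ks <- suppressWarnings(ks.test(res$p_value, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("two-group test is antisymmetric and null on identical groups", {
  set.seed(3)
  a <- array(rnorm(20 * 2 * 3), dim = c(20, 2, 3))
  fc <- toy_fc(a)
  same <- response_tests(fc, fc)
  expect_true(all(same$statistic == 0, na.rm = TRUE))
  b <- array(rnorm(20 * 2 * 3), dim = c(20, 2, 3))
  fcb <- toy_fc(b)
  ab <- response_tests(fc, fcb)
  ba <- response_tests(fcb, fc)
  expect_equal(ab$statistic, -ba$statistic)
  expect_equal(ab$p_value, ba$p_value)
})

test_that("a planted two-unit group shift is detected with high power", {
  hits <- 0L
  for (r in 1:100) {
    set.seed(r)
    a <- array(rnorm(30 * 1 * 3, 0, 0.1), dim = c(30, 1, 3))
    b <- array(rnorm(30 * 1 * 3, 0, 0.1), dim = c(30, 1, 3))
    a[1, 1, ] <- a[1, 1, ] + 2
    res <- response_tests(toy_fc(a), toy_fc(b))
    p <- res$p_value[res$feature == "F001"]
    if (!is.na(p) && p < 0.001) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("BH q-values follow the step-up formula", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.037), 0.037)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  # NAs (untestable) are excluded from the family
  q <- bh_fdr(c(0.01, NA, 0.02))
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], p.adjust(c(0.01, 0.02), "BH"))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("temporal signature takes the union over time with directions", {
  set.seed(5)
  a <- array(rnorm(50 * 8 * 3, 0, 0.2), dim = c(50, 8, 3))
  a[1, 5, ] <- a[1, 5, ] + 5        # F001 responds only at T5, upward
  a[2, 3, ] <- a[2, 3, ] - 5        # F002 responds only at T3, downward
  res <- temporal_tests(toy_fc(a))
  sig <- temporal_signature(res, alpha = 0.01)
  expect_true(all(c("F001", "F002") %in% sig$features))
  expect_equal(sig$direction$direction[sig$direction$feature == "F001" &
                                         sig$direction$time == 5], "up")
  expect_equal(sig$direction$direction[sig$direction$feature == "F002" &
                                         sig$direction$time == 3], "down")
  expect_equal(unname(sig$first_time["F001"]), 5)
  # alpha = 0 empties the signature
  expect_length(temporal_signature(res, alpha = 0)$features, 0)
})

test_that("planted responders are recovered with controlled empirical FDR", {
  recovered <- c(); fdp <- c()
  for (r in 1:25) {
    set.seed(100 + r)
    a <- array(rnorm(300 * 4 * 3, 0, 0.2), dim = c(300, 4, 3))
    planted <- 1:30
    a[planted, 2, ] <- a[planted, 2, ] + 3
    res <- temporal_tests(toy_fc(a))
    sig <- temporal_signature(res, alpha = 0.01)
    found <- sig$features
    planted_names <- sprintf("F%03d", planted)
    recovered <- c(recovered, mean(planted_names %in% found))
    fdp <- c(fdp, if (length(found)) mean(!(found %in% planted_names)) else 0)
  }
  expect_equal(mean(recovered), 1, tolerance = 0.01)
  expect_lte(mean(fdp), 0.05)
})

test_that("proliferative signature is the exact intersection", {
  mk <- function(features) {
    structure(list(features = sort(features),
                   direction = data.frame(feature = features, time = 1,
                                          direction = "up", log2fc = 1),
                   first_time = setNames(rep(1, length(features)), features),
                   alpha = 0.01),
              class = "signature_set")
  }
  t_p <- mk(c("A", "B", "C"))
  resp <- mk(c("B", "C", "D"))
  expect_identical(proliferative_signature(t_p, resp)$features, c("B", "C"))
  expect_length(proliferative_signature(mk("A"), mk("Z"))$features, 0)
  expect_identical(proliferative_signature(t_p, mk(c("A", "B", "C")))$features,
                   t_p$features)
})

test_that("symbol matching is case-insensitive and the overlap arithmetic holds", {
  expect_identical(match_pairs(c("A", "B"), c("B", "C")), "B")
  expect_identical(match_pairs(c("EGR1", "TANK"), c("Egr1", "kmo")), "EGR1")
  expect_identical(match_pairs(c("A", "B"), c("a", "b")), c("A", "B"))
  # worked overlap example: 430 genes, 374 proteins, 779 unique symbols
  genes <- sprintf("G%04d", 1:430)
  prots <- c(sprintf("G%04d", 1:25), sprintf("P%04d", 1:349))
  s <- signature_summary(genes, prots)
  expect_equal(s$n_gene, 430)
  expect_equal(s$n_protein, 374)
  expect_equal(s$n_unique_symbols, 779)
  expect_equal(s$n_shared, 25)
  expect_equal(s$n_shared, s$n_gene + s$n_protein - s$n_unique_symbols)
})
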