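test_that("confusion counts partition actives and decoys by hit status", {
  act <- sprintf("a%d", 1:10); dec <- sprintf("d%d", 1:5)
  c1 <- confusion(act, act, dec)
  expect_equal(c1[c("TP", "FP", "TN", "FN")], list(TP = 10L, FP = 0L,
                                                   TN = 5L, FN = 0L))
  c0 <- confusion(character(0), act, dec)
  expect_equal(c0$TP, 0L); expect_equal(c0$FP, 0L)
  c2 <- confusion(act[1:7], act, dec)
  expect_equal(c2[c("TP", "FP", "TN", "FN")], list(TP = 7L, FP = 0L,
                                                   TN = 5L, FN = 3L))
  expect_error(confusion("a1", c("a1", "x"), c("x", "d1")), "overlap")
  expect_error(confusion("zz", act, dec), "outside")
})

test_that("metric formulas match their printed definitions", {
  perfect <- compute_metrics(list(TP = 5L, FN = 0L, TN = 10L, FP = 0L))
  expect_equal(perfect, list(recall = 1, specificity = 1, mcc = 1))
  nd <- compute_metrics(list(TP = 0L, FN = 5L, TN = 10L, FP = 0L))
  expect_equal(nd$recall, 0)
  expect_equal(nd$specificity, 1)
  expect_identical(nd$mcc, "ND")
  m <- compute_metrics(list(TP = 3L, FN = 2L, TN = 8L, FP = 2L))
  expect_equal(m$mcc, (3 * 8 - 2 * 2) / sqrt(5 * 10 * 5 * 10))
  expect_equal(m$mcc, 0.4)
})

test_that("specificity is 1 whenever no decoy is retrieved", {
  set.seed(99)
  for (k in 1:50) {
    c4 <- list(TP = sample(0:20, 1L), FN = sample(0:20, 1L),
               TN = sample(1:20, 1L), FP = 0L)
    expect_equal(compute_metrics(c4)$specificity, 1)
  }
})

test_that("composition statistics count enabled features and never exclusion spheres", {
  f <- feature_points(c("AR", "AR", "H", "H", "H"),
                      matrix(runif(15, 0, 10), 5L))
  p <- pharmacophore("comp", "LB", "r", "agonist", f,
                     exclusion_spheres(matrix(runif(30, 0, 10), 10L)))
  st <- composition_stats(list(p))
  expect_equal(unname(st$type_fractions["AR"]), 0.4)
  expect_equal(unname(st$type_fractions["H"]), 0.6)
  expect_equal(sum(st$type_fractions), 1)
  expect_equal(st$median_features, 5)
  empty <- composition_stats(list())
  expect_length(empty$type_fractions, 0L)
})

test_that("composition comparison flags planted differences and skips degenerate input", {
  set.seed(5)
  mk <- function(n_hba, id) {
    types <- c(rep("HBA", n_hba), "H", "AR")
    pharmacophore(id, "LB", "r", "agonist",
                  feature_points(types, matrix(runif(3 * length(types), 0, 20),
                                               length(types)) +
                                   seq_along(types) * 3))
  }
  ens_a <- lapply(1:20, function(i) mk(2L, sprintf("a%d", i)))
  ens_b <- lapply(1:20, function(i) mk(5L, sprintf("b%d", i)))
  cmp <- compare_composition(ens_a, ens_b)
  expect_lt(cmp$p_value[cmp$type == "HBA"], 0.05)
  same <- compare_composition(ens_a, ens_a)
  expect_true(all(same$p_value > 0.9))
  expect_warning(res <- compare_composition(ens_a[1], ens_b[1]), "skipped")
  expect_null(res)
})

test_that("Kendall tau matches a brute-force pair count (tau-b, tie-corrected)", {
  brute_tau_b <- function(x, y) {
    n <- length(x); conc <- disc <- tx <- ty <- 0
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      sx <- sign(x[j] - x[i]); sy <- sign(y[j] - y[i])
      if (sx == 0 && sy == 0) next
      else if (sx == 0) tx <- tx + 1
      else if (sy == 0) ty <- ty + 1
      else if (sx == sy) conc <- conc + 1
      else disc <- disc + 1
    }
    (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
  }
  expect_equal(kendall_tau(1:3, c(10, 20, 30))$tau, 1)
  expect_equal(kendall_tau(1:3, c(3, 2, 1))$tau, -1)
  expect_equal(kendall_tau(1:4, c(1, 3, 2, 4))$tau, 2 / 3)
  expect_equal(brute_tau_b(1:4, c(1, 3, 2, 4)), 2 / 3)
  set.seed(11)
  for (k in 1:20) {
    x <- sample(1:6, 8L, replace = TRUE)
    y <- sample(1:6, 8L, replace = TRUE)
    if (length(unique(x)) < 2L || length(unique(y)) < 2L) next
    expect_equal(kendall_tau(x, y)$tau, brute_tau_b(x, y), tolerance = 1e-9)
  }
  expect_identical(kendall_tau(rep(1, 4), 1:4)$tau, "ND")
})

test_that("report rows serialize ND as a literal string", {
  row <- metrics_report_row("dsX", "SB",
                            compute_metrics(list(TP = 0L, FN = 3L, TN = 4L,
                                                 FP = 0L)))
  expect_identical(row$MCC, "ND")
  expect_equal(row$Sp, 1)
})
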