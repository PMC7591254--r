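test_that("cell tabulation is exact and order-invariant", {
  meta <- data.frame(
    sample_id = c("s1", "s1", "s1", "s2", "s2"),
    condition = c("Ctrl", "Ctrl", "Ctrl", "D0", "D0"),
    cluster = c("k1", "k1", "k2", "k1", "k2"))
  cc <- tabulate_counts(meta)
  expect_equal(cc$counts["s1", "k1"], 2)
  expect_equal(cc$counts["s1", "k2"], 1)
  expect_equal(cc$counts["s2", "k1"], 1)
  expect_equal(unname(cc$total_cells), c(3, 2))
  expect_equal(as.character(cc$condition), c("Ctrl", "D0"))

  perm <- meta[sample(nrow(meta)), ]
  expect_identical(tabulate_counts(perm)$counts, cc$counts)

  single <- meta; single$cluster <- "k1"
  cs <- tabulate_counts(single)
  expect_equal(unname(cs$counts[, "k1"]), unname(cs$total_cells))
})

test_that("the NB fit reduces to Poisson and respects its offset", {
  set.seed(50)
  tot <- rep(5000, 9)
  cond <- factor(rep(c("Ctrl", "D0", "D2"), each = 3))
  y <- rpois(9, 250)
  f <- fit_nb_glm(y, cond, log(tot))
  g <- glm(y ~ cond + offset(log(tot)), family = poisson)
  expect_lt(f$dispersion, 1e-4)
  expect_lt(max(abs(f$coefficients - coef(g))), 1e-4)

  # doubling offsets shifts the intercept by -ln 2 only
  f2 <- fit_nb_glm(y, cond, log(tot * 2))
  expect_equal(unname(f2$coefficients[1] - f$coefficients[1]), -log(2),
               tolerance = 1e-6)
  expect_lt(max(abs(f2$coefficients[-1] - f$coefficients[-1])), 1e-8)

  # counts exactly proportional to offsets: condition effects vanish
  y3 <- c(50, 100, 200, 50, 100, 200, 50, 100, 200)
  t3 <- y3 * 20
  f3 <- fit_nb_glm(y3, cond, log(t3))
  expect_lt(max(abs(f3$coefficients[-1])), 1e-6)

  expect_warning(z <- fit_nb_glm(rep(0, 9), cond, log(tot)), "zero")
  expect_true(z$flagged)
  expect_warning(fit_nb_glm(c(0, 0, 0, 5, 8, 6, 7, 9, 4), cond, log(tot)),
                 "continuity")
})

test_that("identical composition across conditions is not called", {
  counts <- matrix(rep(c(100, 400, 50), each = 6), 6, 3)
  cc <- structure(list(counts = counts, total_cells = rowSums(counts),
                       condition = factor(rep(c("Ctrl", "D0"), each = 3))),
                  class = "cluster_counts")
  # identical counts leave no residual variance; edgeR warns while
  # degenerating gracefully
  res <- suppressWarnings(test_abundance(cc,
                                         contrasts = list(c("D0", "Ctrl"))))
  expect_true(all(res$p_value > 0.99))
  expect_true(all(abs(res$log_fold_change) < 1e-8))
  expect_error(test_abundance(cc, contrasts = list(c("D9", "Ctrl"))),
               "absent")
})

test_that("an 80-fold planted frequency shift is detected decisively", {
  set.seed(51)
  meta <- NULL
  props <- list(Ctrl = c(homeo = 0.8488, chem = 0.05, ribo = 0.05,
                         mhc = 0.05, prolif = 0.0012),
                D0 = c(0.60, 0.10, 0.10, 0.10, 0.10),
                D2 = c(0.60, 0.10, 0.10, 0.10, 0.10))
  for (cd in names(props)) for (s in 1:3) {
    pop <- sample(names(props$Ctrl), 5000, TRUE, props[[cd]])
    meta <- rbind(meta, data.frame(sample_id = paste0(cd, s),
                                   condition = cd, cluster = pop))
  }
  res <- test_abundance(tabulate_counts(meta))
  hit <- res[res$cluster == "prolif" & res$contrast == "D0 vs Ctrl", ]
  expect_lte(hit$p_value, 0.001)
  expect_gt(hit$log_fold_change, log(20))
})

test_that("scaling counts and totals together is inert where it can be", {
  set.seed(52)
  counts <- matrix(rnbinom(9 * 5, mu = rep(c(300, 1500, 400, 250, 150),
                                           each = 9), size = 40), 9, 5)
  mk <- function(k) structure(list(counts = counts * k,
                                   total_cells = (rowSums(counts) + 2000) * k,
                                   condition = factor(rep(c("Ctrl", "D0",
                                                            "D2"), each = 3))),
                              class = "cluster_counts")
  r1 <- test_abundance(mk(1), contrasts = list(c("D0", "Ctrl")))
  r3 <- test_abundance(mk(3), contrasts = list(c("D0", "Ctrl")))
  # the NB variance function (and the fold-change shrinkage prior) is not
  # scale-free, so agreement is approximate, not exact
  expect_equal(r1$log_fold_change, r3$log_fold_change, tolerance = 1e-2)
  expect_equal(r1$p_value, r3$p_value, tolerance = 1e-2)
})

test_that("one sample per level falls back to a chi-square test", {
  counts <- matrix(c(10, 80, 30, 60, 55, 20), 3, 2)
  cc <- structure(list(counts = counts, total_cells = rowSums(counts) + 500,
                       condition = factor(c("Ctrl", "D0", "D2"))),
                  class = "cluster_counts")
  expect_warning(res <- test_abundance(cc,
                                       contrasts = list(c("D0", "Ctrl"))),
                 "likelihood-ratio")
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
})

test_that("detection power rises with fold change and sample size", {
  set.seed(53)
  p_at <- function(fold, n_per) {
    meta <- NULL
    for (cd in c("Ctrl", "D0", "D2")) for (s in seq_len(n_per)) {
      pr <- if (cd == "Ctrl") c(a = 0.97, b = 0.03) else {
        c(a = 1 - 0.03 * fold, b = 0.03 * fold)
      }
      pop <- sample(names(pr), 3000, TRUE, pr)
      meta <- rbind(meta, data.frame(sample_id = paste0(cd, s),
                                     condition = cd, cluster = pop))
    }
    res <- suppressWarnings(test_abundance(tabulate_counts(meta),
                                           contrasts = list(c("D0", "Ctrl"))))
    res$p_value[res$cluster == "b"]
  }
  p_fold <- vapply(c(1.5, 3, 6), p_at, numeric(1), n_per = 3)
  expect_true(all(diff(log(p_fold)) < 0))
})
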