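test_that("genotype summaries compute means, standard errors and exclusions", {
  d <- tibble::tibble(
    genotype = c("g1", "g2", "g2"), collection = "c", season = "2022",
    ws_index = c(2, 1, 3), permeance_m_s = c(2e-6, 1e-6, -5e-7)
  )
  s <- suppressMessages(summarize_genotypes(d))
  one <- s[s$genotype == "g1" & s$trait == "ws_index", ]
  expect_equal(one$mean, 2)
  expect_true(is.na(one$se))
  two <- s[s$genotype == "g2" & s$trait == "ws_index", ]
  expect_equal(two$mean, 2)
  expect_equal(two$se, 1)

  # negative-permeance fruit excluded from the log trait with a count
  logp <- s[s$genotype == "g2" & s$trait == "log10_permeance", ]
  expect_equal(logp$mean, log10(1e-6))
  expect_equal(logp$n, 1L)
  expect_equal(attr(s, "n_excluded_log"), 1L)

  expect_error(summarize_genotypes(d[0, ]), "empty")
})

test_that("coefficient of variation matches hand arithmetic and is scale-invariant", {
  expect_equal(cv_percent(c(5, 5, 5)), 0)
  expect_equal(cv_percent(c(8, 12)), 100 * sqrt(8) / 10)
  x <- c(3, 9, 4, 8)
  expect_equal(cv_percent(10 * x), cv_percent(x))
  expect_error(cv_percent(c(-1, 1)), "zero mean")
})

test_that("correlation tables are symmetric with unit diagonal and correct stars", {
  set.seed(12)
  d <- tibble::tibble(genotype = paste0("g", 1:30),
                      a = rnorm(30), c_flat = 1)
  d$b <- 2 * d$a + 1 # exactly linear
  d$noise <- rnorm(30)
  cm <- correlation_matrix(d, c("a", "b", "noise", "c_flat"))
  expect_equal(cm$r[cm$trait_x == "a" & cm$trait_y == "a"], 1)
  expect_equal(cm$r[cm$trait_x == "a" & cm$trait_y == "b"], 1, tolerance = 1e-12)
  expect_lt(cm$p[cm$trait_x == "a" & cm$trait_y == "b"], 1e-12)
  # symmetry
  expect_equal(cm$r[cm$trait_x == "a" & cm$trait_y == "noise"],
               cm$r[cm$trait_x == "noise" & cm$trait_y == "a"])
  # constant trait is undefined, not an error
  expect_true(is.na(cm$r[cm$trait_x == "a" & cm$trait_y == "c_flat"]))
  # stars consistent with p for every emitted cell
  ok <- is.na(cm$p) | cm$stars == star_code(cm$p)
  expect_true(all(ok))

  expect_error(correlation_matrix(d[1:2, ], c("a", "b")), "fewer than 3")
})

test_that("the water-soaking regression recovers exact and null relationships", {
  d <- tibble::tibble(log10_permeance = seq(-6.4, -5.2, length.out = 10))
  d$ws_index <- 2 + 1.5 * (d$log10_permeance + 5.8)
  f <- regress_ws_on_log_permeance(d)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  expect_equal(f$slope, 1.5, tolerance = 1e-10)
  expect_equal(glance(f)$r_squared_pct, 100, tolerance = 1e-9)
  expect_identical(tidy(f)$term[2], "log10_permeance")
  expect_s3_class(autoplot(f), "ggplot")

  expect_error(regress_ws_on_log_permeance(d[1:2, ]), "at least 3")
})

test_that("letter displays separate and join groups per their own p-values", {
  set.seed(21)
  d <- tibble::tibble(
    group = rep(c("a1", "a2"), each = 10),
    value = rnorm(20, 5, 1)
  )
  for (m in c("tukey", "mann_whitney")) {
    tb <- compare_groups(d, "value", "group", method = m)
    expect_identical(tb$letters[1], tb$letters[2]) # same population: share a letter
    expect_true(letters_consistent(tb))
  }

  # widely separated groups get distinct letters under both conventions
  d2 <- tibble::tibble(group = rep(c("lo", "hi"), each = 10),
                       value = c(rnorm(10, 0, 1), rnorm(10, 10, 1)))
  for (m in c("tukey", "mann_whitney")) {
    tb <- compare_groups(d2, "value", "group", method = m)
    expect_false(tb$letters[1] == tb$letters[2])
    expect_true(letters_consistent(tb))
  }
})

test_that("three-group letter displays are monotone at large effect sizes", {
  hits <- vapply(1:20, function(s) {
    set.seed(700 + s)
    d <- tibble::tibble(group = rep(c("g1", "g2", "g3"), each = 10),
                        value = rnorm(30, rep(c(0, 2.5, 5), each = 10), 1))
    tb <- compare_groups(d, "value", "group", method = "tukey")
    stopifnot(letters_consistent(tb))
    identical(tb$letters, c("a", "b", "c"))
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("Dunnett comparisons star lines against the named control", {
  set.seed(33)
  d <- tibble::tibble(
    group = rep(c("control", "lineA", "lineB"), each = 8),
    value = rnorm(24, rep(c(0, 0, 4), each = 8), 1)
  )
  tb <- compare_groups(d, "value", "group", method = "dunnett",
                       control = "control")
  expect_identical(tb$stars[tb$group == "control"], "control")
  expect_identical(tb$stars[tb$group == "lineB"], "***")
  expect_identical(tb$stars[tb$group == "lineA"], "ns")
  expect_error(compare_groups(d, "value", "group", method = "dunnett"),
               "control")
  expect_error(compare_groups(d, "value", "group", method = "dunnett",
                              control = "nope"), "not found")
})

test_that("the insert-absorb letters agree with a crafted p-value matrix", {
  groups <- c("hi", "mid", "lo")
  p <- matrix(1, 3, 3, dimnames = list(groups, groups))
  p["hi", "lo"] <- p["lo", "hi"] <- 0.001 # only the extremes differ
  lt <- cld_insert_absorb(p, groups)
  expect_identical(unname(lt), c("a", "ab", "b"))

  p2 <- matrix(0.001, 3, 3, dimnames = list(groups, groups))
  diag(p2) <- 1
  expect_identical(unname(cld_insert_absorb(p2, groups)), c("a", "b", "c"))
})

test_that("distribution reports conserve counts and give sane normal-probability pairs", {
  x <- c(2, 2, 2, 2, 2)
  r <- distribution_report(x)
  expect_equal(sum(r$histogram$count), 5)
  expect_equal(nrow(r$histogram[r$histogram$count > 0, ]), 1L)

  set.seed(8)
  z <- rnorm(1000)
  rz <- distribution_report(z, bins = 20)
  expect_equal(sum(rz$histogram$count), 1000)
  # Kolmogorov-Smirnov bound at alpha = 0.01 from the QQ pairs
  d_stat <- max(abs(pnorm(rz$qq$sample) - (seq_len(1000) - 0.5) / 1000)) + 0.5 / 1000
  expect_lt(d_stat, 1.628 / sqrt(1000))
  expect_s3_class(autoplot(rz), "ggplot")

  expect_error(distribution_report(1:3), "at least 5")
})
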