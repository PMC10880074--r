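test_that("the Pareto front keeps exactly the non-dominated hits", {
  h <- hits_frame(s35 = c(-5, -4, -3, -6), s10 = c(-3, -6, -4, -2))
  fr <- pareto_front(h)
  expect_equal(fr[c("s35", "s10")],
               data.frame(s35 = c(-3, -5, -6), s10 = c(-4, -3, -2)))

  single <- hits_frame(-2, -7)
  expect_equal(pareto_front(single)[c("s35", "s10")],
               single[c("s35", "s10")])

  # exact duplicates of a front point are all retained
  dup <- hits_frame(s35 = c(-3, -3, -4), s10 = c(-4, -4, -4))
  expect_equal(nrow(pareto_front(dup)), 2L)
  expect_equal(nrow(pareto_front(h[0, ])), 0L)
})

test_that("sort-and-sweep equals the dominance oracle and is idempotent", {
  withr::local_seed(414)
  for (i in 1:50) {
    n <- sample(1:60, 1)
    h <- hits_frame(s35 = round(-runif(n, 0, 10), 2),
                    s10 = round(-runif(n, 0, 10), 2))
    fr <- pareto_front(h)
    or <- oracle_pareto(h)
    expect_setequal(paste(fr$s35, fr$s10), paste(or$s35, or$s10))
    expect_equal(nrow(fr), nrow(or))
    expect_equal(pareto_front(fr)[c("s35", "s10")], fr[c("s35", "s10")])
  }
})

test_that("worst-value cutoffs relax by the uncertainty factor", {
  # front {(-3,-4),(-5,-3),(-6,-2)}: totals {-7,-8,-8}, minima (-6,-4)
  h <- hits_frame(s35 = c(-3, -5, -6), s10 = c(-4, -3, -2))
  units <- data.frame(unit_id = "u1", log2fc = 4, padj = 1e-4)
  cs <- calibrate_cutoffs(units, list(u1 = h), relax = 0.05)
  expect_equal(cs$min_s35, -6.3)
  expect_equal(cs$min_s10, -4.2)
  expect_equal(cs$min_total, -8.4)
  expect_equal(cs$max_evalue, 0.02 * 1.05)
  expect_equal(cs$provenance$units_used, "u1")

  # relax = 0 on a single hit reproduces the hit's own values
  one <- hits_frame(-2, -3, evalue = 0.02)
  cs0 <- calibrate_cutoffs(units, list(u1 = one), relax = 0)
  expect_equal(c(cs0$min_s35, cs0$min_s10, cs0$min_total, cs0$max_evalue),
               c(-2, -3, -5, 0.02))
})

test_that("DE filtering is strict and hitless units are excluded", {
  de <- data.frame(unit_id = c("a", "b", "c", "d"),
                   log2fc = c(4, 2, 3, 5),
                   padj = c(1e-4, 1e-4, 0.05, 1e-3))
  reg <- regulated_units(de)
  expect_equal(reg$unit_id, c("a", "d"))  # log2fc > 2 and padj < 0.05 strict

  h <- hits_frame(-2, -3)
  expect_warning(
    cs <- calibrate_cutoffs(de, list(a = h, d = h[0, ])),
    "no promoter hits")
  expect_equal(cs$provenance$units_excluded, "d")
  expect_error(calibrate_cutoffs(de[2, ], list()), "no regulated units")
  expect_error(
    suppressWarnings(calibrate_cutoffs(de, list(a = h[0, ], d = h[0, ]))),
    "contributed")
  noev <- h; noev$evalue <- NA_real_
  expect_error(calibrate_cutoffs(de, list(a = noev, d = h)), "E-value")
  cs2 <- calibrate_cutoffs(de, list(a = noev, d = h),
                           fixed_max_evalue = 0.05)
  expect_equal(cs2$max_evalue, 0.05 * 1.05)
})

test_that("cutoff filtering is conjunctive with inclusive boundaries", {
  cs <- cutoff_set(-6.3, -4.2, -8.4, 0.05)
  exact <- hits_frame(-6.3, -2.1, evalue = 0.05)  # total exactly -8.4
  expect_equal(nrow(apply_cutoffs(exact, cs)), 1L)

  fail10 <- hits_frame(-1, -4.3, evalue = 0.01)
  expect_equal(nrow(apply_cutoffs(fail10, cs)), 0L)
  faile <- hits_frame(-1, -1, evalue = 0.051)
  expect_equal(nrow(apply_cutoffs(faile, cs)), 0L)

  noev <- hits_frame(-1, -1); noev$evalue <- NA_real_
  expect_error(apply_cutoffs(noev, cs), "E-value")
  expect_equal(nrow(apply_cutoffs(exact[0, ], cs)), 0L)
})

test_that("every calibration hit passes the relaxed cutoffs", {
  withr::local_seed(415)
  units <- data.frame(unit_id = c("u1", "u2", "u3"),
                      log2fc = c(3, 4, 5), padj = rep(1e-4, 3))
  for (i in 1:20) {
    hbu <- lapply(stats::setNames(units$unit_id, units$unit_id), function(u) {
      n <- sample(1:30, 1)
      hits_frame(s35 = -runif(n, 0, 8), s10 = -runif(n, 0, 8),
                 evalue = runif(n, 0, 0.2))
    })
    cs <- calibrate_cutoffs(units, hbu, relax = 0.05)
    fronts <- do.call(rbind, lapply(hbu, pareto_front))
    expect_equal(nrow(apply_cutoffs(fronts, cs)), nrow(fronts))
  }
})

test_that("dominated hits never influence the calibrated cutoffs", {
  # the cutoffs are worst values over the Pareto front, so any hit that is
  # dominated by an existing front member must leave them unchanged
  withr::local_seed(416)
  units <- data.frame(unit_id = "u1", log2fc = 4, padj = 1e-4)
  for (i in 1:20) {
    h1 <- hits_frame(s35 = -runif(10, 0, 8), s10 = -runif(10, 0, 8),
                     evalue = runif(10, 0, 0.1))
    fr <- pareto_front(h1)
    j <- sample(nrow(fr), 3, replace = TRUE)
    dominated <- hits_frame(s35 = fr$s35[j] - runif(3, 0.1, 2),
                            s10 = fr$s10[j] - runif(3, 0.1, 2),
                            evalue = runif(3, 0, 1))
    c1 <- calibrate_cutoffs(units, list(u1 = h1))
    c2 <- calibrate_cutoffs(units, list(u1 = rbind(h1, dominated)))
    expect_equal(c2[c("min_s35", "min_s10", "min_total", "max_evalue")],
                 c1[c("min_s35", "min_s10", "min_total", "max_evalue")])
  }
})

test_that("cutoff sets and DE tables serialize to disk and back", {
  dir <- withr::local_tempdir()
  cs <- cutoff_set(-6.3, -4.2, -8.4, 0.021, provenance = list(
    units_used = "u1", units_excluded = character(0)))
  write_cutoffs(cs, file.path(dir, "cutoffs.json"))
  js <- jsonlite::read_json(file.path(dir, "cutoffs.json"))
  expect_equal(js$min_total, -8.4)

  de <- data.frame(unit_id = "op1", members = "g1,g2,g3",
                   log2fc = 3.2, padj = 1e-5)
  fp <- file.path(dir, "de.tsv")
  write.table(de, fp, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_de_table(fp)
  expect_equal(back$members[[1]], c("g1", "g2", "g3"))
})
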