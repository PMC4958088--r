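test_that("allele frequency spectra count every allele copy", {
  gt <- toy_table(list(M1 = c("100/100", "100/104", "104/104")))
  sp <- allele_freqs(gt, "M1")
  expect_equal(sp$freqs, c(`100` = 0.5, `104` = 0.5))
  expect_equal(sp$n, 6)

  tri <- toy_table(list(M1 = "100/100/104"))
  sp3 <- allele_freqs(tri, "M1")
  expect_equal(sp3$freqs, c(`100` = 2 / 3, `104` = 1 / 3))
  expect_equal(sp3$n, 3)

  expect_error(allele_freqs(gt, "nope"), "unknown marker")
})

test_that("TM442 spectrum spans four alleles over 132 observations", {
  sp <- allele_freqs(tea_genotypes(), "TM442")
  expect_identical(names(sp$freqs), c("268", "280", "286", "292"))
  expect_equal(sp$n, 132)
  expect_equal(sum(sp$freqs), 1, tolerance = 1e-12)
})

test_that("pid and pic match closed-form values", {
  expect_equal(pid(1), 1)
  expect_equal(pid(c(0.5, 0.5)), 0.375)
  expect_equal(pid(rep(0.25, 4)), 0.109375)
  expect_equal(pic(1), 0)
  expect_equal(pic(c(0.5, 0.5)), 0.375)
  expect_equal(pic(rep(0.25, 4)), 0.703125)
  expect_error(pid(c(0.5, 0.4)), "sum to 1")
  expect_error(pic(c(0.6, 0.4, 0)), "positive")
})

test_that("pid equals the brute-force Hardy-Weinberg pair enumeration", {
  set.seed(42)
  for (k in 2:6) {
    for (rep in 1:5) {
      p <- random_freqs(k)
      expect_equal(pid(p), hw_match_oracle(p), tolerance = 1e-12)
    }
  }
})

test_that("pid bounds hold for arbitrary spectra", {
  set.seed(7)
  for (rep in 1:40) {
    p <- random_freqs(sample(2:8, 1))
    v <- pid(p)
    expect_gt(v, 0)
    expect_lte(v, 1)
    expect_gte(v, sum(p^2)^2)         # two-homozygote match bound
    expect_lt(v, 1)                   # polymorphic => < 1
    expect_lt(pic(p), 1 - sum(p^2))   # PIC below expected heterozygosity
  }
})

test_that("observed heterozygosity counts calls with >= 2 distinct alleles", {
  gt <- toy_table(list(M1 = c("100/100", "100/104", "104/104")))
  expect_equal(observed_heterozygosity(gt, "M1"), 1 / 3)
  expect_equal(observed_heterozygosity(
    toy_table(list(M1 = "100/104/108")), "M1"), 1)
  expect_equal(observed_heterozygosity(
    toy_table(list(M1 = c("100/100", "104/104"))), "M1"), 0)
})

test_that("genotype classes partition the cultivars", {
  cls <- genotype_classes(tea_genotypes(), "TM442")
  expect_length(cls, 9)
  expect_identical(cls[["292/292"]], 15L)
  expect_identical(cls[["268/292"]], 1L)
  expect_setequal(unlist(cls), 1:66)

  distinct <- toy_table(list(M1 = c("100/104", "100/108", "104/108")))
  expect_length(genotype_classes(distinct, "M1"), 3)
})

test_that("summarize_markers agrees with by-hand statistics on a toy table", {
  gt <- toy_table(list(M1 = c("100/100", "100/104", "104/104")))
  st <- summarize_markers(gt)
  expect_equal(st$maf, 0.5)
  expect_equal(st$na, 2)
  expect_equal(st$ng, 3)
  expect_equal(st$ho, 1 / 3)
  expect_equal(st$pic, 0.375)
  expect_equal(st$pid, 0.375)

  single <- toy_table(list(M1 = "100/104"))
  st1 <- summarize_markers(single)
  expect_equal(st1$ng, 1)
  expect_equal(st1$ho, 1)
})

test_that("recomputed structural counts for TM442 match the published table", {
  st <- summarize_markers(tea_genotypes())
  row <- st[st$marker == "TM442", ]
  expect_equal(row$na, 4)
  expect_equal(row$ng, 9)
})

test_that("combined_pid multiplies and validates", {
  expect_equal(combined_pid(0.3), 0.3)
  expect_equal(combined_pid(c(0.3, 1)), 0.3)
  expect_equal(combined_pid(c(0.2, 0.4)), 0.08)
  expect_error(combined_pid(numeric(0)), "at least one")
  expect_error(combined_pid(c(0.2, 0)), "\\(0, 1\\]")
  expect_error(combined_pid(1.2), "\\(0, 1\\]")
})

test_that("combined PID never increases when a locus is appended", {
  set.seed(3)
  pids <- runif(20, min = 1e-6, max = 1)
  for (k in 1:19)
    expect_lte(combined_pid(pids[1:(k + 1)]), combined_pid(pids[1:k]))
})

test_that("diagnostic comparison surfaces the published-table discrepancies", {
  cmp <- compare_marker_stats(summarize_markers(tea_genotypes()),
                              tea_marker_stats())
  tm442 <- cmp[cmp$marker == "TM442", ]
  # structural counts agree ...
  expect_equal(tm442$difference[tm442$statistic %in% c("na", "ng")], c(0, 0))
  # ... while the published Ho (0.485) differs from the direct count (0.500)
  expect_equal(tm442$computed[tm442$statistic == "ho"], 0.5)
  expect_equal(tm442$reference[tm442$statistic == "ho"], 0.485)
})

test_that("marker statistics CSV export appends a mean row", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_marker_stats(tea_marker_stats(), f)
  out <- read.csv(f)
  expect_equal(nrow(out), 34)
  expect_equal(out$marker[34], "Mean")
  expect_equal(out$na[34], mean(tea_marker_stats()$na))
})
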