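core_order <- c("TM442", "TM324", "TM351", "TM569", "TM581", "TM461")
fit66 <- cid(tea_genotypes(), markers = core_order)

test_that("the tea diagram splits the root into nine genotype groups", {
  expect_length(fit66$root$branches, 9)
  expect_identical(fit66$markers, core_order)
  # the default marker order (published PID, descending) is the same
  expect_identical(cid(tea_genotypes(), stats = tea_marker_stats())$markers,
                   core_order)
})

test_that("singleton genotypes resolve at depth one", {
  b <- fit66$root$branches
  expect_identical(b[["292/292"]]$cultivars, 15L)   # Bai Ji Guan
  expect_identical(b[["268/292"]]$cultivars, 1L)    # Tie Guan Yin
  node <- b[["268/286"]]
  expect_identical(node$marker, "TM324")
  expect_identical(node$branches[["171/171"]]$cultivars, 56L)  # Yin Shuang
  expect_identical(node$branches[["171/183"]]$cultivars, 65L)  # Feng Huang Dan Cong
})

test_that("all 66 cultivars end in resolved singleton leaves", {
  s <- summary(fit66)
  expect_true(all(s$paths$resolved))
  expect_length(s$unresolved, 0)
  expect_equal(nrow(s$paths), 66)
  expect_equal(s$paths$depth[s$paths$code %in% c(1, 15)], c(1, 1))
  expect_equal(s$paths$depth[s$paths$code %in% c(56, 65)], c(2, 2))
  expect_equal(s$paths$markers[s$paths$code == 56], "TM442,TM324")
})

test_that("every cultivar is identified by its own genotypes", {
  gt <- tea_genotypes()
  for (code in 1:66) {
    sample <- setNames(gt$calls[as.character(code), ], core_order)
    res <- predict(fit66, sample)
    expect_identical(res$outcome, "unique")
    expect_identical(res$cultivar, code)
    expect_gte(nrow(res$path), 1)
  }
})

test_that("lazy traversal needs only the markers on the path", {
  res <- predict(fit66, c(TM442 = "268/286", TM324 = "171/171"))
  expect_identical(res$outcome, "unique")
  expect_identical(res$cultivar, 56L)
  expect_equal(nrow(res$path), 2)
  # depth-1 cultivars need a single genotype
  res15 <- predict(fit66, c(TM442 = "292/292"))
  expect_identical(res15$cultivar, 15L)
})

test_that("unknown genotypes give no_match; missing path markers error", {
  res <- predict(fit66, c(TM442 = "999/999"))
  expect_identical(res$outcome, "no_match")
  expect_identical(res$path,
                   data.frame(marker = "TM442", genotype = "999/999"))
  expect_error(predict(fit66, c(TM442 = "268/286")), "TM324")
  # order-insensitive genotype input
  expect_identical(predict(fit66, c(TM442 = "286/268", TM324 = "171/171"))$cultivar,
                   56L)
})

test_that("path depth equals the first marker index with a unique prefix", {
  gt <- tea_genotypes()
  s <- summary(fit66)
  for (code in 1:66) {
    prefixes <- vapply(seq_along(core_order), function(k)
      paste(gt$calls[as.character(code), core_order[1:k]], collapse = "|"),
      character(1))
    all_prefixes <- lapply(seq_along(core_order), function(k)
      apply(gt$calls[, core_order[1:k], drop = FALSE], 1, paste,
            collapse = "|"))
    first_unique <- which(vapply(seq_along(core_order), function(k)
      sum(all_prefixes[[k]] == prefixes[k]) == 1L, logical(1)))[1]
    expect_equal(s$paths$depth[s$paths$code == code], first_unique)
  }
})

test_that("adding a cultivar with a new root genotype only adds a branch", {
  g <- c(TM442 = "300/300", TM324 = "171/171", TM351 = "244/244",
         TM569 = "265/269", TM581 = "228/228", TM461 = "192/192")
  ext <- add_cultivar(fit66, 67, g, name = "new release")
  expect_length(ext$root$branches, 10)
  expect_identical(ext$root$branches[["300/300"]]$cultivars, 67L)
  # the untouched subtrees are unchanged
  expect_identical(ext$root$branches[["268/286"]],
                   fit66$root$branches[["268/286"]])
  expect_identical(predict(ext, g)$cultivar, 67L)
})

test_that("a full six-locus duplicate becomes a flagged unresolved group", {
  gt <- tea_genotypes()
  dup <- setNames(gt$calls["15", ], core_order)
  ext <- add_cultivar(fit66, 99, dup)
  s <- summary(ext)
  expect_length(s$unresolved, 1)
  expect_setequal(s$unresolved[[1]], c(15, 99))
  res <- predict(ext, dup)
  expect_identical(res$outcome, "ambiguous")
  expect_setequal(res$candidates, c(15, 99))
  expect_error(add_cultivar(fit66, 15, dup), "already present")
})

test_that("incremental insertion equals refitting on the extended table", {
  set.seed(23)
  for (rep in 1:20) {
    loci <- random_loci(3, max_alleles = 3)
    base <- simulate_genotypes(10, loci, triploid_fraction = 0.05)
    fit <- cid(base, markers = names(loci))
    newcomer <- simulate_genotypes(1, loci, triploid_fraction = 0.05)
    g <- setNames(newcomer$calls[1, ], names(loci))
    incremental <- add_cultivar(fit, 11, g, name = "sim11")
    extended <- genotype_table(
      rbind(base$calls, g[names(loci)]),
      data.frame(code = 1:11, name = c(base$cultivars$name, "sim11")))
    refit <- cid(extended, markers = names(loci))
    expect_identical(incremental$root, refit$root)
    expect_identical(incremental$calls, refit$calls)
  }
})

test_that("leaf sets partition the cultivars at every node, on random tables", {
  set.seed(5)
  for (rep in 1:100) {
    loci <- random_loci(sample(2:3, 1), max_alleles = 3)
    gt <- simulate_genotypes(sample(4:12, 1), loci,
                             triploid_fraction = 0.05)
    fit <- cid(gt, markers = names(loci))
    codes <- as.integer(rownames(gt$calls))
    expect_cid_partition(fit$root, codes)
    # self-identification: unique, or ambiguous containing the cultivar
    for (code in codes) {
      res <- predict(fit, setNames(gt$calls[as.character(code), ],
                                   names(loci)))
      expect_true(code %in% res$candidates)
      if (res$outcome == "unique") expect_identical(res$cultivar, code)
    }
  }
})

test_that("JSON serialization round-trips the fitted diagram", {
  txt <- cid_to_json(fit66)
  back <- cid_from_json(txt)
  expect_identical(back$root, fit66$root)
  expect_identical(back$markers, fit66$markers)
  expect_identical(back$calls, fit66$calls)
  expect_identical(predict(back, c(TM442 = "268/286", TM324 = "171/171"))$cultivar,
                   56L)
})

test_that("DOT export has one edge per root branch and marks unresolved leaves", {
  dot <- cid_to_dot(fit66)
  expect_equal(length(grep("^  n1 -> ", strsplit(dot, "\n")[[1]])), 9)
  tiny <- cid(toy_table(list(M1 = c("100/100", "100/100"))), markers = "M1")
  expect_match(cid_to_dot(tiny), "fillcolor=lightgrey")
  expect_match(render_cid(tiny, "text"), "unresolved")
})

test_that("errors: empty order, unknown marker, bad sample input", {
  gt <- tea_genotypes()
  expect_error(cid(gt, markers = character(0)), "empty marker order")
  expect_error(cid(gt, markers = c("TM442", "TMX")), "absent")
  expect_error(predict(fit66, "268/286"), "named")
  expect_error(add_cultivar(fit66, 70, c(TM442 = "268/286")), "missing")
})
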