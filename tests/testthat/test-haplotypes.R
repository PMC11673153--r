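cat0 <- ascal_motif_catalogue(ref0)

test_that("a fully covered exact match returns the catalogued name", {
  hap <- cat0[["Capriola_ASCAL_ITA"]]
  res <- call_haplotype(hap$variants, hap$coverage, cat0)
  expect_identical(res$status, "known")
  expect_identical(res$names, "Capriola_ASCAL_ITA")
})

test_that("coverage gaps merge into the unique consistent haplotype", {
  hap <- cat0[["Wera_ASCAL_ITA"]]
  gap <- setdiff(hap$coverage, 16150:16250)  # drops one shared DOWN variant
  v <- hap$variants[hap$variants$position %in% gap, , drop = FALSE]
  res <- call_haplotype(v, gap, cat0)
  expect_identical(res$status, "known")
  expect_identical(res$names, "Wera_ASCAL_ITA")
})

test_that("coverage restricted to agreeing positions yields the ambiguity set", {
  # Allegra and Wera share their DOWN states; a sample covering only that
  # window cannot tell them apart
  cov <- 16160:16310
  v <- cat0[["Allegra_ASCAL_ITA"]]$variants
  v <- v[v$position %in% cov, , drop = FALSE]
  res <- call_haplotype(v, cov, cat0)
  expect_identical(res$status, "ambiguous")
  expect_setequal(res$names, c("Allegra_ASCAL_ITA", "Wera_ASCAL_ITA"))
})

test_that("a sample with no informative overlap errors, a novel one mints a name", {
  expect_error(call_haplotype(variant_table(), integer(0), cat0),
               "uninformative sample")
  pos <- 15461L  # not a catalogue position
  rb <- ref_base(ref0, pos)
  v <- variant_table(pos, rb, setdiff(c("A", "C", "G", "T"), rb)[1], "substitution")
  cov <- setdiff(15445:16660, 16129:16153)
  res <- call_haplotype(v, cov, cat0, suffix = "ASCAL_ITA")
  expect_identical(res$status, "new")
  expect_identical(res$names, "HT11_ASCAL_ITA")
  expect_s3_class(res$haplotype, "mt_haplotype")
})

test_that("polymorphic-site counts match a brute-force state-matrix scan", {
  # all-reference haplotypes: zero in both modes
  cov <- setdiff(15445:16660, 16129:16153)
  plain <- lapply(1:3, function(i) mt_haplotype(paste0("P", i), variant_table(), cov))
  expect_identical(count_polymorphic_sites(plain, ref0, "dloop", "among"), 0L)
  expect_identical(count_polymorphic_sites(plain, ref0, "dloop", "reference"), 0L)
  expect_error(count_polymorphic_sites(plain, ref0, c(15000, 16000)), "bad region")

  set.seed(77)
  for (rep in 1:8) {
    haps <- random_hap_set(5, ref0)
    for (mode in c("among", "reference")) {
      for (region in list("up", "down", "dloop")) {
        iv <- switch(region, up = ref0$up_interval, down = ref0$down_interval,
                     dloop = ref0$dloop_interval)
        expect_identical(count_polymorphic_sites(haps, ref0, region, mode),
                         brute_polymorphic(haps, iv, mode),
                         info = paste(rep, mode, region))
      }
    }
  }
})

test_that("UP and DOWN counts add to the D-loop count under full coverage", {
  set.seed(8)
  haps <- random_hap_set(6, ref0, gap_prob = 0)
  for (mode in c("among", "reference")) {
    expect_identical(
      count_polymorphic_sites(haps, ref0, "up", mode) +
        count_polymorphic_sites(haps, ref0, "down", mode),
      count_polymorphic_sites(haps, ref0, "dloop", mode)
    )
  }
})

test_that("fixture haplogroup rules classify the catalogue into six groups", {
  rules <- ascal_haplogroup_rules(cat0)
  calls <- vapply(cat0, function(h) assign_haplogroup(h, rules)$haplogroup,
                  character(1))
  expect_identical(sort(as.vector(table(calls)), decreasing = TRUE),
                   c(3L, 3L, 1L, 1L, 1L, 1L))
  counts <- table(calls)
  expect_identical(as.integer(counts[["G"]]), 3L)
  expect_identical(as.integer(counts[["L"]]), 3L)
  expect_setequal(names(counts), c("G", "L", "B", "C", "M", "Q"))
  expect_identical(unname(calls["J_ASCAL_ITA"]), "Q")
  expect_identical(unname(calls["U_ASCAL_ITA"]), "M")
})

test_that("haplogroup assignment handles no-match and uncovered motifs", {
  cov <- setdiff(15445:16660, 16129:16153)
  plain <- mt_haplotype("plain", variant_table(), cov)
  rules <- ascal_haplogroup_rules(cat0)
  res <- assign_haplogroup(plain, rules)
  expect_identical(res$haplogroup, "unclassified")
  # motif position uncovered: rule is a non-match and gets flagged
  gappy <- mt_haplotype("gappy", variant_table(), setdiff(cov, 15460L))
  res2 <- assign_haplogroup(gappy, rules)
  expect_identical(res2$haplogroup, "unclassified")
  expect_true("G" %in% res2$uncovered_rules)
  dup <- list(haplogroup_rule("A", cat0[[1]]$variants[1, ], 1L),
              haplogroup_rule("B", cat0[[2]]$variants[1, ], 1L))
  expect_error(assign_haplogroup(plain, dup), "priorities must be unique")
})

test_that("pairwise differences equal a per-position brute-force comparison", {
  hap <- cat0[["J_ASCAL_ITA"]]
  d0 <- pairwise_differences(list(hap, hap))
  expect_identical(unname(d0[1, 2]), 0L)

  set.seed(99)
  haps <- random_hap_set(5, ref0)
  d <- pairwise_differences(haps)
  expect_identical(d, t(d))
  expect_identical(unname(diag(d)), rep(0L, 5))
  for (i in 1:4) for (j in (i + 1):5) {
    common <- intersect(haps[[i]]$coverage, haps[[j]]$coverage)
    st_i <- .hap_state_test(haps[[i]], common)
    st_j <- .hap_state_test(haps[[j]], common)
    expect_identical(unname(d[i, j]), sum(st_i != st_j))
  }
})

test_that("distance zero iff identical variant sets on fully covered haplotypes", {
  set.seed(13)
  haps <- random_hap_set(6, ref0, gap_prob = 0)
  d <- pairwise_differences(haps)
  keys <- vapply(haps, function(h)
    paste(h$variants$position, h$variants$alt, collapse = ";"), character(1))
  for (i in 1:5) for (j in (i + 1):6) {
    expect_identical(d[i, j] == 0L, keys[i] == keys[j])
  }
})
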