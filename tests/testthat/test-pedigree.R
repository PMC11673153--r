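trio_df <- data.frame(id = c("A", "B", "C"), sire = c(NA, NA, "A"),
                      dam = c(NA, NA, "B"), sex = c("M", "F", "F"),
                      stringsAsFactors = FALSE)

test_that("pedigree validation reports structural defects", {
  v <- validate_pedigree(trio_df)
  expect_true(v$ok)
  expect_identical(founders(v$pedigree), c("A", "B"))

  cyc <- data.frame(id = c("X", "Y"), sire = c("Y", "X"), dam = c(NA, NA))
  expect_false(validate_pedigree(cyc)$ok)
  expect_error(pedigree(cyc), "cycle")

  dang <- data.frame(id = "X", sire = "ghost", dam = NA)
  expect_match(validate_pedigree(dang)$errors, "dangling")

  sexc <- data.frame(id = c("A", "B", "C"), sire = c(NA, NA, "A"),
                     dam = c(NA, NA, "A"))
  expect_match(validate_pedigree(sexc)$errors, "both as sire and dam")

  yr <- data.frame(id = c("A", "C"), sire = c(NA, "A"), dam = c(NA, NA),
                   birth_year = c(2000, 1990))
  expect_match(validate_pedigree(yr)$errors, "born after")
})

test_that("inbreeding matches the closed forms for simple matings", {
  fs <- pedigree(data.frame(id = c("A", "B", "C", "D", "E"),
                            sire = c(NA, NA, "A", "A", "C"),
                            dam = c(NA, NA, "B", "B", "D"),
                            sex = c("M", "F", "M", "F", "F")))
  expect_equal(inbreeding(fs)$F[["E"]], 0.25)
  po <- pedigree(data.frame(id = c("A", "B", "C", "E"),
                            sire = c(NA, NA, "A", "A"),
                            dam = c(NA, NA, "B", "C"),
                            sex = c("M", "F", "F", "F")))
  expect_equal(inbreeding(po)$F[["E"]], 0.25)
  expect_equal(unname(inbreeding(pedigree(trio_df))$F), c(0, 0, 0))
})

test_that("inbreeding equals Wright's path-counting oracle on random pedigrees", {
  set.seed(123)
  for (i in 1:10) {
    df <- random_pedigree_df(n_gen = 5, per_gen = 8)
    ped <- pedigree(df)
    expect_equal(inbreeding(ped)$F, wright_inbreeding(df), tolerance = 1e-12)
  }
})

test_that("founder contributions sum to one and give the closed-form f_e", {
  fc <- founder_contributions(pedigree(trio_df), reference = "C")
  expect_equal(unname(fc$q[c("A", "B")]), c(0.5, 0.5))
  expect_equal(fc$f_e, 2)
  # N equally contributing founders -> f_e = N
  eq <- pedigree(data.frame(id = c("A", "B", "C", "D", "x", "y"),
                            sire = c(NA, NA, NA, NA, "A", "C"),
                            dam = c(NA, NA, NA, NA, "B", "D"),
                            sex = c("M", "F", "M", "F", "F", "F")))
  fc2 <- founder_contributions(eq, reference = c("x", "y"))
  expect_equal(fc2$f_e, 4)
  # one known parent: the unknown side becomes a phantom, sum stays 1
  half <- pedigree(data.frame(id = c("A", "k"), sire = c(NA, "A"),
                              dam = c(NA, NA)))
  fc3 <- founder_contributions(half, reference = "k")
  expect_equal(sum(fc3$q), 1)
  expect_equal(unname(fc3$q[["k/D"]]), 0.5)
  expect_error(founder_contributions(pedigree(trio_df), reference = character(0)),
               "empty reference population")
})

test_that("founder contributions match the gene-dropping expectation", {
  set.seed(55)
  df <- random_pedigree_df(n_gen = 4, per_gen = 5, p_parents = 0.8)
  ped <- pedigree(df)
  refids <- reference_population(ped)
  fc <- founder_contributions(ped, refids)
  # simple test-side gene dropper: average founder-allele frequency
  ids <- ped$id; n <- length(ids)
  reps <- 5000
  origin_ids <- names(fc$q)
  freq_sum <- setNames(numeric(length(origin_ids)), origin_ids)
  sire <- ped$sire; dam <- ped$dam; ord <- ped$order
  for (r in seq_len(reps)) {
    a1 <- character(n); a2 <- character(n)
    for (i in ord) {
      a1[i] <- if (is.na(sire[i])) {
        if (is.na(dam[i])) ids[i] else paste0(ids[i], "/S")
      } else if (runif(1) < 0.5) a1[sire[i]] else a2[sire[i]]
      a2[i] <- if (is.na(dam[i])) {
        if (is.na(sire[i])) ids[i] else paste0(ids[i], "/D")
      } else if (runif(1) < 0.5) a1[dam[i]] else a2[dam[i]]
    }
    pool <- c(a1[match(refids, ids)], a2[match(refids, ids)])
    tt <- table(pool) / length(pool)
    freq_sum[names(tt)] <- freq_sum[names(tt)] + tt
  }
  expect_equal(unname(freq_sum / reps), unname(fc$q), tolerance = 0.01)
})

test_that("a bottleneck sire dominates the marginal ancestor analysis", {
  # S is the son of two founders and fathers every reference animal, so he
  # intercepts his parents' contributions: f_a must drop below f_e
  n <- 8
  df <- data.frame(
    id = c("GA", "GB", "S", paste0("D", 1:n), paste0("K", 1:n)),
    sire = c(NA, NA, "GA", rep(NA, n), rep("S", n)),
    dam = c(NA, NA, "GB", rep(NA, n), paste0("D", 1:n)),
    sex = c("M", "F", "M", rep("F", n), rep("F", n)), stringsAsFactors = FALSE)
  ped <- pedigree(df)
  ea <- effective_ancestors(ped, reference = paste0("K", 1:n))
  expect_identical(names(ea$p)[1], "S")
  expect_gte(ea$p[[1]], 0.5)
  fe <- founder_contributions(ped, paste0("K", 1:n))$f_e
  expect_lt(ea$f_a, fe)
})

test_that("without bottlenecks the effective ancestors equal the founders", {
  eq <- pedigree(data.frame(id = c("A", "B", "C", "D", "x", "y"),
                            sire = c(NA, NA, NA, NA, "A", "C"),
                            dam = c(NA, NA, NA, NA, "B", "D"),
                            sex = c("M", "F", "M", "F", "F", "F")))
  ea <- effective_ancestors(eq, reference = c("x", "y"))
  fc <- founder_contributions(eq, reference = c("x", "y"))
  expect_equal(ea$f_a, fc$f_e, tolerance = 1e-9)
  expect_setequal(names(ea$p), c("A", "B", "C", "D"))
})

test_that("marginal ancestors match a from-scratch recomputation oracle", {
  set.seed(321)
  for (i in 1:6) {
    df <- random_pedigree_df(n_gen = 4, per_gen = 6, p_parents = 0.8)
    ped <- pedigree(df)
    refids <- reference_population(ped)
    if (length(refids) == length(df$id)) next  # no ancestry at all
    ea <- effective_ancestors(ped, refids)
    orc <- naive_effective_ancestors(df, refids)
    expect_equal(unname(ea$p), unname(orc$p), tolerance = 1e-9)
    expect_equal(ea$f_a, orc$f_a, tolerance = 1e-9)
  }
})

test_that("gene dropping honours the exact closed forms and the seed", {
  single <- pedigree(data.frame(id = "A", sire = NA, dam = NA))
  ng1 <- founder_genomes(single, reference = "A", replicates = 50, seed = 4)
  expect_equal(ng1$N_g, 1)
  four <- pedigree(data.frame(id = c("A", "B", "C", "D"), sire = NA, dam = NA))
  ng4 <- founder_genomes(four, reference = c("A", "B", "C", "D"),
                         replicates = 50, seed = 4)
  expect_equal(ng4$N_g, 4)
  ped <- pedigree(trio_df)
  a <- founder_genomes(ped, reference = "C", replicates = 500, seed = 42)
  b <- founder_genomes(ped, reference = "C", replicates = 500, seed = 42)
  expect_identical(a, b)
  expect_error(founder_genomes(ped, reference = "C", replicates = 10),
               "seed is required")
})

test_that("completeness counts individuals with both parents known", {
  expect_equal(completeness(pedigree(trio_df)), 1 / 3)
  allf <- pedigree(data.frame(id = c("A", "B"), sire = NA, dam = NA))
  expect_equal(completeness(allf), 0)
})

test_that("matriline tracing propagates the foundress haplotype", {
  df <- data.frame(id = c("F0", "S", "M1", "M2"),
                   sire = c(NA, NA, "S", "S"),
                   dam = c(NA, NA, "F0", "M1"),
                   sex = c("F", "M", "F", "F"), stringsAsFactors = FALSE)
  ped <- pedigree(df)
  exp <- matriline_expected_haplotype(ped, c(F0 = "HapZ"))
  expect_identical(unname(exp[c("F0", "M1", "M2")]), rep("HapZ", 3))
  expect_identical(unname(exp[["S"]]), "unmapped matriline")
  # broken dam line -> untraceable
  df2 <- rbind(df, data.frame(id = "M3", sire = "S", dam = NA, sex = "F"))
  exp2 <- matriline_expected_haplotype(pedigree(df2), c(F0 = "HapZ"))
  expect_identical(unname(exp2[["M3"]]), "untraceable")
})

test_that("gene-origin summaries respect N_g <= f_a <= f_e <= founders", {
  for (seed in c(2, 9)) {
    sim <- simulate_stud(stud_scenario(generations = 5), seed = seed)
    ped <- pedigree(sim$pedigree_records)
    refids <- stud_reference_ids(sim)
    go <- gene_origin(ped, reference = refids, replicates = 1000, seed = seed + 1)
    expect_lte(go$N_g, go$f_a + 1e-9)
    expect_lte(go$f_a, go$f_e + 1e-9)
    expect_lte(go$f_e, go$total_founders + 1e-9)
    expect_equal(sum(go$q), 1)
    expect_lte(sum(go$p), 1 + 1e-6)
    expect_true(all(go$q >= 0))
  }
})
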