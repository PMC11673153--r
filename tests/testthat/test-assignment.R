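test_that("contingency building is order-invariant and keeps zero rows", {
  m <- data.frame(sample_id = c("a", "b", "c"),
                  family = c("F1", "F1", "F2"),
                  haplotype = c("H1", "H1", "H2"), stringsAsFactors = FALSE)
  tab <- build_contingency(m)
  expect_identical(unname(tab["F1", "H1"]), 2L)
  expect_identical(sum(tab), 3L)
  perm <- build_contingency(m[c(3, 1, 2), ])
  expect_identical(unclass(tab), unclass(perm))
  # single mare
  one <- build_contingency(m[1, ])
  expect_identical(dim(one), c(1L, 1L))
  expect_identical(unname(one[1, 1]), 1L)
  # zero-count family carried through
  tab2 <- build_contingency(m, families = c("F1", "F2", "F3"))
  expect_identical(as.integer(rowSums(tab2)[["F3"]]), 0L)
  expect_error(build_contingency(m[0, ]), "no data")
  bad <- m; bad$family[1] <- ""
  expect_error(build_contingency(bad), "family and haplotype labels")
})

test_that("a diagonal table resolves by unique support alone", {
  m <- diag(3) * c(4, 5, 6)
  dimnames(m) <- list(family = c("A", "B", "C"), haplotype = c("h1", "h2", "h3"))
  storage.mode(m) <- "integer"
  class(m) <- c("contingency_table", class(m))
  asg <- assign_families(m)
  expect_identical(asg$map, list(h1 = "A", h2 = "B", h3 = "C"))
  expect_true(all(asg$steps$rule == "unique-support"))
  ret <- retention(data.frame(sample_id = "x", family = "B", haplotype = "h2"), asg)
  expect_identical(ret$retained, 1L)
})

test_that("assignment is deterministic and permutation-invariant", {
  set.seed(41)
  for (i in 1:20) {
    m <- matrix(rpois(25, 1.2), 5, 5,
                dimnames = list(family = paste0("F", 1:5),
                                haplotype = paste0("h", 1:5)))
    storage.mode(m) <- "integer"
    if (any(colSums(m) == 0) || any(rowSums(m) == 0)) next
    class(m) <- c("contingency_table", class(m))
    a1 <- assign_families(m)
    mp <- m[sample(5), sample(5)]
    class(mp) <- c("contingency_table", class(mp))
    a2 <- assign_families(mp)
    expect_identical(a1$map[sort(names(a1$map))], a2$map[sort(names(a2$map))])
  }
})

test_that("families with mares but no haplotype are flagged, not fatal", {
  m <- rbind(A = c(2L, 0L), B = c(0L, 0L))
  # family B has no mares at all -> not flagged; add a family observed only
  # in an already-claimed haplotype
  m <- rbind(A = c(3L, 0L), B = c(1L, 0L), C = c(0L, 2L))
  dimnames(m) <- list(family = c("A", "B", "C"), haplotype = c("h1", "h2"))
  class(m) <- c("contingency_table", class(m))
  asg <- assign_families(m)
  expect_true("B" %in% asg$families_without_haplotype)
})

test_that("the exhaustive oracle beats a naive column-max greedy on a trap", {
  m <- rbind(A = c(6L, 5L, 0L), B = c(5L, 0L, 0L), C = c(0L, 0L, 3L))
  dimnames(m) <- list(family = c("A", "B", "C"), haplotype = c("h1", "h2", "h3"))
  class(m) <- c("contingency_table", class(m))
  orc <- matching_oracle(m)
  # naive greedy: h1 takes its best family A (6); h2's only family is gone
  greedy_total <- 6L + 0L + 3L
  expect_gt(orc$retained, greedy_total)
  expect_identical(orc$retained, 13L)
  expect_identical(orc$map$h1, "B")
  # diagonal: optimum is the diagonal sum
  d <- rbind(A = c(4L, 0L), B = c(0L, 7L))
  dimnames(d) <- list(family = c("A", "B"), haplotype = c("h1", "h2"))
  class(d) <- c("contingency_table", class(d))
  expect_identical(matching_oracle(d)$retained, 11L)
})

test_that("greedy assignment never beats the exhaustive oracle", {
  set.seed(17)
  checked <- 0
  for (i in 1:40) {
    m <- matrix(rpois(25, 1.5), 5, 5,
                dimnames = list(family = paste0("F", 1:5),
                                haplotype = paste0("h", 1:5)))
    storage.mode(m) <- "integer"
    if (any(colSums(m) == 0) || any(rowSums(m) == 0)) next
    class(m) <- c("contingency_table", class(m))
    asg <- assign_families(m)
    full <- length(asg$unassigned) == 0 &&
      all(vapply(asg$map, length, integer(1)) == 1L)
    if (!full) next
    orc <- try(matching_oracle(m), silent = TRUE)
    if (inherits(orc, "try-error") || is.na(orc$retained)) next
    retained <- sum(vapply(names(asg$map),
                           function(h) m[asg$map[[h]], h], integer(1)))
    expect_lte(retained, orc$retained)
    checked <- checked + 1
  }
  expect_gte(checked, 5)
})

test_that("retention statuses partition the mares", {
  mares <- table1_fixture()
  asg <- assign_families(table1_counts())
  ret <- retention(mares, asg)
  expect_identical(ret$retained + ret$culled + ret$unassessable, nrow(mares))
  # a single mislabeled mare in an otherwise clean stud is exactly the cull
  clean <- data.frame(sample_id = sprintf("m%02d", 1:9),
                      family = rep(c("A", "B", "C"), each = 3),
                      haplotype = rep(c("h1", "h2", "h3"), each = 3),
                      stringsAsFactors = FALSE)
  clean$haplotype[5] <- "h3"  # mare m05 carries the wrong matriline
  asg2 <- assign_families(build_contingency(clean))
  ret2 <- retention(clean, asg2)
  expect_identical(ret2$per_mare$status[5], "culled")
  expect_identical(sum(ret2$per_mare$status == "culled"), 1L)
  # haplotype absent from the map -> unassessable
  odd <- rbind(clean, data.frame(sample_id = "m10", family = "A",
                                 haplotype = "ghost"))
  ret3 <- retention(odd, asg2)
  expect_identical(ret3$unassessable, 1L)
})

test_that("haplotype percentages are rounded half-to-even to one decimal", {
  freq <- haplotype_frequencies(table1_counts())
  expect_identical(freq$percent[freq$haplotype == "J_ASCAL_ITA"], 17.2)
  expect_identical(freq$percent[freq$haplotype == "X_ASCAL_ITA"], 8.6)
  single <- build_contingency(data.frame(sample_id = c("a", "b"),
                                         family = c("F", "F"),
                                         haplotype = c("h", "h")))
  expect_identical(haplotype_frequencies(single)$percent, 100)
})

test_that("removing one mare of an assigned pair leaves the rest of the map intact", {
  mares <- table1_fixture()
  asg <- assign_families(build_contingency(mares))
  # drop one Ivanka/J mare (cell count 15 stays > 0)
  drop <- which(mares$family == "Ivanka" & mares$haplotype == "J_ASCAL_ITA")[1]
  asg2 <- assign_families(build_contingency(mares[-drop, ]))
  expect_identical(asg$map[sort(names(asg$map))], asg2$map[sort(names(asg2$map))])
})
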