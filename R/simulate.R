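.ascal_families <- c("Africa", "Almerina", "Argentina", "Deflorata", "Djebrin",
                     "Europa", "Fistula", "Ivanka", "Sardinia", "Spadiglia",
                     "Theodorosta")

.ascal_haplotypes <- c("X", "Capriola", "Allegra", "Monteaura", "U",
                       "Dubovina", "Batosta", "J", "Slavina", "Wera")

.hap_full <- function(x) paste0(x, "_ASCAL_ITA")

#' The 2014 family-by-haplotype mare counts
#'
#' The packaged worked-example contingency matrix of the 93 genotyped mares
#' of the 2014 stud: eleven pedigree maternal families (rows) by ten
#' detected mtDNA haplotypes (columns). This matrix is the single source
#' for every worked-example test and report in the package.
#'
#' @return An integer matrix of class `contingency_table`.
#' @export
table1_counts <- function() {
  m <- rbind(
    Africa      = c(0, 0, 0, 2, 0, 0, 7, 0, 0, 0),
    Almerina    = c(0, 4, 3, 0, 0, 0, 0, 0, 2, 0),
    Argentina   = c(5, 4, 0, 0, 3, 0, 0, 1, 0, 0),
    Deflorata   = c(0, 6, 2, 0, 0, 0, 0, 0, 0, 0),
    Djebrin     = c(0, 0, 0, 0, 0, 9, 0, 0, 0, 0),
    Europa      = c(0, 0, 0, 0, 1, 0, 0, 0, 0, 0),
    Fistula     = c(0, 6, 5, 0, 0, 0, 0, 0, 0, 0),
    Ivanka      = c(0, 0, 0, 0, 0, 0, 0, 15, 0, 0),
    Sardinia    = c(0, 3, 0, 7, 0, 0, 0, 0, 0, 2),
    Spadiglia   = c(3, 0, 0, 2, 0, 0, 0, 0, 0, 0),
    Theodorosta = c(0, 0, 0, 0, 1, 0, 0, 0, 0, 0)
  )
  storage.mode(m) <- "integer"
  dimnames(m) <- list(family = .ascal_families,
                      haplotype = .hap_full(.ascal_haplotypes))
  class(m) <- c("contingency_table", class(m))
  m
}

#' The 93-mare worked-example records
#'
#' Expands [table1_counts()] into one record per mare (`sample_id`,
#' `family`, `haplotype`), in a fixed canonical order.
#'
#' @return Data frame with 93 rows.
#' @export
table1_fixture <- function() {
  m <- unclass(table1_counts())
  fam <- character(); hap <- character()
  for (f in rownames(m)) {
    for (h in colnames(m)) {
      k <- m[f, h]
      if (k > 0L) {
        fam <- c(fam, rep(f, k)); hap <- c(hap, rep(h, k))
      }
    }
  }
  data.frame(sample_id = sprintf("M%03d", seq_along(fam)),
             family = fam, haplotype = hap, stringsAsFactors = FALSE)
}

#' Family-to-haplotype truth map of the packaged stud
#'
#' The maternal-family to mtDNA-haplotype association of the packaged
#' closed-stud scenario. Europa and Theodorosta share the U haplotype
#' unless `distinct_families` requests a fully distinguishable catalogue
#' (Theodorosta then carries a synthetic private haplotype).
#'
#' @param distinct_families Give Theodorosta its own synthetic haplotype.
#' @return Named character vector family -> haplotype name.
#' @export
ascal_family_map <- function(distinct_families = FALSE) {
  map <- c(Africa = "Batosta", Almerina = "Slavina", Argentina = "X",
           Deflorata = "Capriola", Djebrin = "Dubovina", Europa = "U",
           Fistula = "Allegra", Ivanka = "J", Sardinia = "Wera",
           Spadiglia = "Monteaura", Theodorosta = "U")
  map <- setNames(.hap_full(map), names(map))
  if (distinct_families) map[["Theodorosta"]] <- "UTheo_SYN_ITA"
  map
}

#' Synthetic 10-haplotype motif catalogue (stand-in)
#'
#' Builds the packaged catalogue of ten named control-region haplotypes as
#' substitution motifs on the reference frame. The catalogue is synthetic
#' (the deposited haplotype sequences are not bundled) but is constructed
#' to carry the regional structure of the stud's real haplotypes:
#'
#' * 55 polymorphic sites among the ten haplotypes in the UP region
#'   (np 15445-16153) and 8 in the DOWN region (np 16154-16660);
#' * shared diagnostic variants grouping \{X, Slavina, Dubovina\} and
#'   \{Allegra, Monteaura, Wera\} (used by the fixture haplogroup rules);
#' * identical DOWN-region states within \{Allegra, Wera\} and
#'   \{Capriola, Slavina, Dubovina, X\};
#' * an uncovered ("nd") window at np 16320-16399 for every haplotype
#'   except Allegra and Batosta, which are fully covered.
#'
#' @param ref A [reference_map()]; defaults to the synthetic frame.
#' @param distinct_families Add an eleventh synthetic haplotype private to
#'   Theodorosta (see [ascal_family_map()]).
#' @return Named list of [mt_haplotype()] objects.
#' @export
ascal_motif_catalogue <- function(ref = synthetic_mt_reference(),
                                  distinct_families = FALSE) {
  up_pos <- 15460L + 12L * (0:54)   # 55 UP positions, all below the repeat
  g_shared <- up_pos[1]             # X, Slavina, Dubovina
  l_shared <- up_pos[2]             # Allegra, Monteaura, Wera
  private_sizes <- c(X = 6L, Capriola = 6L, Allegra = 6L, Monteaura = 6L,
                     U = 5L, Dubovina = 5L, Batosta = 5L, J = 5L,
                     Slavina = 5L, Wera = 4L)
  stopifnot(sum(private_sizes) == 53L)
  pool <- up_pos[-(1:2)]
  privates <- list(); k <- 0L
  for (h in names(private_sizes)) {
    privates[[h]] <- pool[(k + 1L):(k + private_sizes[[h]])]
    k <- k + private_sizes[[h]]
  }
  down <- list(
    X = c(16230L, 16260L), Capriola = c(16230L, 16260L),
    Slavina = c(16230L, 16260L), Dubovina = c(16230L, 16260L),
    Allegra = c(16170L, 16200L), Wera = c(16170L, 16200L),
    Batosta = c(16290L, 16430L), J = 16500L, Monteaura = 16600L,
    U = integer(0)
  )
  full_cov <- setdiff(.interval_seq(ref$dloop_interval),
                      if (is.null(ref$repeat_interval)) integer(0)
                      else .interval_seq(ref$repeat_interval))
  nd_cov <- setdiff(full_cov, 16320:16399)

  build <- function(short, positions, coverage) {
    positions <- sort(positions)
    rb <- ref_base(ref, positions)
    mt_haplotype(.hap_full(short),
                 variant_table(positions, rb, unname(.complement_base(rb)),
                               rep("substitution", length(positions))),
                 coverage, ref = ref)
  }
  cat <- list()
  for (h in .ascal_haplotypes) {
    pos <- c(privates[[h]], down[[h]])
    if (h %in% c("X", "Slavina", "Dubovina")) pos <- c(pos, g_shared)
    if (h %in% c("Allegra", "Monteaura", "Wera")) pos <- c(pos, l_shared)
    cov <- if (h %in% c("Allegra", "Batosta")) full_cov else nd_cov
    cat[[.hap_full(h)]] <- build(h, pos, cov)
  }
  if (distinct_families) {
    pos <- c(privates[["U"]], down[["U"]], 16116L)
    rb <- ref_base(ref, sort(pos))
    cat[["UTheo_SYN_ITA"]] <- mt_haplotype(
      "UTheo_SYN_ITA",
      variant_table(sort(pos), rb, unname(.complement_base(rb)),
                    rep("substitution", length(pos))),
      nd_cov, ref = ref)
  }
  keys <- vapply(cat, function(h) paste(.variant_keys(h$variants), collapse = ";"),
                 character(1))
  stopifnot(!anyDuplicated(keys))   # catalogue must be injective
  cat
}

#' Fixture haplogroup rules for the packaged catalogue
#'
#' Diagnostic-motif rules classifying the packaged haplotypes into six
#' haplogroups: G = \{X, Slavina, Dubovina\} and L = \{Allegra, Monteaura,
#' Wera\} via their shared variants, and B/C/M/Q as singletons (Capriola,
#' Batosta, U, J) via one private variant each. Real analyses must supply
#' genuine diagnostic motifs from the haplogroup nomenclature; these rules
#' exist so the classification machinery is testable offline.
#'
#' @param catalogue An [ascal_motif_catalogue()].
#' @return List of [haplogroup_rule()].
#' @export
ascal_haplogroup_rules <- function(catalogue = ascal_motif_catalogue()) {
  motif_of <- function(hap, pos) {
    v <- catalogue[[.hap_full(hap)]]$variants
    v[v$position %in% pos, , drop = FALSE]
  }
  first_private <- function(hap) {
    v <- catalogue[[.hap_full(hap)]]$variants
    v <- v[v$position >= 15460 & v$position <= 16128, , drop = FALSE]
    # skip the two shared leading positions
    v <- v[!v$position %in% c(15460L, 15472L), , drop = FALSE]
    v[1, , drop = FALSE]
  }
  list(
    haplogroup_rule("G", motif_of("X", 15460L), 1L),
    haplogroup_rule("L", motif_of("Allegra", 15472L), 2L),
    haplogroup_rule("B", first_private("Capriola"), 3L),
    haplogroup_rule("Q", first_private("J"), 4L),
    haplogroup_rule("C", first_private("Batosta"), 5L),
    haplogroup_rule("M", first_private("U"), 6L)
  )
}

#' Describe a closed-stud simulation scenario
#'
#' Bundles the parameters of the synthetic closed stud: a multi-generation
#' pedigree bred in complete genetic segregation under conservation
#' management (per-family quotas protect every matriline), strict
#' dam-to-offspring mtDNA transmission, a configurable family-label
#' recording-error rate, missing-parent injection, and a haplotype motif
#' catalogue per family.
#'
#' @param families Character vector of maternal family names.
#' @param foundresses_per_family Founder mares per family.
#' @param male_founders Number of founder stallions.
#' @param generations Number of discrete generations bred after the
#'   founders.
#' @param mean_offspring Poisson mean of offspring per mare per generation.
#' @param mares_per_generation Carrying capacity on females kept for
#'   breeding each generation (allocated evenly across families, which is
#'   what keeps matrilines alive in a conservation stud).
#' @param stallions_per_generation Males kept for breeding each generation.
#' @param label_error_rate Probability that a female's recorded family
#'   label is switched to a different family (the recorded label only; her
#'   transmitted haplotype always follows the true matriline).
#' @param missing_parent_rate Probability that a non-founder's recorded
#'   parents are lost (both recorded unknown).
#' @param family_map Named vector family -> haplotype name
#'   (default [ascal_family_map()]).
#' @param msy_proportions Haplotype proportions for [emit_msy()].
#' @param n_sample_mares Optional cap: sample this many final-generation
#'   mares for genotyping.
#' @param max_population Hard guard on total pedigree size.
#' @return An object of class `stud_scenario`.
#' @export
stud_scenario <- function(families = .ascal_families,
                          foundresses_per_family = 3L,
                          male_founders = 6L,
                          generations = 8L,
                          mean_offspring = 4,
                          mares_per_generation = 44L,
                          stallions_per_generation = 8L,
                          label_error_rate = 0.1,
                          missing_parent_rate = 0.05,
                          family_map = ascal_family_map(),
                          msy_proportions = c(HT01 = 0.2, HT02 = 0.8, HT3 = 0),
                          n_sample_mares = NULL,
                          max_population = 50000L) {
  stopifnot(length(families) >= 1L, !anyDuplicated(families))
  stopifnot(label_error_rate >= 0, label_error_rate <= 1)
  stopifnot(missing_parent_rate >= 0, missing_parent_rate <= 1)
  stopifnot(abs(sum(msy_proportions) - 1) < 1e-9)
  stopifnot(all(families %in% names(family_map)))
  structure(list(families = families,
                 foundresses_per_family = as.integer(foundresses_per_family),
                 male_founders = as.integer(male_founders),
                 generations = as.integer(generations),
                 mean_offspring = mean_offspring,
                 mares_per_generation = as.integer(mares_per_generation),
                 stallions_per_generation = as.integer(stallions_per_generation),
                 label_error_rate = label_error_rate,
                 missing_parent_rate = missing_parent_rate,
                 family_map = family_map,
                 msy_proportions = msy_proportions,
                 n_sample_mares = n_sample_mares,
                 max_population = as.integer(max_population)),
            class = "stud_scenario")
}

.with_seed <- function(seed, expr) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Breed `n_gen` generations starting from the given mothers/fathers.
# `state` is an environment holding the growing record vectors.
.breed <- function(state, scenario, mothers, fathers, gen_start, n_gen) {
  for (g in seq_len(n_gen)) {
    gen <- gen_start + g - 1L
    if (!length(fathers)) fathers <- state$id[state$sex == "M"]
    if (!length(fathers)) stop("no breeding males left")
    n_off <- rpois(length(mothers), scenario$mean_offspring)
    tot <- sum(n_off)
    if (tot > 0L) {
      dam <- rep(mothers, n_off)
      fam <- state$fam_true[match(dam, state$id)]
      id <- sprintf("I%05d", state$n + seq_len(tot))
      state$n <- state$n + tot
      sire <- fathers[sample.int(length(fathers), tot, replace = TRUE)]
      sx <- ifelse(runif(tot) < 0.5, "F", "M")
      state$id <- c(state$id, id)
      state$sire <- c(state$sire, sire)
      state$dam <- c(state$dam, dam)
      state$sex <- c(state$sex, sx)
      state$birth_year <- c(state$birth_year, rep(1900L + 8L * gen, tot))
      state$fam_true <- c(state$fam_true, fam)
      state$generation <- c(state$generation, rep(gen, tot))
      new_f <- id[sx == "F"]; new_m <- id[sx == "M"]
    } else {
      new_f <- character(); new_m <- character()
    }
    if (length(state$id) > scenario$max_population) {
      stop("simulated population exceeded max_population")
    }
    # conservation management: per-family female quotas, capped stallions
    quota <- ceiling(scenario$mares_per_generation / length(scenario$families))
    kept_f <- character()
    fam_new <- state$fam_true[match(new_f, state$id)]
    for (f in unique(fam_new)) {
      ff <- new_f[fam_new == f]
      if (length(ff) > quota) ff <- ff[sample.int(length(ff), quota)]
      kept_f <- c(kept_f, ff)
    }
    if (length(new_m) > scenario$stallions_per_generation) {
      new_m <- new_m[sample.int(length(new_m), scenario$stallions_per_generation)]
    }
    mothers <- kept_f
    fathers <- new_m
  }
  list(mothers = mothers, fathers = fathers)
}

.one_stud_run <- function(scenario) {
  state <- new.env(parent = emptyenv())
  state$id <- character(); state$sire <- character(); state$dam <- character()
  state$sex <- character(); state$birth_year <- integer()
  state$fam_true <- character(); state$generation <- integer()
  state$n <- 0L
  add <- function(id, sire, dam, sex, by, fam, gen) {
    state$id <- c(state$id, id); state$sire <- c(state$sire, sire)
    state$dam <- c(state$dam, dam); state$sex <- c(state$sex, sex)
    state$birth_year <- c(state$birth_year, by)
    state$fam_true <- c(state$fam_true, fam)
    state$generation <- c(state$generation, gen)
  }
  mothers <- character()
  for (f in scenario$families) {
    for (k in seq_len(scenario$foundresses_per_family)) {
      state$n <- state$n + 1L
      id <- sprintf("I%05d", state$n)
      add(id, NA_character_, NA_character_, "F", 1900L, f, 0L)
      mothers <- c(mothers, id)
    }
  }
  fathers <- character()
  for (k in seq_len(scenario$male_founders)) {
    state$n <- state$n + 1L
    id <- sprintf("I%05d", state$n)
    add(id, NA_character_, NA_character_, "M", 1900L, NA_character_, 0L)
    fathers <- c(fathers, id)
  }
  .breed(state, scenario, mothers, fathers, 1L, scenario$generations)
  state
}

#' Simulate a closed stud
#'
#' Generates a multi-generation closed pedigree under the scenario's
#' conservation management, transmits mtDNA families strictly dam to
#' offspring, injects recording errors (family-label switches on females,
#' lost parent records), and returns the recorded pedigree together with a
#' full truth log. Deterministic for a given seed. If any maternal family's
#' female line goes extinct before the final generation the run is retried
#' (bounded, with a warning).
#'
#' @param scenario A [stud_scenario()].
#' @param seed Mandatory integer seed.
#' @param max_retries Retries allowed on matriline extinction.
#' @return An object of class `stud_simulation`: list with
#'   `pedigree_records` (recorded data: `id`, `sire`, `dam`, `sex`,
#'   `birth_year`, `family`), `truth` (per individual: true family,
#'   recorded family, `mislabeled`, `generation`), `mares` (ids of the
#'   genotyped final-generation females), `error_log`, `missing_log`,
#'   `scenario`, `seed`.
#' @export
simulate_stud <- function(scenario, seed, max_retries = 20L) {
  stopifnot(inherits(scenario, "stud_scenario"))
  if (missing(seed)) stop("an explicit seed is required")
  .with_seed(seed, {
    state <- NULL
    for (attempt in seq_len(max_retries)) {
      st <- .one_stud_run(scenario)
      final_gen <- max(st$generation)
      fin_f <- st$id[st$sex == "F" & st$generation == final_gen]
      fams_alive <- unique(st$fam_true[match(fin_f, st$id)])
      if (setequal(fams_alive, scenario$families)) { state <- st; break }
      warning("matriline extinct before final generation; retrying simulation")
    }
    if (is.null(state)) stop("matriline extinction persisted across retries")

    n <- length(state$id)
    recorded_family <- state$fam_true
    is_f <- state$sex == "F"
    flip <- is_f & runif(n) < scenario$label_error_rate
    for (i in which(flip)) {
      others <- setdiff(scenario$families, state$fam_true[i])
      recorded_family[i] <- others[sample.int(length(others), 1L)]
    }
    rec_sire <- state$sire; rec_dam <- state$dam
    nonf <- !(is.na(state$sire) & is.na(state$dam))
    lost <- nonf & runif(n) < scenario$missing_parent_rate
    rec_sire[lost] <- NA_character_
    rec_dam[lost] <- NA_character_

    final_gen <- max(state$generation)
    mares <- state$id[is_f & state$generation == final_gen]
    if (!is.null(scenario$n_sample_mares) &&
        length(mares) > scenario$n_sample_mares) {
      mares <- mares[sample.int(length(mares), scenario$n_sample_mares)]
    }

    structure(list(
      pedigree_records = data.frame(
        id = state$id, sire = rec_sire, dam = rec_dam, sex = state$sex,
        birth_year = state$birth_year, family = recorded_family,
        stringsAsFactors = FALSE),
      truth = data.frame(
        id = state$id, family_true = state$fam_true,
        family_recorded = recorded_family,
        mislabeled = flip, generation = state$generation, sex = state$sex,
        stringsAsFactors = FALSE),
      mares = mares,
      error_log = data.frame(
        id = state$id[flip], family_true = state$fam_true[flip],
        family_recorded = recorded_family[flip], stringsAsFactors = FALSE),
      missing_log = state$id[lost],
      scenario = scenario, seed = seed
    ), class = "stud_simulation")
  })
}

#' @export
print.stud_simulation <- function(x, ...) {
  cat("Simulated closed stud:", nrow(x$pedigree_records), "individuals,",
      length(x$mares), "genotyped mares,",
      nrow(x$error_log), "label errors\n")
  invisible(x)
}

#' Continue breeding a simulated stud from a retained subset
#'
#' Breeds further generations starting from a retained subset of the
#' existing animals (e.g. after haplotype-based culling), with no new label
#' errors or record losses. Used to study how diversity statistics respond
#' to a cull.
#'
#' @param sim A [simulate_stud()] result.
#' @param keep_ids Ids allowed to breed (females among them become the
#'   mothers, males the fathers).
#' @param generations Number of additional generations.
#' @param seed Mandatory integer seed.
#' @return A new `stud_simulation` with extended records.
#' @export
continue_stud <- function(sim, keep_ids, generations, seed) {
  stopifnot(inherits(sim, "stud_simulation"))
  if (missing(seed)) stop("an explicit seed is required")
  tr <- sim$truth
  stopifnot(all(keep_ids %in% tr$id))
  .with_seed(seed, {
    state <- new.env(parent = emptyenv())
    state$id <- tr$id
    state$sire <- sim$pedigree_records$sire
    state$dam <- sim$pedigree_records$dam
    state$sex <- tr$sex
    state$birth_year <- sim$pedigree_records$birth_year
    state$fam_true <- tr$family_true
    state$generation <- tr$generation
    state$n <- max(as.integer(sub("^I", "", tr$id)))
    mothers <- keep_ids[tr$sex[match(keep_ids, tr$id)] == "F"]
    fathers <- keep_ids[tr$sex[match(keep_ids, tr$id)] == "M"]
    g0 <- max(tr$generation) + 1L
    .breed(state, sim$scenario, mothers, fathers, g0, generations)

    keep_old <- seq_len(nrow(tr))
    new_idx <- seq_along(state$id) > nrow(tr)
    recorded_family <- c(tr$family_recorded, state$fam_true[new_idx])
    final_gen <- max(state$generation)
    mares <- state$id[state$sex == "F" & state$generation == final_gen]
    structure(list(
      pedigree_records = data.frame(
        id = state$id, sire = state$sire, dam = state$dam, sex = state$sex,
        birth_year = state$birth_year, family = recorded_family,
        stringsAsFactors = FALSE),
      truth = data.frame(
        id = state$id, family_true = state$fam_true,
        family_recorded = recorded_family,
        mislabeled = c(tr$mislabeled, rep(FALSE, sum(new_idx))),
        generation = state$generation, sex = state$sex,
        stringsAsFactors = FALSE),
      mares = mares,
      error_log = sim$error_log,
      missing_log = sim$missing_log,
      scenario = sim$scenario, seed = seed
    ), class = "stud_simulation")
  })
}

#' Reference ids of a simulated stud
#'
#' The "living animals" of a simulated stud: every individual born in the
#' final generation. This is the id list to hand to the gene-origin
#' statistics as the reference population (the recorded pedigree has no
#' death dates, so the no-progeny default would sweep in historical
#' non-breeders).
#'
#' @param sim A [simulate_stud()] result.
#' @return Character ids.
#' @export
stud_reference_ids <- function(sim) {
  tr <- sim$truth
  tr$id[tr$generation == max(tr$generation)]
}

#' Genotyped-mare table of a simulated stud
#'
#' One row per genotyped mare: her recorded family label and the haplotype
#' her true matriline transmits (observed haplotypes always follow the true
#' matriline; only the label can be wrong).
#'
#' @param sim A [simulate_stud()] result.
#' @return Data frame `sample_id`, `family`, `haplotype`, `mislabeled`.
#' @export
stud_mare_table <- function(sim) {
  tr <- sim$truth[match(sim$mares, sim$truth$id), ]
  data.frame(sample_id = tr$id,
             family = tr$family_recorded,
             haplotype = unname(sim$scenario$family_map[tr$family_true]),
             mislabeled = tr$mislabeled,
             stringsAsFactors = FALSE)
}

#' Emit control-region sequences for a set of mares
#'
#' Builds each mare's D-loop sequence as the reference subsequence with her
#' haplotype's variants applied; positions outside the haplotype's coverage
#' (the "nd" windows) are emitted as `N`. Only substitution motifs are
#' supported. Optionally writes a FASTA file and a metadata CSV.
#'
#' @param mares Data frame with `sample_id` and `haplotype` (and optionally
#'   `family`, `year`).
#' @param catalogue Named list of [mt_haplotype()]; every haplotype in
#'   `mares` must be present, and every motif must lie inside the D-loop
#'   interval.
#' @param ref A [reference_map()].
#' @param dir Optional output directory (writes `sequences.fasta`,
#'   `mares.csv`).
#' @return List with `sequences` (a named `DNAStringSet`) and `metadata`.
#' @export
emit_sequences <- function(mares, catalogue, ref = synthetic_mt_reference(),
                           dir = NULL) {
  stopifnot(all(c("sample_id", "haplotype") %in% names(mares)))
  miss <- setdiff(unique(mares$haplotype), names(catalogue))
  if (length(miss)) stop("haplotypes missing from catalogue: ",
                         paste(miss, collapse = ", "))
  dl <- ref$dloop_interval
  base_chars <- strsplit(substr(ref$sequence, dl[1], dl[2]), "")[[1]]
  rep_pos <- if (is.null(ref$repeat_interval)) integer(0)
             else .interval_seq(ref$repeat_interval)
  seq_for <- function(hname) {
    hap <- catalogue[[hname]]
    v <- hap$variants
    if (any(v$kind != "substitution")) {
      stop("only substitution motifs are supported by the emitter")
    }
    if (any(v$position < dl[1] | v$position > dl[2])) {
      stop("motif outside the D-loop interval")
    }
    chars <- base_chars
    chars[v$position - dl[1] + 1L] <- v$alt
    nd <- setdiff(.interval_seq(dl), c(hap$coverage, rep_pos))
    chars[nd - dl[1] + 1L] <- "N"
    paste(chars, collapse = "")
  }
  uniq <- unique(mares$haplotype)
  seq_by_hap <- setNames(vapply(uniq, seq_for, character(1)), uniq)
  seqs <- Biostrings::DNAStringSet(seq_by_hap[mares$haplotype])
  names(seqs) <- mares$sample_id
  meta <- data.frame(sample_id = mares$sample_id,
                     family = if ("family" %in% names(mares)) mares$family else NA,
                     year = if ("year" %in% names(mares)) mares$year else NA,
                     stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    Biostrings::writeXStringSet(seqs, file.path(dir, "sequences.fasta"))
    write.csv(meta, file.path(dir, "mares.csv"), row.names = FALSE)
  }
  list(sequences = seqs, metadata = meta)
}

#' Emit a stallion MSY genotype table
#'
#' Draws haplotype labels by exact quota (largest-remainder apportionment of
#' `n` across the proportions, so a stated composition like 8-of-10 is
#' reproduced deterministically), plants the defining diagnostic variant
#' state per the rule table, and shuffles sample order under the seed.
#'
#' @param n Number of stallions.
#' @param proportions Named proportions over `HT01`, `HT02`, `HT3`.
#' @param seed Mandatory integer seed (used only for the shuffle).
#' @param rules An [msy_rules()] table.
#' @return Data frame `sample_id`, `YE3`, `YE17`, `YXX`, `true_haplotype`.
#' @export
emit_msy <- function(n = 10L, proportions = c(HT01 = 0.2, HT02 = 0.8, HT3 = 0),
                     seed, rules = msy_rules()) {
  if (missing(seed)) stop("an explicit seed is required")
  stopifnot(abs(sum(proportions) - 1) < 1e-9, all(proportions >= 0))
  raw <- proportions * n
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac_order <- order(raw - counts, decreasing = TRUE)
    counts[frac_order[seq_len(rem)]] <- counts[frac_order[seq_len(rem)]] + 1
  }
  labels <- rep(names(counts), counts)
  .with_seed(seed, {
    labels <- labels[sample.int(length(labels))]
    states <- function(ht) {
      st <- c(YE3 = "reference", YE17 = "reference", YXX = "reference")
      if (ht == "HT02") st[[rules$ht2_locus]] <- "variant"
      if (ht == "HT3") st[[rules$ht3_locus]] <- "variant"
      st
    }
    m <- t(vapply(labels, states, character(3)))
    data.frame(sample_id = sprintf("ST%02d", seq_len(n)),
               YE3 = m[, "YE3"], YE17 = m[, "YE17"], YXX = m[, "YXX"],
               true_haplotype = labels,
               stringsAsFactors = FALSE, row.names = NULL)
  })
}
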