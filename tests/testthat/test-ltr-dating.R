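make_element <- function(id = "e1", age_sub = 0, n = 100,
                         domains = FULL_LENGTH_DOMAINS, family = "Athila") {
  s <- rand_dna(n)
  ltr_element(id, ltr5 = s, ltr3 = s, family = family,
              domains_present = domains)
}

test_that("full-length filter requires all five protein domains", {
  els <- list(make_element("all5"),
              make_element("no_int", domains = c("GAG", "RT", "RH", "AP")),
              make_element("none", domains = character()))
  kept <- filter_full_length(els)
  expect_identical(vapply(kept, `[[`, "", "element_id"), "all5")
  expect_identical(filter_full_length(list()), list())
})

test_that("substitution frequencies count compared sites with pairwise gap deletion", {
  set.seed(31)
  s <- rand_dna(100)
  fr <- substitution_frequencies(align_ltr_pair(c(s, s)))
  expect_identical(fr[c("p", "q", "n_sites")], list(p = 0, q = 0, n_sites = 100L))

  # plant 10 isolated transitions and 5 isolated transversions
  b <- strsplit(s, "")[[1]]
  ts_map <- c(A = "G", G = "A", C = "T", T = "C")
  tv_map <- c(A = "C", G = "T", C = "G", T = "A")
  ts_pos <- seq(3, 93, by = 10)
  tv_pos <- seq(7, 47, by = 10)
  b2 <- b
  b2[ts_pos] <- ts_map[b[ts_pos]]
  b2[tv_pos] <- tv_map[b[tv_pos]]
  fr2 <- substitution_frequencies(align_ltr_pair(c(s, paste(b2, collapse = ""))))
  expect_equal(fr2$p, 0.10)
  expect_equal(fr2$q, 0.05)
  expect_identical(fr2$n_sites, 100L)

  # 20 extra bases in one sequence: gap columns drop out of n_sites
  s_long <- paste0(s, rand_dna(20))
  fr3 <- substitution_frequencies(align_ltr_pair(c(s_long, s)))
  expect_identical(fr3$n_sites, 100L)
})

test_that("K2P distance matches the closed form and flags saturation", {
  expect_equal(k2p_distance(0, 0)$K, 0)
  expect_equal(k2p_distance(0.10, 0.05)$K, 0.1701812, tolerance = 1e-6)
  expect_true(k2p_distance(0.45, 0.10)$saturated)
  expect_true(k2p_distance(0.1, 0.5)$saturated)
  expect_false(k2p_distance(0.449, 0.10)$saturated)

  # strictly increasing in p and in q on the valid domain
  grid <- seq(0, 0.2, by = 0.02)
  for (q in c(0, 0.05, 0.1)) {
    Ks <- vapply(grid, function(p) k2p_distance(p, q)$K, numeric(1))
    expect_true(all(diff(Ks) > 0))
  }
  for (p in c(0, 0.05, 0.1)) {
    Ks <- vapply(grid, function(q) k2p_distance(p, q)$K, numeric(1))
    expect_true(all(diff(Ks) > 0))
  }
})

test_that("insertion time is K/2r with strict-recency classification at the boundary", {
  it0 <- insertion_time(0)
  expect_equal(it0$T_years, 0)
  expect_true(it0$recent)

  # K = 0.013 at the default rate sits exactly on the 0.5 My boundary: old
  it <- insertion_time(0.013, rate_r = 1.3e-8)
  expect_equal(it$T_years, 5e5, tolerance = 1e-9)
  expect_false(it$recent)

  # doubling the rate halves the age
  for (K in c(0.001, 0.02, 0.1)) {
    expect_equal(insertion_time(K, rate_r = 2.6e-8)$T_years,
                 insertion_time(K, rate_r = 1.3e-8)$T_years / 2)
  }
  expect_error(insertion_time(0.01, rate_r = 0), "rate_r")
})

test_that("dating recovers planted ages from simulated LTR pairs", {
  # 200 replicate pairs of 1 kb at K_true = 0.05: mean K-hat within 3 SE
  K_true <- 0.05
  n_rep <- 200; len <- 1000
  Khat <- numeric(n_rep)
  set.seed(55)
  anc <- replicate(n_rep, rand_dna(len))
  for (i in seq_len(n_rep)) {
    spec1 <- evolution_spec(rate_r = 1e-8, age_years = K_true / 2 / 1e-8,
                            seed = 2 * i)
    spec2 <- evolution_spec(rate_r = 1e-8, age_years = K_true / 2 / 1e-8,
                            seed = 2 * i + 1)
    aln <- align_ltr_pair(c(mutate_sequence_k2p(anc[i], spec1),
                            mutate_sequence_k2p(anc[i], spec2)))
    fr <- substitution_frequencies(aln)
    Khat[i] <- k2p_distance(fr$p, fr$q)$K
  }
  se <- sd(Khat) / sqrt(n_rep)
  expect_lt(abs(mean(Khat) - K_true), 3 * se)
})

test_that("recency contingency tabulates per-genome recent/old counts", {
  tab <- recency_contingency(c(TRUE, TRUE, FALSE, FALSE),
                             c(TRUE, FALSE, FALSE, FALSE))
  expect_identical(unclass(unname(tab)),
                   matrix(c(2L, 2L, 1L, 3L), 2, byrow = TRUE))
  tab2 <- recency_contingency(c(TRUE, TRUE), c(TRUE))
  expect_identical(unname(tab2[, "old"]), c(0L, 0L))
  expect_error(recency_contingency(logical(0), TRUE), "at least one")

  # simulated libraries at the planted fractions: cells within 3 binomial SE
  set.seed(77)
  n <- 3834
  rec_a <- runif(n) < 0.266
  rec_b <- runif(n) < 0.096
  tab3 <- recency_contingency(rec_a, rec_b)
  expect_lt(abs(tab3[1, "recent"] - n * 0.266), 3 * sqrt(n * 0.266 * 0.734))
  expect_lt(abs(tab3[2, "recent"] - n * 0.096), 3 * sqrt(n * 0.096 * 0.904))
})

test_that("exact Fisher test matches brute-force enumeration and is symmetric", {
  expect_equal(fisher_exact(matrix(5, 2, 2)), 1)

  tab <- matrix(c(1, 11, 9, 3), 2, 2)   # [[1,9],[11,3]]
  expect_equal(fisher_exact(tab), fisher_brute(tab), tolerance = 1e-10)
  expect_equal(fisher_exact(tab), 0.002759456, tolerance = 1e-6)

  set.seed(41)
  for (case in 1:25) {
    tab <- matrix(rpois(4, 6) + 1, 2, 2)
    p <- fisher_exact(tab)
    expect_gt(p, 0); expect_lte(p, 1)
    expect_equal(p, fisher_exact(tab[2:1, ]), tolerance = 1e-12)
    expect_equal(p, fisher_exact(t(tab)), tolerance = 1e-12)
    # independent library route
    expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-7)
  }
  expect_error(fisher_exact(matrix(c(-1, 2, 3, 4), 2, 2)), "negative")
  expect_error(fisher_exact(matrix(c(0, 0, 3, 4), 2, 2)), "margins")
})

test_that("family copy summary reproduces fold ratios and fractions", {
  fams_a <- c(rep("Athila", 6117), rep("Tekay", 1000))
  fams_b <- c(rep("Athila", 241), rep("Tekay", 3000))
  out <- family_copy_summary(fams_a, fams_b)
  ath <- out[out$family == "Athila", ]
  expect_identical(round(ath$fold_ratio), 25)
  expect_equal(sum(out$fraction_a), 1)
  expect_equal(sum(out$fraction_b), 1)

  out2 <- family_copy_summary(c("Ale", "Ale"), character(0))
  expect_true(is.na(out2$fold_ratio))
  expect_false("CRM" %in% out2$family)
})

test_that("cumulative age curves are monotone CDF estimates", {
  grid <- seq(0, 2e6, by = 1e5)
  curve <- cumulative_age_curve(rep(7e5, 10), grid)
  expect_identical(unique(curve$cumulative_fraction[curve$age_years < 7e5]), 0)
  expect_identical(unique(curve$cumulative_fraction[curve$age_years >= 7e5]), 1)

  set.seed(13)
  ages <- runif(2000, 0, 2e6)
  curve2 <- cumulative_age_curve(ages, grid)
  expect_true(all(diff(curve2$cumulative_fraction) >= 0))
  expect_equal(curve2$cumulative_fraction[length(grid)], 1)
  for (i in seq_along(grid)) {
    expected <- grid[i] / 2e6
    se <- sqrt(max(expected * (1 - expected), 1e-12) / 2000)
    expect_lte(abs(curve2$cumulative_fraction[i] - expected),
               3 * se + 1e-12)
  }
  expect_error(cumulative_age_curve(numeric(0), grid), "no dated")
})

test_that("repeat fractions are renormalized after organelle removal", {
  tab <- data.frame(cluster = c("c1", "c2", "c3"),
                    annotation = c("Athila", "plastid", "Athila"),
                    reads = c(80, 200, 40),
                    organelle = c(FALSE, TRUE, FALSE))
  out <- repeat_fraction_renormalize(tab, total_reads = 1000)
  expect_equal(out$genome_fraction[out$annotation == "Athila"],
               120 / 800)
  expect_lte(sum(out$genome_fraction), 1)

  # no organelle clusters: fractions unchanged
  tab2 <- tab; tab2$organelle <- FALSE
  out2 <- repeat_fraction_renormalize(tab2, total_reads = 1000)
  expect_equal(out2$genome_fraction[out2$annotation == "Athila"], 120 / 1000)

  tab3 <- data.frame(cluster = "c1", annotation = "plastid", reads = 10,
                     organelle = TRUE)
  expect_error(repeat_fraction_renormalize(tab3, total_reads = 10), "all reads")
})

test_that("the dating pipeline is deterministic end to end", {
  lib <- simulate_ltr_library(20, ltr_length = 400, internal_length = 60,
                              spacer = 20, seed = 8)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_ltr_library(lib, d1)
  r1 <- date_ltrs(file.path(d1, "elements.gff3"),
                  file.path(d1, "genome.fasta"), out_dir = file.path(d1, "o"))
  r2 <- date_ltrs(file.path(d1, "elements.gff3"),
                  file.path(d1, "genome.fasta"), out_dir = file.path(d2, "o"))
  for (f in c("element_ages.tsv", "family_summary.tsv",
              "cumulative_ages.tsv")) {
    expect_identical(readLines(file.path(d1, "o", f)),
                     readLines(file.path(d2, "o", f)))
  }
  # estimated ages correlate with planted truth
  merged <- merge(r1$elements, lib$truth, by = "element_id")
  expect_gt(cor(merged$T_years, merged$true_age_years), 0.9)
})
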