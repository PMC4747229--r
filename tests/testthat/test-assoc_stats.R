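test_that("Fisher exact reproduces printed group comparisons and degenerate cases", {
  # PTEN: 8 of 29 MSI-H vs 3 of 113 MSS
  expect_lt(fisher_two_sided(8, 21, 3, 110)$p_value, 0.001)
  # identical groups carry no signal
  expect_warning(res <- fisher_two_sided(0, 10, 0, 10), "degenerate")
  expect_equal(res$p_value, 1)
  # transposition and simultaneous row/column swap leave p unchanged
  tab <- matrix(c(9, 20, 2, 111), 2, byrow = TRUE)
  p <- fisher_two_sided(tab)$p_value
  expect_equal(fisher_two_sided(t(tab))$p_value, p)
  expect_equal(fisher_two_sided(tab[2:1, 2:1])$p_value, p)
})

test_that("Fisher matches the independent reference implementation on assorted tables", {
  set.seed(7)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 8) + 1, 2)
    expect_equal(fisher_two_sided(tab)$p_value,
                 stats::fisher.test(tab)$p.value,
                 tolerance = 1e-10)
  }
})

test_that("Fisher equals the enumeration oracle on a lattice of small-table margins", {
  for (r1 in c(1, 2, 5, 9, 14)) {
    for (r2 in c(1, 4, 7, 13)) {
      n <- r1 + r2
      for (c1 in seq_len(n - 1)) {
        sup <- oracle_fisher_support(r1, r2, c1)
        for (a in sup$x) {
          p_oracle <- min(1, sum(sup$probs[
            sup$probs <= sup$probs[sup$x == a] * (1 + 1e-7)]))
          p_impl <- fisher_two_sided(a, r1 - a, c1 - a, r2 - c1 + a)$p_value
          if (abs(p_impl - p_oracle) > 1e-9) {
            fail(sprintf("mismatch at a=%d b=%d c=%d d=%d: %.12f vs %.12f",
                         a, r1 - a, c1 - a, r2 - c1 + a, p_impl, p_oracle))
          }
        }
      }
    }
  }
  succeed()
})

test_that("chi-square matches the closed-form 2x2 statistic and printed bounds", {
  # identical row proportions: statistic 0, p 1
  even <- chi_square_2x2(matrix(c(5, 10, 10, 20), 2, byrow = TRUE))
  expect_equal(even$statistic, 0)
  expect_equal(even$p_value, 1)
  # mTOR pathway membership table
  expect_lt(chi_square_2x2(matrix(c(17, 12, 20, 93), 2,
                                  byrow = TRUE))$p_value, 0.001)
  # textbook closed form n(ad-bc)^2 / (r1 r2 c1 c2)
  set.seed(21)
  for (i in 1:50) {
    m <- matrix(rpois(4, 6) + 1, 2)
    a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
    n <- sum(m)
    stat <- n * (a * d - b * c)^2 /
      ((a + b) * (c + d) * (a + c) * (b + d))
    res <- chi_square_2x2(m)
    expect_equal(res$statistic, stat, tolerance = 1e-12)
    expect_equal(res$p_value, stats::pchisq(stat, 1, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
  expect_warning(deg <- chi_square_2x2(matrix(c(0, 0, 3, 4), 2)),
                 "degenerate")
  expect_equal(deg$p_value, 1)
})

test_that("Fisher and chi-square agree asymptotically in the significance tail", {
  # the exact and asymptotic p-values track each other closely where it
  # matters: well-filled tables (expected cells >= 10) whose p reaches the
  # 0.01 tail; at mid-range p the two conventions legitimately differ by
  # several percent even at these cell sizes
  set.seed(31)
  n_tail <- 0L
  for (i in 1:5000) {
    m <- matrix(rpois(4, 40) + 10, 2)
    e <- outer(rowSums(m), colSums(m)) / sum(m)
    if (!all(e >= 10)) next
    pf <- fisher_two_sided(m)$p_value
    pc <- chi_square_2x2(m)$p_value
    if (min(pf, pc) > 0.01) next
    n_tail <- n_tail + 1L
    expect_lt(abs(pf - pc), 0.01)
  }
  expect_gt(n_tail, 10L)
})

test_that("pooled t-test matches the closed form and handles degenerate variance", {
  x <- c(1, 2, 3)
  y <- c(2, 4, 9)
  sp2 <- (2 * stats::var(x) + 2 * stats::var(y)) / 4
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  p <- 2 * stats::pt(-abs(tstat), df = 4)
  res <- two_sample_t(x, y)
  expect_equal(res$statistic, tstat, tolerance = 1e-12)
  expect_equal(res$p_value, p, tolerance = 1e-12)

  expect_equal(two_sample_t(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_warning(r1 <- two_sample_t(c(2, 2), c(2, 2)), "equal means")
  expect_equal(r1$p_value, 1)
  expect_warning(r0 <- two_sample_t(c(2, 2), c(3, 3)), "unequal means")
  expect_equal(r0$p_value, 0)
  expect_error(two_sample_t(1, c(1, 2)), "at least 2")
})

test_that("burden-scale group separation is detected at the reference effect size", {
  # NB draws at the reference means/SDs, n = 113 vs 29; the pooled t is ~3.6
  # so p < 0.001 sits near the median replicate and p < 0.05 is near-certain
  set.seed(1234)
  nb <- function(n, m, s) rnbinom(n, size = m^2 / (s^2 - m), mu = m)
  ps <- replicate(200, {
    two_sample_t(nb(113, 2.4, 1.6), nb(29, 3.7, 2.2))$p_value
  })
  expect_lt(median(ps), 0.001)
  expect_gte(mean(ps < 0.05), 0.85)
})

test_that("gene frequency table counts tumors once per set and reproduces printed tables", {
  sim <- generate_cohort(simulation_params(seed = 8))
  coh <- sim$cohort
  gf <- gene_frequency_table(coh)
  expect_true(all(gf$mss_mutated <= gf$mss_total))
  expect_true(all(gf$msih_mutated <= gf$msih_total))
  expect_true(all(gf$p_value >= 0 & gf$p_value <= 1))

  # tumor-level counting: multiplicity within a tumor counts once,
  # verified against brute-force per-tumor membership
  muts <- coh$mutations
  status <- coh$samples$msi_status[match(muts$tumor_id, coh$samples$tumor_id)]
  for (nm in c("PTEN", "mTOR", "RTK")) {
    genes <- default_gene_sets()[[nm]]
    brute_mss <- length(unique(muts$tumor_id[muts$gene %in% genes &
                                               status == "MSS"]))
    expect_equal(gf$mss_mutated[gf$name == nm], brute_mss)
  }

  # a fixture built to the printed PIK3CA proportions yields the printed table
  mss_flags <- c(rep(1L, 17), rep(0L, 96))
  msih_flags <- c(rep(1L, 10), rep(0L, 19))
  rows <- tibble::tibble(
    tumor_id = c(sprintf("S%03d", which(mss_flags == 1)),
                 sprintf("H%03d", which(msih_flags == 1))),
    gene = "PIK3CA",
    hgvs_c = "c.3140A>G",
    variant_class = "substitution"
  )
  samples <- tibble::tibble(
    tumor_id = c(sprintf("S%03d", 1:113), sprintf("H%03d", 1:29)),
    msi_status = c(rep("MSS", 113), rep("MSI_H", 29))
  )
  fix <- cohort(rows, samples = samples)
  gfx <- gene_frequency_table(fix, gene_sets = list(PIK3CA = "PIK3CA"))
  expect_equal(unname(gfx$table[[1]]),
               matrix(c(10, 19, 17, 96), 2, byrow = TRUE))
  expect_equal(gfx$mss_pct, 15)
  expect_equal(gfx$msih_pct, 34)

  expect_error(gene_frequency_table(fix, gene_sets = list(x = "NOT_A_GENE")),
               "config error")
})

test_that("repeat-indel tallies conserve totals and handle indel-free groups", {
  sim <- generate_cohort(simulation_params(seed = 13))
  ann <- annotate_cohort_repeats(sim$cohort, sim$references)
  tab <- indel_repeat_table(sim$cohort, ann)
  tot <- tab[tab$gene == "Total", ]
  per_gene <- tab[tab$gene != "Total", ]
  expect_equal(sum(per_gene$mss_indels), tot$mss_indels)
  expect_equal(sum(per_gene$msih_indels), tot$msih_indels)
  expect_equal(sum(per_gene$mss_repeat_indels), tot$mss_repeat_indels)
  expect_equal(sum(per_gene$msih_repeat_indels), tot$msih_repeat_indels)

  # group with no indels: zero per-tumor rate, not-evaluable ratio
  no_indel <- make_labeled_cohort(c(1L, 1L), c(1L, 1L))
  ann0 <- annotate_cohort_repeats(no_indel, reference_fixtures("ATM"))
  tab0 <- indel_repeat_table(no_indel, ann0)
  expect_equal(tab0$mss_per_tumor[tab0$gene == "Total"], 0)
  expect_true(is.na(tab0$mss_ratio[tab0$gene == "Total"]))
})
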