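# brute-force upper tail by pmf summation, the small-n oracle
brute_tail <- function(s, n, p) {
  if (s == 0L) return(1)
  sum(vapply(s:n, function(k) choose(n, k) * p^k * (1 - p)^(n - k), numeric(1)))
}

test_that("chance decoy-match probability is unique decoy matches over unique spectra", {
  r <- tiny_records()   # 3 spectra, 1 decoy PSM-site
  expect_equal(estimate_random_match_prob(r), 1 / 3)

  no_dec <- make_records(psm_rows("p1", "STYK", 1, 0.5),
                         psm_rows("p2", "STYK", 2, 0.5))
  expect_equal(estimate_random_match_prob(no_dec), 0)

  all_dec <- make_records(psm_rows("p1", "AAVK", 1, 0.5),
                          psm_rows("p2", "AAVK", 2, 0.5))
  expect_equal(estimate_random_match_prob(all_dec), 1)
  expect_error(estimate_random_match_prob(no_dec[0, ]), "empty")
})

test_that("site observation counts use PSM coverage by protein coordinate", {
  # position 11 phosphorylated in 3 of 4 covering PSMs
  r <- make_records(
    psm_rows("p1", "SSTAYK", 1, 0.9),
    psm_rows("p2", "SSTAYK", 1, 0.8),
    psm_rows("p3", "SSTAYK", 1, 0.7),
    psm_rows("p4", "SSTAYK", 3, 0.6)
  )
  cnt <- site_observation_counts(r)
  row11 <- cnt[cnt$protein_pos == 11, ]
  expect_equal(row11$s, 3L)
  expect_equal(row11$n, 4L)

  # two different peptidoforms covering the same protein position: s unions
  r2 <- make_records(
    psm_rows("p1", "SSTAYK", 3, 0.9),                       # pos 13
    psm_rows("p2", "SSTAYK", 3, 0.8),
    psm_rows("p3", "TAYKLL", 1, 0.7, protein_start = 13),   # same protein pos
    psm_rows("p4", "TAYKLL", 1, 0.7, protein_start = 13),
    psm_rows("p5", "TAYKLL", 1, 0.6, protein_start = 13)
  )
  cnt2 <- site_observation_counts(r2)
  expect_equal(cnt2$s[cnt2$protein_pos == 13], 5L)

  # explicit coverage table adds unphosphorylated PSMs to n
  cov <- data.frame(psm_id = paste0("c", 1:7), peptide = "SSTAYK",
                    protein = "P1", protein_start = 11)
  cnt3 <- site_observation_counts(r, coverage = cov)
  expect_equal(cnt3$n[cnt3$protein_pos == 11], 7L)

  # a phospho observation outside all coverage is inconsistent
  cov_bad <- cov[1, ]
  cov_bad$protein_start <- 500
  expect_error(site_observation_counts(r, coverage = cov_bad), "inconsistent")
})

test_that("binomial penalty is the survival-function upper tail", {
  expect_equal(binomial_penalty(1, 100, 0.02), 1 - 0.98^100)
  expect_equal(binomial_penalty(0, 57, 0.3), 1)
  expect_equal(binomial_penalty(3, 3, 0.1), 0.1^3)
  expect_error(binomial_penalty(4, 3, 0.1), "s <= n")
  expect_error(binomial_penalty(1, 3, 1.3), "p must")
  # pmf variant
  expect_equal(binomial_penalty(2, 5, 0.2, mode = "pmf"), dbinom(2, 5, 0.2))
  # numerically sane at large n
  expect_true(binomial_penalty(1, 1e5, 1e-6) > 0)
  expect_lt(binomial_penalty(90000, 1e5, 0.5), 1e-100)
})

test_that("penalty matches brute-force pmf summation and is monotone", {
  for (p in c(0.001, 0.05, 0.3)) {
    for (n in c(1, 4, 9)) {
      for (s in 0:n) {
        expect_equal(binomial_penalty(s, n, p), brute_tail(s, n, p),
                     tolerance = 1e-12)
      }
    }
  }
  # (1 - P_s) non-decreasing in s at fixed n, p
  pen <- binomial_penalty(0:10, 10, 0.1)
  expect_true(all(diff(1 - pen) >= -1e-12))
  # P_s non-decreasing in n at fixed s >= 1
  tail_n <- vapply(2:40, function(n) binomial_penalty(2, n, 0.1), numeric(1))
  expect_true(all(diff(tail_n) >= -1e-12))
})

test_that("score adjustment multiplies by one minus the penalty", {
  r <- make_records(
    psm_rows("p1", "SSTAYK", 1, 0.95),
    psm_rows("p2", "SSTAYK", 4, 0.5)
  )
  ctx <- build_binomial_context(r)
  expect_equal(ctx$p, 0.5)           # 1 decoy match over 2 spectra
  adj <- adjust_scores(r, ctx)
  expect_equal(adj$score_adj, adj$final_score * (1 - adj$p_s))
  expect_true(all(adj$score_adj <= adj$final_score + 1e-12))

  # no decoy matches anywhere: p = 0, every site keeps its score
  r0 <- make_records(psm_rows("p1", "STYK", 1, 0.9),
                     psm_rows("p2", "STYK", 2, 0.4))
  adj0 <- adjust_scores(r0, build_binomial_context(r0))
  expect_equal(adj0$score_adj, adj0$final_score)

  # unknown site in context is a consistency error
  ctx2 <- ctx
  ctx2$counts <- ctx2$counts[ctx2$counts$protein_pos != 11, ]
  expect_error(adjust_scores(r, ctx2), "not present")
})

test_that("adjustment penalises rarely observed sites more heavily", {
  sim <- default_fixture()
  adj <- adjust_scores(sim$records, build_binomial_context(sim$records))
  expect_true(all(adj$score_adj <= adj$final_score + 1e-12))
  # the penalty factor grows with s at equal coverage
  cnt <- site_observation_counts(sim$records)
  cnt$p_s <- binomial_penalty(cnt$s, cnt$n, estimate_random_match_prob(sim$records))
  by_n <- split(cnt, cnt$n)
  for (grp in by_n[vapply(by_n, nrow, integer(1)) > 2]) {
    o <- order(grp$s)
    expect_true(all(diff(grp$p_s[o]) <= 1e-12) ||
                  !is.unsorted(rev(grp$p_s[o]), strictly = FALSE))
  }
})
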