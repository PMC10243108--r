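# naive per-group recomputations used as oracles
naive_max <- function(v) max(v)
naive_mean <- function(v) mean(v)
naive_product <- function(v) 1 - prod(1 - v)

test_that("max collapse keeps the best score per peptidoform site", {
  r <- make_records(
    psm_rows("p1", "SSTAYK", 1, 0.7),
    psm_rows("p2", "SSTAYK", 1, 0.97),
    psm_rows("p3", "SSTAYK", 1, 0.4)
  )
  out <- collapse_psm_sites(r, "max")
  expect_equal(nrow(out), 1L)
  expect_equal(out$collapsed_score, 0.97)
  expect_equal(out$psm_support, 3L)

  single <- collapse_psm_sites(make_records(psm_rows("p1", "STYK", 1, 0.66)), "max")
  expect_equal(single$collapsed_score, 0.66)
  expect_equal(single$psm_support, 1L)
})

test_that("per-site maxima may come from different PSMs of one peptidoform", {
  r <- make_records(
    psm_rows("p1", "SSTAYK", c(1, 3), c(0.9, 0.5)),
    psm_rows("p2", "SSTAYK", c(1, 3), c(0.6, 0.8))
  )
  out <- collapse_psm_sites(r, "max")
  expect_equal(out$collapsed_score[out$site_pos == 1], 0.9)
  expect_equal(out$collapsed_score[out$site_pos == 3], 0.8)
})

test_that("mean collapse averages and never exceeds max", {
  r <- make_records(
    psm_rows("p1", "SSTAYK", 1, 0.8),
    psm_rows("p2", "SSTAYK", 1, 0.6)
  )
  expect_equal(collapse_psm_sites(r, "mean")$collapsed_score, 0.7)
  sim <- default_fixture()
  mx <- collapse_psm_sites(sim$records, "max")
  mn <- collapse_psm_sites(sim$records, "mean")
  key <- function(d) paste(d$peptidoform_key, d$site_pos)
  expect_true(all(mn$collapsed_score[match(key(mx), key(mn))] <=
                    mx$collapsed_score + 1e-12))
})

test_that("mm collapse assigns the best PSM's mean to all its sites", {
  r <- make_records(
    psm_rows("p1", "SSTAYK", c(1, 3), c(0.9, 0.5)),   # mean 0.7
    psm_rows("p2", "SSTAYK", c(1, 3), c(0.85, 0.75))  # mean 0.8 -> representative
  )
  out <- collapse_psm_sites(r, "mm")
  expect_equal(out$collapsed_score, c(0.8, 0.8))
  # variant: keep the site's own score from the representative PSM
  out2 <- collapse_psm_sites(r, "mm", mm_assign = "site_score")
  expect_equal(out2$collapsed_score[out2$site_pos == 1], 0.85)
  expect_equal(out2$collapsed_score[out2$site_pos == 3], 0.75)

  one <- collapse_psm_sites(make_records(psm_rows("p1", "STYK", 1, 0.4)), "mm")
  expect_equal(one$collapsed_score, 0.4)

  # all PSMs identical scores: mm equals max
  r3 <- make_records(
    psm_rows("p1", "SSTAYK", 1, 0.5),
    psm_rows("p2", "SSTAYK", 1, 0.5)
  )
  expect_equal(collapse_psm_sites(r3, "mm")$collapsed_score,
               collapse_psm_sites(r3, "max")$collapsed_score)
})

test_that("product collapse accumulates evidence and dominates max", {
  r <- make_records(
    psm_rows("p1", "SSTAYK", 1, 0.9),
    psm_rows("p2", "SSTAYK", 1, 0.8)
  )
  expect_equal(collapse_psm_sites(r, "product")$collapsed_score, 0.98)
  sim <- default_fixture()
  mx <- collapse_psm_sites(sim$records, "max")
  pr <- collapse_psm_sites(sim$records, "product")
  key <- function(d) paste(d$peptidoform_key, d$site_pos)
  expect_true(all(pr$collapsed_score[match(key(mx), key(pr))] >=
                    mx$collapsed_score - 1e-12))
})

test_that("collapse propagates support counts and conservative decoy flags", {
  r <- tiny_records()
  out <- collapse_psm_sites(r, "max")
  # grouped per (peptidoform, site): ps1/ps3 share the no-mod... distinct keys
  expect_true(all(out$psm_support >= 1L))
  expect_lte(nrow(out), nrow(r))
  # the peptidoform containing the decoy PSM carries the flag on all its sites
  dec_forms <- unique(out$peptidoform_key[out$is_decoy_site])
  expect_true(all(out$decoy_flag[out$peptidoform_key %in% dec_forms]))
})

test_that("protein-site collapse uniquifies positions by maximum", {
  pf <- collapse_psm_sites(make_records(
    psm_rows("p1", "SSTAYK", 1, 0.91),
    psm_rows("p2", "KSSTAYK", 2, 0.99, protein_start = 10)
  ), "max")
  ps <- collapse_protein_sites(pf)
  expect_equal(nrow(ps), 1L)
  expect_equal(ps$collapsed_score, 0.99)
  expect_equal(ps$pform_support, 2L)

  pf2 <- collapse_psm_sites(make_records(
    psm_rows("p1", "SSTAYK", 1, 0.5),
    psm_rows("p2", "SSTAYK", 3, 0.6)
  ), "max")
  expect_equal(nrow(collapse_protein_sites(pf2)), 2L)
})

test_that("all four methods equal naive recomputation on random groups", {
  set.seed(7)
  for (rep in 1:20) {
    k <- sample(1:6, 1)
    scores <- round(runif(k), 3)
    rows <- lapply(seq_len(k), function(i)
      psm_rows(paste0("p", i), "SSTAYK", 1, scores[i]))
    r <- do.call(make_records, rows)
    expect_equal(collapse_psm_sites(r, "max")$collapsed_score, naive_max(scores))
    expect_equal(collapse_psm_sites(r, "mean")$collapsed_score, naive_mean(scores))
    expect_equal(collapse_psm_sites(r, "product")$collapsed_score,
                 naive_product(scores))
    # single-site PSMs: mm reduces to max of per-PSM scores
    expect_equal(collapse_psm_sites(r, "mm")$collapsed_score, naive_max(scores))
  }
})
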