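test_that("oligomer construction honors end type, parity and composition", {
  expect_equal(build_oligomer(oligomer_pool("diol", discrete_dp = 1)), "G")
  expect_equal(
    build_oligomer(oligomer_pool("diacid", discrete_dp = 5, u_fraction = 0)),
    "SGSGS"
  )
  expect_error(oligomer_pool("diacid", discrete_dp = 4), "odd")
  expect_error(oligomer_pool("diacid"), "exactly one")
  expect_error(oligomer_pool("diacid", mean_dp = 5, discrete_dp = 5), "exactly one")

  withr::with_seed(11, {
    for (pool in list(
      oligomer_pool("diacid", mean_dp = 5, u_fraction = 0.5),
      oligomer_pool("diol", mean_dp = 10, u_fraction = 0.3),
      oligomer_pool("diacid", discrete_dp = 7, u_fraction = 1),
      oligomer_pool("diol", discrete_dp = 11, u_fraction = 0.1)
    )) {
      seqs <- build_oligomer(pool, 300)
      len <- nchar(seqs)
      expect_true(all(len %% 2L == 1L))
      expect_false(any(grepl("GG|[SU][SU]", seqs)))
      n_b <- len - nchar(gsub("[SU]", "", seqs))
      if (pool$end_type == "diacid") {
        expect_true(all(substr(seqs, 1, 1) != "G" & substr(seqs, len, len) != "G"))
        expect_equal(n_b, (len + 1L) %/% 2L)
      } else {
        expect_true(all(substr(seqs, 1, 1) == "G" & substr(seqs, len, len) == "G"))
        expect_equal(n_b, (len - 1L) %/% 2L)
      }
    }
  })
})

test_that("disperse oligomer lengths hit the targeted mean DP and B count", {
  withr::with_seed(5, {
    seqs <- build_oligomer(oligomer_pool("diacid", mean_dp = 5, u_fraction = 0.5), 1e5)
    len <- nchar(seqs)
    expect_equal(mean(len), 5, tolerance = 0.05 / 5)
    expect_equal(mean((len + 1) / 2), 3, tolerance = 0.03 / 3)
  })
})

test_that("oligomer junctions preserve strict A/B alternation", {
  withr::with_seed(13, {
    acid <- build_oligomer(oligomer_pool("diacid", mean_dp = 5, u_fraction = 0.5), 200)
    diol <- build_oligomer(oligomer_pool("diol", mean_dp = 10, u_fraction = 0.2), 200)
    joined <- paste0(acid, diol) # diacid ends B, diol starts A
    expect_false(any(grepl("GG|[SU][SU]", joined)))
    joined2 <- paste0(diol, acid)
    expect_false(any(grepl("GG|[SU][SU]", joined2)))
  })
})

test_that("assembled ensembles are valid, reproducible, and obey the chain-length law", {
  spec <- test_spec(n_chains = 500, seed = 42)
  ens <- simulate_ensemble(spec)
  expect_s3_class(ens, "copolymer_ensemble")
  expect_equal(nrow(ens), 500)
  expect_false(any(grepl("GG|[SU][SU]", ens$sequence)))
  expect_equal(nchar(ens$sequence), ens$n_monomers)

  ens2 <- simulate_ensemble(spec)
  expect_identical(ens$sequence, ens2$sequence)

  # single-oligomer chains are unchanged oligomers of the starting pool
  singles <- ens[ens$n_oligomers == 1, ]
  acid_singles <- singles[singles$starts_with == "diacid", ]
  expect_true(all(substr(acid_singles$sequence, 1, 1) != "G"))
  expect_true(all(nchar(singles$sequence) %% 2 == 1))

  expect_error(copolymer_spec(spec$acid_pool, spec$diol_pool, 0.9, 0, seed = 1),
               "positive integer")
  expect_error(copolymer_spec(spec$acid_pool, spec$diol_pool, 0.9, 10),
               "seed")
})

test_that("chain means match the closed forms: 10 oligomers and 75 monomers per chain", {
  spec <- test_spec(n_chains = 1e5, seed = 7)
  ens <- simulate_ensemble(spec)
  expect_equal(mean(ens$n_oligomers), 10, tolerance = 0.1 / 10)
  expect_equal(mean(ens$n_monomers), 75, tolerance = 0.5 / 75)
  # U content: 5 diacid oligomers per chain x 3 B positions x 0.5
  expect_equal(mean(count_u(ens$sequence)), 7.5, tolerance = 0.1 / 7.5)
})

test_that("chain-length histograms conserve chains and match the coupling law", {
  spec <- test_spec(n_chains = 2e4, seed = 19)
  ens <- simulate_ensemble(spec)
  h_m <- chain_length_histogram(ens, "monomers")
  h_o <- chain_length_histogram(ens, "oligomers")
  expect_equal(sum(h_m$n), nrow(ens))
  expect_equal(sum(h_o$n), nrow(ens))

  cap <- 45 # pool the tail so expected counts stay above ~5
  obs <- tabulate(factor(pmin(ens$n_oligomers, cap), levels = 1:cap))
  prob <- flory_pmf(1:cap, 0.9)
  prob[cap] <- 1 - sum(prob[-cap])
  expect_gt(stats::chisq.test(obs, p = prob)$p.value, 0.01)

  # excess of odd- over even-length chains at low monomer counts
  low <- h_m[h_m$length <= 15, ]
  expect_gt(sum(low$n[low$length %% 2 == 1]), sum(low$n[low$length %% 2 == 0]))
})

test_that("random analog spec places the overall U fraction in both pools", {
  spec <- random_analog_spec(0.2, 5, 10, p = 0.9, n_chains = 10, seed = 1)
  expect_equal(spec$acid_pool$u_fraction, 0.2)
  expect_equal(spec$diol_pool$u_fraction, 0.2)
  expect_equal(random_analog_spec(0, 5, 10, 0.9, 10, 1)$acid_pool$u_fraction, 0)
  expect_equal(random_analog_spec(1, 5, 10, 0.9, 10, 1)$diol_pool$u_fraction, 1)
})
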