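test_that("block-length averages match hand-computed values", {
  expect_equal(number_average(2, 3), 2)
  expect_equal(number_average(c(1, 3)), 2)
  expect_equal(length_weighted_average(2, 3), 2)
  expect_equal(length_weighted_average(c(1, 3)), 2.5)
  expect_equal(dispersity(c(1, 3)), 1.25)
  expect_equal(dispersity(rep(7, 10)), 1)

  # zero-length stubs enter the number average only
  expect_equal(number_average(c(0, 2), c(1, 1)), 1)
  expect_equal(length_weighted_average(c(0, 2), c(1, 1)), 2)

  expect_error(number_average(numeric()), "Empty")
  expect_error(length_weighted_average(c(0, 0)), "undefined")
  expect_error(dispersity(c(0, 0)), "undefined")
})

test_that("length-weighted average dominates the number average (dispersity >= 1)", {
  withr::with_seed(2, {
    for (i in 1:50) {
      lengths <- sample(0:30, sample(2:12, 1))
      counts <- sample(1:50, length(lengths), replace = TRUE)
      if (sum(lengths * counts) == 0) next
      expect_gte(
        length_weighted_average(lengths, counts) + 1e-12,
        number_average(lengths, counts)
      )
      expect_gte(dispersity(lengths, counts) + 1e-12, 1)
    }
  })
})

test_that("repeat-unit summaries are half the monomer-scale ones, same dispersity", {
  res <- simulate_digest(test_spec(f_acid = 0.35, f_diol = 0.1, n_chains = 3000))
  s_m <- summarize_digest(res, scale = "monomer")
  s_r <- summarize_digest(res, scale = "repeat_unit")
  expect_equal(s_r$dp_n, s_m$dp_n / 2)
  expect_equal(s_r$dp_l, s_m$dp_l / 2)
  expect_equal(s_r$dispersity, s_m$dispersity)
  expect_equal(s_r$n_fragments, res$n_chains + res$n_cleavages)
})

test_that("histograms follow the binning rule and the length weighting", {
  # fragments m = {2, 3, 3} all fall in repeat-unit bin 1
  res <- coposeq:::new_digest_result(
    counts = tibble::tibble(
      monomer_count = c(2L, 3L), origin = c("end", "internal"),
      count = c(1L, 2L)
    ),
    n_chains = 1, n_cleavages = 2, total_monomers_pre = 10
  )
  h <- digest_histogram(res, scale = "repeat_unit")
  expect_equal(h$length, 1L)
  expect_equal(h$n, 3L)
  expect_equal(h$n_l, 3L) # (N_l)_i = DP_i * N_i on the reported scale

  h_m <- digest_histogram(res, scale = "monomer", weighting = "length")
  expect_equal(h_m$n_l, h_m$length * h_m$n)
  expect_equal(sum(h_m$n), 3L)
})

test_that("SEC-like export drops sub-repeat-unit fragments and normalizes traces", {
  ps <- simulate_digest(test_spec(f_acid = 0.5, f_diol = 0, n_chains = 5000, seed = 3))
  tr <- sec_like_export(ps)
  expect_true(all(tr$size >= 1))
  expect_equal(tr$log10_size, log10(tr$size))

  rand <- simulate_digest(random_analog_spec(0.2, 5, 10, 0.9, 5000, seed = 4))
  ref <- sec_like_export(rand)
  norm <- sec_like_export(ps, normalize_to = ref)
  expect_equal(max(norm$intensity), max(ref$intensity))

  masses <- c(G = 190, S = 230)
  tr_mass <- sec_like_export(ps, mass_map = masses)
  expect_true(all(tr_mass$size >= masses["G"] + masses["S"] - 1e-9))
  expect_error(sec_like_export(ps, mass_map = c(G = 190)), "mass_map")
})

test_that("tidy and glance expose the histogram and the repeat-unit summary", {
  res <- simulate_digest(test_spec(n_chains = 500, seed = 8))
  td <- tidy(res)
  expect_true(all(c("length", "n", "n_l") %in% names(td)))
  expect_equal(sum(td$n), res$n_chains + res$n_cleavages)
  gl <- glance(res)
  expect_equal(gl$scale, "repeat_unit")
  expect_equal(gl$seed, 8L)
})

test_that("balanced-split digestion matches an i.i.d.-U chain construction (KS)", {
  n <- 4000
  bal <- simulate_digest(random_analog_spec(0.2, 5, 10, 0.9, n, seed = 55))
  # independent construction: U-free chains, then i.i.d. U at every B position
  ens0 <- simulate_ensemble(test_spec(f_acid = 0, f_diol = 0, n_chains = n, seed = 56))
  seqs <- withr::with_seed(57, {
    vapply(strsplit(ens0$sequence, "", fixed = TRUE), function(chars) {
      b <- chars == "S"
      chars[b][stats::runif(sum(b)) < 0.2] <- "U"
      paste(chars, collapse = "")
    }, character(1))
  })
  iid <- digest_ensemble(tibble::tibble(sequence = seqs))
  expand <- function(res) rep(res$counts$monomer_count, res$counts$count)
  ks <- suppressWarnings(stats::ks.test(expand(bal), expand(iid)))
  expect_gt(ks$p.value, 0.01)
})
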