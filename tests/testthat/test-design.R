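test_that("cut matrix cells count conservative and liberal hits", {
  v <- tibble::tibble(id = "a", species = "sp1", residues = "GGAATATTCC")
  cm <- cut_matrix(v, SSPI)
  expect_equal(cm$n_conservative, 1L)
  expect_equal(cm$n_liberal, 1L)
  expect_equal(cm$n_total, 1L)

  v2 <- tibble::tibble(id = "b", species = "sp1", residues = "GGAATANTCC")
  cm2 <- cut_matrix(v2, SSPI)
  expect_equal(cm2$n_conservative, 0L) # ambiguity splits the modes
  expect_equal(cm2$n_liberal, 1L)
})

test_that("a planted diagnostic is recovered from generator output", {
  decoys <- bundled_enzymes()[bundled_enzymes()$name != "SspI", ]
  sim <- simulate_voucher_set(n_species = 5L, vouchers_per_species = 10L,
                              seq_len = 700L, mutation_rate = 0.02,
                              target_species = 1L, enzyme = SSPI,
                              seed = 7L, scrub_enzymes = decoys)
  cm <- cut_matrix(sim$vouchers, bundled_enzymes())
  target <- sim$truth$target_species
  tgt_col <- cm[cm$enzyme == "SspI" & cm$species == target, ]
  expect_equal(tgt_col$n_conservative, 10L)
  expect_equal(tgt_col$n_liberal, 10L)
  other <- cm[cm$enzyme == "SspI" & cm$species != target, ]
  expect_equal(sum(other$n_liberal), 0L)
  expect_equal(other$n_total, rep(10L, 4L))
  expect_equal(diagnostic_enzymes(cm, target), "SspI")
  # agrees with the brute-force column filter
  expect_equal(oracle_diagnostics(cm, target), "SspI")
})

test_that("an enzyme cutting one non-target voucher is a near-miss", {
  cm <- tibble::tibble(
    species = rep(c("t", "o"), each = 1),
    enzyme = "E1",
    n_conservative = c(5L, 0L),
    n_liberal = c(5L, 1L),
    n_total = c(5L, 9L)
  )
  expect_equal(diagnostic_enzymes(cm, "t"), character(0))
  rep_ <- rflp_diagnostics(cm, "t")
  expect_equal(rep_$near_misses$enzyme, "E1")
  expect_equal(rep_$near_misses$n_nontarget_cut, 1L)
  expect_error(diagnostic_enzymes(cm, "absent"), "unknown target")
})

test_that("diagnostic search equals brute force on random matrices", {
  withr::with_seed(29, {
    for (i in 1:40) {
      cm <- random_cut_matrix(sample(2:8, 1), sample(2:12, 1))
      target <- sample(unique(cm$species), 1)
      expect_equal(diagnostic_enzymes(cm, target),
                   oracle_diagnostics(cm, target))
    }
  })
})

test_that("parallel-digest search returns exactly the minimal covering sets", {
  # hand case: E1 cuts only A, E2 cuts only B
  cm <- tibble::tibble(
    species = rep(c("A", "B", "C"), times = 2),
    enzyme = rep(c("E1", "E2"), each = 3),
    n_conservative = c(4L, 0L, 0L, 0L, 3L, 0L),
    n_liberal = c(4L, 0L, 0L, 0L, 3L, 0L),
    n_total = c(4L, 3L, 5L, 4L, 3L, 5L)
  )
  expect_equal(parallel_digest_sets(cm, c("A", "B")), list(c("E1", "E2")))
  # single-enzyme diagnostic stays a singleton (minimality)
  expect_equal(parallel_digest_sets(cm, "A"), list("E1"))
  # unreachable target
  expect_equal(parallel_digest_sets(cm, c("A", "C")), list())
  expect_error(parallel_digest_sets(cm, "A", max_set_size = 0L))
})

test_that("parallel-digest search matches exhaustive enumeration", {
  withr::with_seed(37, {
    for (i in 1:40) {
      cm <- random_cut_matrix(sample(2:6, 1), sample(2:8, 1))
      k <- sample(1:3, 1)
      targets <- sample(unique(cm$species),
                        sample(1:min(3, length(unique(cm$species))), 1))
      got <- parallel_digest_sets(cm, targets, max_set_size = k)
      want <- oracle_parallel_sets(cm, targets, max_set_size = k)
      expect_true(set_collection_equal(got, want))
      # every returned set re-verifies; no proper subset qualifies
      for (s in got) {
        sub <- cm[cm$enzyme %in% s, ]
        expect_equal(sum(sub$n_liberal[!sub$species %in% targets]), 0L)
        for (t in targets) {
          expect_true(any(sub$n_conservative[sub$species == t] ==
                            sub$n_total[sub$species == t]))
        }
      }
    }
  })
})

test_that("adding a cut non-target voucher revokes the diagnosis", {
  decoys <- bundled_enzymes()[bundled_enzymes()$name != "SspI", ]
  sim <- simulate_voucher_set(n_species = 3L, vouchers_per_species = 4L,
                              seq_len = 300L, seed = 13L,
                              scrub_enzymes = decoys)
  target <- sim$truth$target_species
  cm <- cut_matrix(sim$vouchers, bundled_enzymes())
  expect_true("SspI" %in% diagnostic_enzymes(cm, target))
  spoiler <- sim$vouchers[sim$vouchers$species == target, ][1, ]
  spoiler$id <- "spoiler"
  spoiler$species <- unique(sim$vouchers$species)[2] # carries the site
  cm2 <- cut_matrix(dplyr::bind_rows(sim$vouchers, spoiler),
                    bundled_enzymes())
  expect_false("SspI" %in% diagnostic_enzymes(cm2, target))
})

test_that("predicted gel patterns tally distinct digests and flag variants", {
  folmer <- bundled_primers("Folmer")
  amps <- vapply(1:3, function(s) {
    sim <- simulate_pcr_template(
      folmer, interior_len = 660L,
      plant_sites = list(list(enzyme = SSPI, cut_at = 228L)), seed = s
    )
    extract_amplicons(sim$template, folmer)$amplicon[1]
  }, character(1))
  vouchers <- tibble::tibble(id = paste0("v", 1:3),
                             species = "Neogobius melanostomus",
                             residues = amps)
  pat <- predict_rflp_pattern(vouchers, SSPI, cocktail = NULL)
  expect_equal(nrow(pat), 1L)
  expect_equal(pat$pattern, "228,481")
  expect_equal(pat$n_vouchers, 3L)
  expect_false(attr(pat, "polymorphic"))

  # ablate the site in one voucher: two patterns, polymorphism flagged
  broken <- vouchers
  site <- find_cut_sites(broken$residues[1], SSPI)$motif_start[1]
  substr(broken$residues[1], site + 1L, site + 1L) <- "C"
  pat2 <- predict_rflp_pattern(broken, SSPI, cocktail = NULL)
  expect_equal(nrow(pat2), 2L)
  expect_true(attr(pat2, "polymorphic"))

  # enzyme with no site: single uncut band (amplicons scrubbed of the motif)
  withr::with_seed(88, {
    no_site <- vouchers
    no_site$residues <- vapply(no_site$residues, function(s) {
      paste(rflpdiet:::scrub_motif(strsplit(s, "")[[1]], BGLII),
            collapse = "")
    }, character(1), USE.NAMES = FALSE)
  })
  pat3 <- predict_rflp_pattern(no_site, BGLII, cocktail = NULL)
  expect_equal(pat3$pattern, "709")

  # full pipeline from templates through the cocktail
  sim <- simulate_pcr_template(
    folmer, interior_len = 660L,
    plant_sites = list(list(enzyme = SSPI, cut_at = 228L)), seed = 77L
  )
  tmpl_vouchers <- tibble::tibble(id = "t1", species = "x",
                                  residues = sim$template)
  pat4 <- predict_rflp_pattern(tmpl_vouchers, SSPI, cocktail = folmer)
  expect_equal(pat4$pattern, "228,481")
  expect_error(predict_rflp_pattern(tmpl_vouchers[0, ], SSPI,
                                    cocktail = folmer),
               "no amplicon")
})

test_that("error rates follow the confusion-matrix definitions", {
  # corroborated study endpoint: 75 confirmed positives, 44 negatives
  records <- tibble::tibble(
    prey_id = sprintf("p%03d", 1:119),
    rflp_call = c(rep("positive", 75), rep("negative", 44)),
    truth_call = c(rep("Neogobius melanostomus", 75), rep("Other sp.", 44))
  )
  err <- estimate_rflp_error(records, "Neogobius melanostomus")
  expect_equal(err$first_order, 0)
  expect_equal(err$second_order, 0)

  rec2 <- tibble::tibble(
    prey_id = sprintf("q%02d", 1:20),
    rflp_call = c(rep("positive", 10), rep("negative", 10)),
    truth_call = c(rep("T", 9), rep("O", 11))
  )
  err2 <- estimate_rflp_error(rec2, "T")
  expect_equal(err2$first_order, 1 / 11)
  expect_equal(err2$second_order, 0)

  all_target <- tibble::tibble(prey_id = "a", rflp_call = "positive",
                               truth_call = "T")
  err3 <- estimate_rflp_error(all_target, "T")
  expect_true(is.na(err3$first_order)) # empty denominator is NA, not 0
  expect_equal(err3$second_order, 0)
})
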