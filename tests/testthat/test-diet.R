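test_that("a single-prey table gives 100 percent everywhere", {
  toy <- tibble::tibble(prey_taxon = "Neogobius melanostomus",
                        occurrence = 1L, weight_g = 5, number = 1L,
                        is_coarse = FALSE)
  dt <- diet_iri(toy, n_predators = 1L, n_empty = 0L)
  expect_equal(dt$pct_occurrence, 100)
  expect_equal(dt$pct_weight, 100)
  expect_equal(dt$pct_number, 100)
  expect_equal(dt$pct_iri, 100)
})

test_that("the embedded tables reproduce the published diet percentages", {
  counts <- bass_stomach_counts()
  smb <- diet_iri(bass_diet("SMB"),
                  n_predators = counts$n_predators[counts$species == "SMB"],
                  n_empty = counts$n_empty[counts$species == "SMB"])
  goby_smb <- smb[smb$prey_taxon == "Neogobius melanostomus", ]
  expect_equal(goby_smb$pct_occurrence, 100 * 144 / 167, tolerance = 1e-12)
  expect_equal(round(goby_smb$pct_occurrence), 86)
  expect_equal(goby_smb$pct_iri, 98.78819, tolerance = 1e-6)
  expect_equal(round(goby_smb$pct_iri), 99)

  lmb <- diet_iri(bass_diet("LMB"), n_predators = 84L, n_empty = 46L)
  goby_lmb <- lmb[lmb$prey_taxon == "Neogobius melanostomus", ]
  expect_equal(goby_lmb$pct_weight, 100 * 81.6 / 285.7, tolerance = 1e-12)
  expect_equal(round(goby_lmb$pct_weight), 29)
  expect_equal(goby_lmb$pct_iri, 68.49794, tolerance = 1e-6)
  expect_equal(round(goby_lmb$pct_iri), 68)
})

test_that("percent IRI sums to 100 and ignores the occurrence denominator", {
  withr::with_seed(41, {
    for (i in 1:20) {
      k <- sample(2:9, 1)
      diet <- tibble::tibble(
        prey_taxon = sprintf("sp%02d", seq_len(k)),
        occurrence = sample(1:30, k, replace = TRUE),
        weight_g = stats::runif(k, 0.1, 100),
        number = sample(1:40, k, replace = TRUE),
        is_coarse = FALSE
      )
      a <- diet_iri(diet, n_predators = 100L, n_empty = 30L,
                    occ_denom = "non_empty")
      b <- diet_iri(diet, n_predators = 100L, n_empty = 30L,
                    occ_denom = "all")
      expect_equal(sum(a$pct_iri), 100, tolerance = 1e-9)
      expect_equal(a$pct_iri, b$pct_iri, tolerance = 1e-12)
      expect_false(isTRUE(all.equal(a$pct_occurrence, b$pct_occurrence)))
    }
  })
})

test_that("record-level aggregation matches a hand-computed table", {
  records <- tibble::tibble(
    predator_id = c("P1", "P1", "P1", "P2", "P3"),
    predator_species = "LMB",
    prey_taxon = c("Goby", "Goby", "Alewife", NA, "Fish"),
    digestion_rank = c(4L, 3L, 2L, 1L, 2L),
    wet_weight_g = c(5, 3, 2, NA, 4),
    id_method = c("visual", "sequence", "sequence", "none", "none")
  )
  dt <- diet_composition(records)
  expect_equal(attr(dt, "n_predators"), 3L)
  expect_equal(attr(dt, "n_empty"), 1L)
  goby <- dt[dt$prey_taxon == "Goby", ]
  # occ denom 2 non-empty; weight denom 14 g; number denom 4 (all records)
  expect_equal(goby$pct_occurrence, 50)
  expect_equal(goby$pct_weight, 100 * 8 / 14)
  expect_equal(goby$pct_number, 50)
  iri_goby <- 50 * (100 * 8 / 14 + 50)
  iri_alewife <- 50 * (100 * 2 / 14 + 25)
  expect_equal(goby$pct_iri, 100 * iri_goby / (iri_goby + iri_alewife))
  expect_true(is.na(dt$pct_iri[dt$prey_taxon == "Fish"])) # coarse row
})

test_that("Hill numbers reproduce the published diversities", {
  lmb <- bass_diet("LMB")
  p_lmb <- lmb$number[!lmb$is_coarse] / sum(lmb$number[!lmb$is_coarse])
  expect_equal(round(hill_diversity(p_lmb, 1), 2), 5.53)
  expect_equal(round(hill_diversity(p_lmb, 2), 2), 4.04)
  smb <- bass_diet("SMB")
  p_smb <- smb$number[!smb$is_coarse] / sum(smb$number[!smb$is_coarse])
  expect_equal(round(hill_diversity(p_smb, 2), 2), 1.22)
})

test_that("Hill numbers agree with an independent implementation", {
  withr::with_seed(43, {
    for (i in 1:10) {
      n <- sample(2:12, 1)
      p <- stats::runif(n)
      p <- p / sum(p)
      expect_equal(hill_diversity(p, 1),
                   exp(vegan::diversity(p, index = "shannon")),
                   tolerance = 1e-10)
      expect_equal(hill_diversity(p, 2),
                   vegan::diversity(p, index = "invsimpson"),
                   tolerance = 1e-10)
    }
  })
})

test_that("Hill profiles are non-increasing, continuous at q = 1, and equal
           richness for uniform compositions", {
  withr::with_seed(47, {
    for (i in 1:10) {
      n <- sample(2:10, 1)
      p <- stats::runif(n)
      p <- p / sum(p)
      qs <- seq(0, 4, by = 0.05)
      d <- hill_diversity(p, qs)
      expect_true(all(diff(d) <= 1e-9))
      expect_equal(d[qs == 0], n)
      lim <- hill_diversity(p, 1 - 1e-8)
      expect_equal(hill_diversity(p, 1), lim, tolerance = 1e-6)
      u <- rep(1 / n, n)
      expect_equal(hill_diversity(u, c(0, 0.5, 1, 2, 3)), rep(n, 5),
                   tolerance = 1e-9)
    }
  })
  expect_error(hill_diversity(c(0.5, -0.5, 1), 1), "positive")
  expect_error(hill_diversity(c(0.3, 0.3), 1), "sum to 1")
})

test_that("diversity profiles and the relative-diversity curve", {
  counts <- dplyr::bind_rows(
    dplyr::mutate(bass_diet("LMB"), predator_species = "LMB"),
    dplyr::mutate(bass_diet("SMB"), predator_species = "SMB")
  ) |>
    dplyr::filter(!is_coarse) |>
    dplyr::select(predator_species, prey_taxon, n = number)
  prof <- diversity_profile(counts)
  g <- glance(prof)
  expect_equal(round(g$D1[g$predator_species == "LMB"], 2), 5.53)
  expect_equal(round(g$D2[g$predator_species == "LMB"], 2), 4.04)
  expect_equal(round(g$D2[g$predator_species == "SMB"], 2), 1.22)
  expect_equal(g$richness, c(9, 5))

  ratio <- diversity_ratio(prof, "LMB", "SMB")
  at09 <- ratio$ratio[abs(ratio$q - 0.9) < 1e-9]
  expect_true(at09 > 3.8 && at09 < 3.9)
  expect_equal(attr(ratio, "argmax"), 0.9)

  same <- dplyr::mutate(counts[counts$predator_species == "LMB", ],
                        predator_species = "copy")
  prof2 <- diversity_profile(dplyr::bind_rows(
    counts[counts$predator_species == "LMB", ], same))
  r2 <- diversity_ratio(prof2, "LMB", "copy")
  expect_equal(r2$ratio, rep(1, nrow(r2)))
})

test_that("stomach summaries count empties as zero-item stomachs", {
  records <- tibble::tibble(
    predator_id = c("P1", "P1", "P2", "P3"),
    predator_species = "SMB",
    prey_taxon = c("Goby", "Goby", NA, "Goby"),
    digestion_rank = c(4L, 2L, 1L, 3L),
    wet_weight_g = c(6, 2, NA, 4),
    id_method = c("visual", "none", "none", "sequence")
  )
  s <- stomach_summaries(records)
  expect_equal(s$n_predators, 3L)
  expect_equal(s$n_empty, 1L)
  expect_equal(s$pct_empty, 100 / 3)
  expect_equal(s$mean_items_per_stomach, 1)
  expect_equal(s$se_items_per_stomach, stats::sd(c(2, 0, 1)) / sqrt(3))
  expect_equal(s$mean_item_weight_g, 4)
  expect_equal(s$mean_stomach_weight_g, 4)

  empty_only <- tibble::tibble(
    predator_id = c("P1", "P2"), predator_species = "LMB",
    prey_taxon = NA_character_, digestion_rank = 1L,
    wet_weight_g = NA_real_, id_method = "none"
  )
  se <- stomach_summaries(empty_only)
  expect_equal(se$mean_items_per_stomach, 0)
  expect_equal(se$pct_empty, 100)
})

test_that("trophic position maps the baseline to level 2 and is affine", {
  expect_identical(trophic_position(8.5), 2)
  expect_equal(trophic_position(11.9), 3)
  expect_equal(trophic_position(15.64), 4.1)
  # affine in its argument: TP(a + b) - TP(a) = b / enrichment
  withr::with_seed(53, {
    x <- stats::runif(10, 5, 20)
    b <- stats::runif(10, -3, 3)
    expect_equal(trophic_position(x + b) - trophic_position(x), b / 3.4)
  })
  expect_error(trophic_position(10, enrichment = 0), "positive")
})

test_that("relative weight follows the printed power laws", {
  ws_lmb <- 10^-5.528 * 400^3.273
  expect_equal(relative_weight(400, ws_lmb, "LMB"), 100)
  expect_equal(relative_weight(400, 1.157 * ws_lmb, "LMB"), 115.7)
  ws_smb <- 10^-5.329 * 400^3.200
  expect_false(isTRUE(all.equal(ws_lmb, ws_smb)))
  expect_equal(relative_weight(400, ws_lmb, "SMB"), 100 * ws_lmb / ws_smb)
  expect_error(relative_weight(-1, 100, "LMB"), "positive")
  expect_error(relative_weight(400, 100, "XX"), "unknown species")
})

test_that("Fulton's condition factor obeys the cubic law and units", {
  expect_equal(fulton_k(1000, 10), 100)
  expect_equal(fulton_k(500, 20), fulton_k(500, 10) / 8)
  # unit identity: K = c * W / L^3 is invariant when c compensates the units,
  # c' = c * (length factor)^3 / (weight factor)
  w_g <- 750; fl_cm <- 9.3
  expect_equal(fulton_k(w_g, fl_cm, constant = 100),
               fulton_k(w_g / 1000, fl_cm / 100, constant = 100 * 1e-6 / 1e-3))
  expect_error(fulton_k(0, 10), "positive")
})
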