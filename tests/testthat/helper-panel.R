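# Engineered species templates for the blocking-primer panel tests:
# one template per species with blocker windows matching or mismatching
# the stabilizer/determiner segments as the study observed.

make_species_panel <- function() {
  blk <- bundled_blocking_primers()
  coi3 <- bundled_primers("COI-3")
  win <- function(b, s, d) list(blocker = b, stabilizer_match = s,
                                determiner_match = d)
  tmpl <- function(windows, seed) {
    simulate_pcr_template(coi3, interior_len = 260L,
                          blocker_windows = windows, seed = seed)$template
  }
  tibble::tibble(
    species = c("Micropterus salmoides", "Micropterus dolomieu",
                "Alosa pseudoharengus", "Neogobius melanostomus"),
    sequence = c(
      # LMB: every blocker fully complementary
      tmpl(list(win(blk[1, ], TRUE, TRUE), win(blk[2, ], TRUE, TRUE),
                win(blk[3, ], TRUE, TRUE)), 401L),
      # SMB: DPO stabilizers anneal, determiners and the plain oligo do not
      tmpl(list(win(blk[1, ], FALSE, FALSE), win(blk[2, ], TRUE, FALSE),
                win(blk[3, ], TRUE, FALSE)), 402L),
      # Alewife: only the conventional DPO stabilizer anneals
      tmpl(list(win(blk[1, ], FALSE, FALSE), win(blk[2, ], TRUE, FALSE),
                win(blk[3, ], FALSE, TRUE)), 403L),
      # Round Goby: no stabilizer anneals
      tmpl(list(win(blk[1, ], FALSE, FALSE), win(blk[2, ], FALSE, TRUE),
                win(blk[3, ], FALSE, TRUE)), 404L)
    )
  )
}
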