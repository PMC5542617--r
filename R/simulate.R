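# Seed-deterministic generators: voucher sets with a planted diagnostic
# restriction site, PCR templates with planted primer / restriction /
# blocker windows, and stomach-content tables with the multinomial prey
# composition, empty-stomach fraction and rank-dependent identification
# failure of real dissection data. Each generator returns a truth record so
# tests can verify recovery against known ground truth.
#
# All randomness flows through one stream seeded per call (withr::with_seed);
# no global RNG state is touched.

BASES <- c("A", "C", "G", "T")

rand_bases <- function(n) sample(BASES, n, replace = TRUE)

mutate_chars <- function(chars, rate) {
  if (rate <= 0) return(chars)
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(BASES, chars[i]), 1L)
  }
  chars
}

# Remove liberal-mode occurrences of a motif (both strands) from a character
# vector, leaving protected motif starts and positions untouched. Errors when
# the constraint cannot be met within the retry budget.
scrub_motif <- function(chars, enzyme, protect = integer(0),
                        protect_pos = integer(0), max_rounds = 200L) {
  pats <- list(seq_masks(enzyme$recognition))
  rc <- revcomp(enzyme$recognition)
  if (!identical(rc, enzyme$recognition)) pats <- c(pats, list(seq_masks(rc)))
  m <- nchar(enzyme$recognition)
  frozen <- union(protect_span(protect, m), protect_pos)
  for (round in seq_len(max_rounds)) {
    tmask <- unname(.NUC_MASK[chars])
    starts <- unique(unlist(lapply(pats, scan_motif, tmask = tmask,
                                   match_mode = "liberal")))
    starts <- starts[!(starts %in% protect)]
    if (length(starts) == 0L) return(chars)
    redrawn <- FALSE
    for (s in starts) {
      span <- setdiff((s + 1L):(s + m), frozen)
      if (length(span) == 0L) next
      chars[span] <- rand_bases(length(span))
      redrawn <- TRUE
    }
    if (!redrawn) break # every remaining hit sits inside a protected span
  }
  stop("could not satisfy site-absence constraint for ", enzyme$name,
       call. = FALSE)
}

# 1-based positions covered by protected motif starts (0-based).
protect_span <- function(protect_starts, m) {
  if (length(protect_starts) == 0L) return(integer(0))
  unique(unlist(lapply(protect_starts, function(s) (s + 1L):(s + m))))
}

# IUPAC codes of set size >= 2 containing a given base.
.AMBIG_FOR <- list(
  A = c("R", "W", "M", "D", "H", "V", "N"),
  C = c("Y", "S", "M", "B", "H", "V", "N"),
  G = c("R", "S", "K", "B", "D", "V", "N"),
  T = c("Y", "W", "K", "B", "D", "H", "N")
)

#' Simulate a voucher set with a planted diagnostic enzyme
#'
#' Draws one random ancestor per species, derives vouchers as per-base
#' mutated copies, writes the planted enzyme's recognition site into every
#' target-species voucher at one fixed locus, and guarantees the site absent
#' (liberal matching, both strands) from every non-target voucher and from
#' every other locus of the target vouchers. Optionally replaces a fraction
#' of positions with compatible IUPAC ambiguity codes without violating the
#' plant. Identical seeds give identical output.
#'
#' @param n_species Number of species.
#' @param vouchers_per_species Vouchers per species (scalar or length
#'   `n_species`).
#' @param seq_len Voucher length, bp (must exceed the motif length + 10).
#' @param mutation_rate Per-base mutation probability within species.
#' @param target_species Index of the species receiving the planted site.
#' @param enzyme One-row enzyme tibble to plant.
#' @param ambiguity_rate Fraction of positions replaced by compatible
#'   ambiguity codes (default 0).
#' @param seed Integer seed.
#' @param species_names Optional species names (default `"Species 01"`, ...).
#' @param locus 0-based motif start of the plant (default `seq_len %/% 3`).
#' @param scrub_enzymes Optional enzyme tibble (e.g. the decoy catalog) whose
#'   recognition sites are additionally removed from every voucher, so the
#'   planted enzyme is the unique diagnostic by construction. Without it the
#'   planted enzyme is still always recovered, but a decoy can qualify by
#'   chance when the target ancestor happens to carry its site.
#' @return List with `vouchers` (tibble `id`, `species`, `residues`) and
#'   `truth` (target species, enzyme, locus, cut coordinate, parameters).
#' @export
simulate_voucher_set <- function(n_species = 5L, vouchers_per_species = 10L,
                                 seq_len = 652L, mutation_rate = 0.02,
                                 target_species = 1L, enzyme = NULL,
                                 ambiguity_rate = 0, seed = 1L,
                                 species_names = NULL, locus = NULL,
                                 scrub_enzymes = NULL) {
  if (is.null(enzyme)) enzyme <- restriction_enzyme("SspI", "AAT^ATT")
  m <- nchar(enzyme$recognition)
  stopifnot(seq_len > m + 10L, mutation_rate >= 0, mutation_rate < 1,
            ambiguity_rate >= 0, ambiguity_rate < 1,
            target_species >= 1L, target_species <= n_species)
  if (is.null(species_names)) {
    species_names <- sprintf("Species %02d", seq_len(n_species))
  }
  nv <- rep_len(vouchers_per_species, n_species)
  if (is.null(locus)) locus <- seq_len %/% 3L
  stopifnot(locus >= 0L, locus + m <= seq_len)
  withr::with_seed(seed, {
    planted_motif <- resolve_iupac(enzyme$recognition)
    scrub_list <- if (is.null(scrub_enzymes)) list() else
      lapply(seq_len(nrow(scrub_enzymes)), function(k) scrub_enzymes[k, ])
    # scrub the planted enzyme and any decoys until jointly clean (a redraw
    # for one motif can reintroduce another)
    clean <- function(chars, protect_start = NULL) {
      prot <- if (is.null(protect_start)) integer(0)
        else protect_span(protect_start, m)
      for (round in seq_len(60L)) {
        before <- chars
        chars <- scrub_motif(chars, enzyme,
                             protect = protect_start %||% integer(0),
                             protect_pos = prot)
        for (se in scrub_list) {
          chars <- scrub_motif(chars, se, protect_pos = prot)
        }
        if (identical(chars, before)) return(chars)
      }
      stop("could not satisfy joint site-absence constraints", call. = FALSE)
    }
    rows <- list()
    for (s in seq_len(n_species)) {
      is_target <- s == target_species
      ancestor <- clean(rand_bases(seq_len))
      for (v in seq_len(nv[s])) {
        chars <- mutate_chars(ancestor, mutation_rate)
        if (is_target) {
          chars[(locus + 1L):(locus + m)] <-
            strsplit(planted_motif, "")[[1]]
          chars <- clean(chars, locus)
        } else {
          chars <- clean(chars)
        }
        if (ambiguity_rate > 0) {
          n_amb <- round(ambiguity_rate * seq_len)
          avoid <- if (is_target) protect_span(locus, m) else integer(0)
          pool <- setdiff(seq_len(seq_len), avoid)
          pos <- sample(pool, min(n_amb, length(pool)))
          for (p in pos) {
            chars[p] <- sample(.AMBIG_FOR[[chars[p]]], 1L)
          }
          chars <- clean(chars, if (is_target) locus)
        }
        rows[[length(rows) + 1L]] <- tibble::tibble(
          id = sprintf("SYN%02d-%03d", s, v),
          species = species_names[s],
          residues = paste(chars, collapse = "")
        )
      }
    }
    vouchers <- dplyr::bind_rows(rows)
    list(
      vouchers = vouchers,
      truth = list(
        target_species = species_names[target_species],
        enzyme = enzyme$name,
        locus = locus,
        cut_coord = locus + enzyme$cut_top,
        planted_motif = planted_motif,
        seed = seed,
        params = list(n_species = n_species, vouchers_per_species = nv,
                      seq_len = seq_len, mutation_rate = mutation_rate,
                      ambiguity_rate = ambiguity_rate,
                      scrubbed_decoys = if (is.null(scrub_enzymes))
                        character(0) else scrub_enzymes$name)
      )
    )
  })
}

mismatch_base <- function(code) {
  excl <- base_set(code)
  pool <- setdiff(BASES, excl)
  if (length(pool) == 0L) return(NA_character_) # universal code: cannot mismatch
  if (length(pool) == 1L) pool else sample(pool, 1L)
}

#' Simulate a PCR template with planted primer, restriction and blocker sites
#'
#' Builds a template carrying exact binding sites for one forward and one
#' reverse primer of a cocktail around a random interior, optionally plants
#' restriction sites at requested amplicon cut coordinates, and writes
#' blocking-primer windows whose stabilizer and determiner segments match or
#' mismatch on demand. The planted enzymes have no other liberal-mode site
#' in the amplicon.
#'
#' @param cocktail Primer tibble.
#' @param interior_len Length of the template interior between the two
#'   binding sites, bp.
#' @param plant_sites List of `list(enzyme = <one-row enzyme tibble>,
#'   cut_at = <0-based amplicon cut coordinate>)`.
#' @param blocker_windows List of `list(blocker = <one-row parsed blocker>,
#'   stabilizer_match = TRUE, determiner_match = TRUE, at = <0-based template
#'   start, optional>)`.
#' @param fwd,rev Index of the forward / reverse primer to use (default 1).
#' @param pad Lengths of random flanks outside the binding sites.
#' @param seed Integer seed.
#' @param max_tries Interior redraw budget for scrubbing accidental sites.
#' @return List with `template` and `truth` (primer names, amplicon length
#'   and span, planted cut coordinates, blocker window positions).
#' @export
simulate_pcr_template <- function(cocktail, interior_len = 660L,
                                  plant_sites = NULL, blocker_windows = NULL,
                                  fwd = 1L, rev = 1L, pad = c(30L, 30L),
                                  seed = 1L, max_tries = 50L) {
  stopifnot(interior_len > 0L)
  fw <- dplyr::filter(cocktail, .data$direction == "forward")[fwd, ]
  rv <- dplyr::filter(cocktail, .data$direction == "reverse")[rev, ]
  stopifnot(nrow(fw) == 1L, nrow(rv) == 1L)
  withr::with_seed(seed, {
    fbind <- resolve_iupac(binding_region(fw))
    rsite <- revcomp(resolve_iupac(binding_region(rv)))
    fb_len <- nchar(fbind)
    rs_len <- nchar(rsite)
    fwd_full <- nchar(fw$sequence)
    rev_full <- nchar(rv$sequence)
    amp_len <- fwd_full + interior_len + rev_full
    # amplicon coordinate -> interior index (1-based), NA outside interior
    amp_to_interior <- function(p) {
      i <- as.integer(p) - fwd_full + 1L
      if (i < 1L || i > interior_len) NA_integer_ else i
    }
    for (attempt in seq_len(max_tries)) {
      interior <- rand_bases(interior_len)
      protect <- list()
      ok <- TRUE
      for (ps in plant_sites %||% list()) {
        enz <- ps$enzyme
        m <- nchar(enz$recognition)
        a_start <- ps$cut_at - enz$cut_top
        i_start <- amp_to_interior(a_start)
        if (is.na(i_start) || is.na(amp_to_interior(a_start + m - 1L))) {
          stop("planted site for ", enz$name,
               " does not fit inside the template interior", call. = FALSE)
        }
        interior[i_start:(i_start + m - 1L)] <-
          strsplit(resolve_iupac(enz$recognition), "")[[1]]
        protect[[length(protect) + 1L]] <-
          list(enzyme = enz, start = i_start - 1L)
      }
      # scrub accidental liberal sites of each planted enzyme elsewhere
      scrub_fail <- FALSE
      for (pr in protect) {
        interior <- tryCatch(
          scrub_motif(interior, pr$enzyme,
                      protect = vapply(
                        Filter(function(x) x$enzyme$name == pr$enzyme$name,
                               protect),
                        function(x) x$start, integer(1))),
          error = function(e) { scrub_fail <<- TRUE; interior }
        )
      }
      if (scrub_fail) next
      # blocker windows live in the interior after the planted sites
      occupied <- unlist(lapply(protect, function(pr) {
        protect_span(pr$start, nchar(pr$enzyme$recognition))
      }))
      windows <- list()
      cursor <- 5L
      for (bw in blocker_windows %||% list()) {
        bl <- bw$blocker
        core <- bl$core
        mlen <- nchar(core)
        at <- bw$at
        if (is.null(at)) {
          at <- cursor
          cursor <- cursor + mlen + 7L
        }
        span <- (at + 1L):(at + mlen)
        if (max(span) > interior_len) {
          stop("blocker window for ", bl$name, " does not fit in the ",
               "interior", call. = FALSE)
        }
        if (any(span %in% occupied)) {
          stop("contradictory window requests: overlapping loci",
               call. = FALSE)
        }
        occupied <- c(occupied, span)
        # perfect-complement window, then break the requested segments
        pat <- strsplit(revcomp(resolve_iupac(core)), "")[[1]]
        core_chars <- strsplit(core, "")[[1]]
        break_segment <- function(a, b) {
          len <- b - a + 1L
          k <- max(2L, ceiling(0.4 * len))
          pos <- sort(sample(a:b, min(k, len)))
          for (j in pos) {
            bad <- mismatch_base(core_chars[j])
            if (!is.na(bad)) pat[mlen - j + 1L] <<- revcomp(bad)
          }
        }
        if (bl$is_dpo) {
          if (!isTRUE(bw$stabilizer_match)) {
            break_segment(bl$stab_start, bl$stab_end)
          }
          if (!isTRUE(bw$determiner_match)) {
            break_segment(bl$det_start, bl$det_end)
          }
        } else if (!isTRUE(bw$determiner_match) ||
                   !isTRUE(bw$stabilizer_match)) {
          break_segment(bl$det_start, bl$det_end)
        }
        interior[span] <- pat
        windows[[length(windows) + 1L]] <- list(
          blocker = bl$name, template_start = pad[1] + fb_len + at,
          stabilizer_match = isTRUE(bw$stabilizer_match),
          determiner_match = isTRUE(bw$determiner_match)
        )
      }
      template <- paste(
        c(rand_bases(pad[1]), strsplit(fbind, "")[[1]], interior,
          strsplit(rsite, "")[[1]], rand_bases(pad[2])),
        collapse = ""
      )
      # verify the amplicon digests exactly at the planted coordinates
      amp <- paste0(fw$sequence,
                    paste(interior, collapse = ""),
                    revcomp(rv$sequence))
      planted_cuts <- sort(vapply(plant_sites %||% list(),
                                  function(ps) as.integer(ps$cut_at),
                                  integer(1)))
      observed <- sort(unique(unlist(lapply(
        plant_sites %||% list(),
        function(ps) find_cut_sites(chartr("N", "A", amp), ps$enzyme,
                                    "liberal")$cut_coord
      ))))
      if (length(planted_cuts) > 0 && !identical(observed, planted_cuts)) {
        next # accidental site survived (e.g. straddling a boundary); redraw
      }
      return(list(
        template = template,
        truth = list(
          fwd_primer = fw$name, rev_primer = rv$name,
          amplicon_length = amp_len,
          amplicon_span = c(pad[1], pad[1] + fb_len + interior_len + rs_len),
          planted_cuts = planted_cuts,
          blocker_windows = windows,
          seed = seed
        )
      ))
    }
    stop("could not build a clean template in ", max_tries, " attempts",
         call. = FALSE)
  })
}

#' Default prey composition of Smallmouth Bass stomachs
#'
#' Identified-prey proportions from the published Smallmouth Bass number
#' column (n = 278), used as the default multinomial composition of
#' [simulate_stomach_table()].
#'
#' @return Named numeric vector summing to 1.
#' @export
smb_prey_composition <- function() {
  c("Alosa pseudoharengus" = 24, "Lepomis gibbosus" = 1,
    "Neogobius melanostomus" = 251, "Orconectes propinquus" = 1,
    "Orconectes virilis" = 1) / 278
}

prey_class <- function(taxon) {
  ifelse(grepl("^Orconectes", taxon), "Crayfish", "Fish")
}

#' Simulate a stomach-content record table
#'
#' Per predator: the stomach is empty with probability `empty_prob`
#' (emitting a rank-1 marker record); otherwise it holds `1 + Poisson`
#' prey items, each drawing a taxon from the multinomial composition, a
#' digestion rank, a lognormal wet weight, and an identification method that
#' is downgraded to `"none"` (with the taxon coarsened to its class) with
#' the rank's failure probability. Defaults emulate the Smallmouth Bass
#' study conditions: 264 predators, 97/264 empty, the published prey
#' composition, mean 287/167 items per non-empty stomach and a mean item
#' weight near 4.25 g.
#'
#' @param n_predators Number of predators.
#' @param empty_prob Probability a stomach is empty.
#' @param composition Named taxon probabilities summing to 1.
#' @param mean_items Mean items per non-empty stomach (>= 1; the Poisson
#'   component has mean `mean_items - 1`).
#' @param weight_meanlog,weight_sdlog Lognormal wet-weight parameters
#'   (scalars, or named per taxon for `weight_meanlog`).
#' @param id_failure Named failure probability per digestion rank
#'   (`"2"`..`"5"`).
#' @param rank_probs Named sampling probabilities of ranks 2-5 for items.
#' @param predator_species Label for the predator column.
#' @param seed Integer seed.
#' @return List with `records` (prey-record tibble) and `truth` (generating
#'   parameters plus the true taxa of identification failures).
#' @export
simulate_stomach_table <- function(n_predators = 264L,
                                   empty_prob = 97 / 264,
                                   composition = smb_prey_composition(),
                                   mean_items = 287 / 167,
                                   weight_meanlog = log(4.25) - 0.8^2 / 2,
                                   weight_sdlog = 0.8,
                                   id_failure = c("2" = 0.05, "3" = 0.02,
                                                  "4" = 0, "5" = 0),
                                   rank_probs = c("2" = 175, "3" = 49,
                                                  "4" = 63, "5" = 0) / 287,
                                   predator_species = "SMB",
                                   seed = 1L) {
  stopifnot(abs(sum(composition) - 1) < 1e-9,
            all(composition >= 0),
            empty_prob >= 0, empty_prob <= 1,
            all(id_failure >= 0 & id_failure <= 1),
            mean_items >= 1)
  withr::with_seed(seed, {
    pid <- sprintf("P%05d", seq_len(n_predators))
    empty <- stats::runif(n_predators) < empty_prob
    n_items <- integer(n_predators)
    n_items[!empty] <- 1L + stats::rpois(sum(!empty), mean_items - 1)
    total <- sum(n_items)
    item_pid <- rep(pid, n_items)
    taxon <- if (total) sample(names(composition), total, replace = TRUE,
                               prob = composition) else character(0)
    rank <- as.integer(sample(names(rank_probs), total, replace = TRUE,
                              prob = rank_probs))
    ml <- if (length(weight_meanlog) > 1L) unname(weight_meanlog[taxon])
      else rep(weight_meanlog, total)
    w <- stats::rlnorm(total, meanlog = ml, sdlog = weight_sdlog)
    failed <- stats::runif(total) < unname(id_failure[as.character(rank)])
    obs_taxon <- as.character(ifelse(failed, prey_class(taxon), taxon))
    method <- as.character(ifelse(failed, "none",
                                  ifelse(rank >= 4L, "visual", "sequence")))
    records <- dplyr::bind_rows(
      tibble::tibble(
        predator_id = pid[empty], predator_species = predator_species,
        prey_taxon = NA_character_, digestion_rank = 1L,
        wet_weight_g = NA_real_, id_method = "none"
      ),
      tibble::tibble(
        predator_id = item_pid, predator_species = predator_species,
        prey_taxon = obs_taxon, digestion_rank = rank,
        wet_weight_g = w, id_method = method
      )
    ) |>
      dplyr::arrange(.data$predator_id)
    list(
      records = records,
      truth = list(
        composition = composition, empty_prob = empty_prob,
        mean_items = mean_items, seed = seed,
        id_failures = tibble::tibble(
          predator_id = item_pid[failed],
          true_taxon = taxon[failed],
          observed_taxon = obs_taxon[failed],
          digestion_rank = rank[failed]
        )
      )
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
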