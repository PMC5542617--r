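# Shared fixtures and independent brute-force oracles for property tests.

SSPI <- restriction_enzyme("SspI", "AAT^ATT")
NSII <- restriction_enzyme("NsiI", "ATGCA^T")
BGLII <- restriction_enzyme("BglII", "A^GATCT")

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# All full resolutions of an ambiguous residue string.
enumerate_resolutions <- function(residues) {
  sets <- lapply(strsplit(residues, "")[[1]], base_set)
  apply(expand.grid(sets, stringsAsFactors = FALSE), 1L,
        paste, collapse = "")
}

# Concrete-template motif hits: 0-based starts where every template base is
# inside the motif code's base set.
concrete_hits <- function(template, motif) {
  tc <- strsplit(template, "")[[1]]
  mc <- strsplit(motif, "")[[1]]
  m <- length(mc)
  n <- length(tc)
  if (n < m) return(integer(0))
  starts <- integer(0)
  for (s in 0:(n - m)) {
    ok <- all(vapply(seq_len(m), function(j) {
      tc[s + j] %in% base_set(mc[j])
    }, logical(1)))
    if (ok) starts <- c(starts, s)
  }
  starts
}

# Position-wise oracle over all resolutions of an ambiguous template:
# conservative = hit in every resolution, liberal = hit in at least one.
oracle_motif_starts <- function(template, motif, match_mode) {
  res <- enumerate_resolutions(template)
  hit_sets <- lapply(res, concrete_hits, motif = motif)
  all_starts <- sort(unique(unlist(hit_sets)))
  keep <- vapply(all_starts, function(s) {
    in_each <- vapply(hit_sets, function(h) s %in% h, logical(1))
    if (match_mode == "conservative") all(in_each) else any(in_each)
  }, logical(1))
  all_starts[keep]
}

oracle_cut_sites <- function(template, enzyme, match_mode) {
  motif <- enzyme$recognition
  fw <- oracle_motif_starts(template, motif, match_mode)
  out <- data.frame(motif_start = fw, strand = rep("+", length(fw)))
  rc <- revcomp(motif)
  if (!identical(rc, motif)) {
    rv <- oracle_motif_starts(template, rc, match_mode)
    out <- rbind(out, data.frame(motif_start = rv,
                                 strand = rep("-", length(rv))))
  }
  out[order(out$motif_start, out$strand), , drop = FALSE]
}

# Random small cut matrix with consistent counts.
random_cut_matrix <- function(n_species, n_enzymes) {
  species <- sprintf("sp%02d", seq_len(n_species))
  enzymes <- sprintf("E%02d", seq_len(n_enzymes))
  totals <- sample(1:6, n_species, replace = TRUE)
  grid <- expand.grid(species = species, enzyme = enzymes,
                      stringsAsFactors = FALSE)
  grid$n_total <- totals[match(grid$species, species)]
  grid$n_liberal <- vapply(grid$n_total, function(t) sample(0:t, 1),
                           integer(1))
  grid$n_conservative <- vapply(grid$n_liberal, function(l) sample(0:l, 1),
                                integer(1))
  out <- tibble::as_tibble(grid[, c("species", "enzyme", "n_conservative",
                                    "n_liberal", "n_total")])
  class(out) <- c("cut_matrix", class(out))
  out
}

# Brute-force diagnostic filter straight from the predicate.
oracle_diagnostics <- function(matrix, target) {
  enz <- unique(matrix$enzyme)
  keep <- vapply(enz, function(e) {
    sub <- matrix[matrix$enzyme == e, ]
    tgt <- sub[sub$species == target, ]
    all(tgt$n_conservative == tgt$n_total) &&
      sum(sub$n_liberal[sub$species != target]) == 0L
  }, logical(1))
  enz[keep]
}

# Brute-force minimal parallel-digest sets by full subset enumeration.
oracle_parallel_sets <- function(matrix, targets, max_set_size) {
  enz <- unique(matrix$enzyme)
  qualifies <- function(set) {
    sub <- matrix[matrix$enzyme %in% set, ]
    if (sum(sub$n_liberal[!sub$species %in% targets]) > 0L) return(FALSE)
    all(vapply(targets, function(t) {
      any(vapply(set, function(e) {
        cell <- sub[sub$enzyme == e & sub$species == t, ]
        cell$n_conservative == cell$n_total
      }, logical(1)))
    }, logical(1)))
  }
  sets <- list()
  for (k in seq_len(min(max_set_size, length(enz)))) {
    for (combo in utils::combn(enz, k, simplify = FALSE)) {
      if (qualifies(combo)) sets[[length(sets) + 1L]] <- combo
    }
  }
  minimal <- Filter(function(s) {
    !any(vapply(sets, function(o) {
      length(o) < length(s) && all(o %in% s)
    }, logical(1)))
  }, sets)
  minimal
}

set_collection_equal <- function(a, b) {
  norm <- function(x) sort(vapply(x, function(s) paste(sort(s), collapse = "+"),
                                  character(1)))
  identical(norm(a), norm(b))
}
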