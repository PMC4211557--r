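# Default hotspot windows: rough spans of the three CDRs on the fixed
# 130-residue variable-region coordinate (documented as approximations;
# configurable).
DEFAULT_HOTSPOTS <- data.frame(start = c(26L, 50L, 95L),
                               end = c(35L, 58L, 110L),
                               multiplier = c(4, 4, 6))

#' Somatic-hypermutation simulation parameters
#'
#' Per-position substitution rates are
#' `base_rate * exp(-(L - i)/decay_length) * hotspot multiplier`, clipped to
#' \[0, 1\]: the positional factor rises toward the C-terminus (emulating, at
#' the protein level, the loss of germline motifs with distance from the
#' transcription start that AID-driven hypermutation produces), and
#' CDR-like hotspot windows multiply the rate further.
#'
#' @param base_rate Per-residue substitution probability scale (default 0.07,
#'   chosen so a 130-residue clonotype averages 5--10 substitutions; the
#'   underlying biology fixes no protein-level value).
#' @param decay_length Length scale of the positional factor, residues
#'   (default 50).
#' @param hotspot_windows Data frame (start, end, multiplier); default three
#'   CDR-like windows 26--35 (x4), 50--58 (x4), 95--110 (x6).
#' @param seed Integer master seed for clonotype generation.
#' @param alphabet Residue alphabet substitutions are drawn from (default the
#'   20 standard letters; a restricted alphabet lets tests plant motifs that
#'   provably occur nowhere else).
#' @return An `shm_parameters` list.
#' @export
shm_parameters <- function(base_rate = 0.07, decay_length = 50,
                           hotspot_windows = DEFAULT_HOTSPOTS, seed = 1,
                           alphabet = aa_alphabet()) {
  if (base_rate < 0 || base_rate > 1)
    stop_contract("`base_rate` must be in [0, 1]")
  if (decay_length <= 0) stop_contract("`decay_length` must be positive")
  stopifnot(is.data.frame(hotspot_windows),
            all(c("start", "end", "multiplier") %in% names(hotspot_windows)))
  structure(list(base_rate = base_rate, decay_length = decay_length,
                 hotspot_windows = hotspot_windows, seed = seed,
                 alphabet = alphabet),
            class = "shm_parameters")
}

#' Per-position substitution rates implied by SHM parameters
#'
#' @param length Sequence length in residues.
#' @param params An `shm_parameters` object.
#' @return Numeric vector of per-position substitution probabilities,
#'   clipped to \[0, 1\]. Its sum is the expected mutation count per
#'   clonotype.
#' @export
position_mutation_rates <- function(length, params) {
  stopifnot(inherits(params, "shm_parameters"))
  length <- check_scalar_count(length, "length")
  i <- seq_len(length)
  rate <- params$base_rate * exp(-(length - i) / params$decay_length)
  for (h in seq_len(nrow(params$hotspot_windows))) {
    w <- params$hotspot_windows[h, ]
    in_w <- i >= w$start & i <= min(w$end, length)
    rate[in_w] <- rate[in_w] * w$multiplier
  }
  pmin(pmax(rate, 0), 1)
}

#' Generate a synthetic germline library
#'
#' Emulates a family-structured germline gene library: each family descends
#' from its own random ancestor, members within a family diverge by a small
#' fraction of positions, so intra-family identity far exceeds inter-family
#' identity. Usage weights (the probability each germline seeds a clonotype)
#' are drawn from a flat Dirichlet and sum to 1. Fully reproducible per
#' seed.
#'
#' @param n_germlines Number of germline sequences.
#' @param length Sequence length (default 130, the fixed variable-region
#'   coordinate).
#' @param n_families Number of families (default 4, capped at
#'   `n_germlines`).
#' @param seed Integer seed.
#' @param member_divergence Fraction of positions mutated from the family
#'   ancestor per member (default 0.04).
#' @param alphabet Residue alphabet (default all 20).
#' @return A `germline_library`: list with `sequences` (`tcem_records`,
#'   `is_germline = TRUE`), `usage_weights` (named, sums to 1), `families`
#'   (named character).
#' @export
make_germline_library <- function(n_germlines, length = 130,
                                  n_families = min(4, n_germlines),
                                  seed = 1, member_divergence = 0.04,
                                  alphabet = aa_alphabet()) {
  n_germlines <- check_scalar_count(n_germlines, "n_germlines")
  n_families <- check_scalar_count(n_families, "n_families")
  length <- check_scalar_count(length, "length", min = 15)
  if (n_families > n_germlines)
    stop_contract("`n_families` cannot exceed `n_germlines`")
  ancestors <- lapply(seq_len(n_families), function(f)
    with_seed(derive_seed(seed, "ancestor", f),
              sample(alphabet, length, replace = TRUE)))
  fam <- rep_len(seq_len(n_families), n_germlines)
  seqs <- vapply(seq_len(n_germlines), function(g) {
    anc <- ancestors[[fam[g]]]
    with_seed(derive_seed(seed, "member", g), {
      n_mut <- max(1L, round(member_divergence * length))
      pos <- sample(length, n_mut)
      for (p in pos) anc[p] <- sample(setdiff(alphabet, anc[p]), 1L)
      paste(anc, collapse = "")
    })
  }, character(1))
  ids <- sprintf("IGHV%d-%02d", fam, stats::ave(fam, fam, FUN = seq_along))
  w <- with_seed(derive_seed(seed, "usage"),
                 stats::rgamma(n_germlines, shape = 1))
  w <- w / sum(w)
  structure(list(
    sequences = sequence_records(id = ids, residues = seqs,
                                 description = sprintf("germline family %d",
                                                       fam),
                                 is_germline = TRUE),
    usage_weights = setNames(w, ids),
    families = setNames(as.character(fam), ids)),
    class = "germline_library")
}

#' @export
print.germline_library <- function(x, ...) {
  cat(sprintf("<germline_library> %d germlines in %d family(ies), length %d\n",
              nrow(x$sequences), length(unique(x$families)),
              nchar(x$sequences$residues[1])))
  invisible(x)
}

#' Simulate one somatically hypermutated clonotype
#'
#' Each position mutates independently with its [position_mutation_rates()]
#' probability; a mutated position is substituted by a uniformly random
#' different residue from the parameter alphabet. No insertions or
#' deletions, so positional alignment with the germline is exact and the
#' mutated positions are recorded as ground truth.
#'
#' @param germline A single germline record.
#' @param params An `shm_parameters` object.
#' @param clone_id Id for the new record (default `"clone1"`).
#' @param seed Seed for this clonotype; default derives from `params$seed`
#'   and `clone_id`, so generation is order-independent.
#' @return A `simulated_clonotype`: list with `record` (one-row
#'   `tcem_records`), `germline_id`, `mutated_positions` (integer vector).
#' @export
simulate_clonotype <- function(germline, params, clone_id = "clone1",
                               seed = NULL) {
  stopifnot(inherits(params, "shm_parameters"))
  rec <- as_record(germline)
  L <- nchar(rec$residues)
  if (L < 15L) stop_contract("germline shorter than 15 residues")
  if (is.null(seed)) seed <- derive_seed(params$seed, "clone", clone_id)
  rates <- position_mutation_rates(L, params)
  chars <- strsplit(rec$residues, "")[[1]]
  mutated <- with_seed(seed, {
    hit <- which(runif(L) < rates)
    for (p in hit)
      chars[p] <- sample(setdiff(params$alphabet, chars[p]), 1L)
    hit
  })
  structure(list(
    record = sequence_records(id = clone_id,
                              residues = paste(chars, collapse = ""),
                              description = sprintf("clonotype of %s",
                                                    rec$id)),
    germline_id = rec$id,
    mutated_positions = as.integer(mutated)),
    class = "simulated_clonotype")
}

#' Simulate a ground-truth-labeled repertoire
#'
#' Draws parent germlines according to the library's usage weights and
#' applies [simulate_clonotype()] to each draw. The result carries the
#' germline library as `germline_reference` and a `ground_truth` table of
#' mutated positions per clonotype, so origin attribution can be checked
#' against truth.
#'
#' @param library A `germline_library`.
#' @param n_clonotypes Number of clonotypes to generate.
#' @param params An `shm_parameters` object.
#' @param seed Master seed (default `params$seed`).
#' @return A `repertoire_dataset` whose `ground_truth` is a data frame
#'   (clonotype_id, germline_id, n_mutations, mutated_positions
#'   \[list-column\]).
#' @export
simulate_repertoire <- function(library, n_clonotypes, params,
                                seed = params$seed) {
  stopifnot(inherits(library, "germline_library"),
            inherits(params, "shm_parameters"))
  n_clonotypes <- check_scalar_count(n_clonotypes, "n_clonotypes")
  parents <- with_seed(derive_seed(seed, "parent_draws"),
                       sample(library$sequences$id, n_clonotypes,
                              replace = TRUE, prob = library$usage_weights))
  ids <- sprintf("clone%05d", seq_len(n_clonotypes))
  clones <- lapply(seq_len(n_clonotypes), function(i) {
    gl <- library$sequences[library$sequences$id == parents[i], ,
                            drop = FALSE]
    simulate_clonotype(gl, params, clone_id = ids[i],
                       seed = derive_seed(seed, "clone", i))
  })
  records <- do.call(rbind, lapply(clones, `[[`, "record"))
  class(records) <- c("tcem_records", "data.frame")
  gt <- data.frame(clonotype_id = ids, germline_id = parents,
                   n_mutations = vapply(clones, function(cl)
                     length(cl$mutated_positions), integer(1)),
                   stringsAsFactors = FALSE)
  gt$mutated_positions <- lapply(clones, `[[`, "mutated_positions")
  repertoire_dataset(records,
                     provenance = sprintf(
                       "simulate_repertoire: %d clonotypes from %d germlines, base_rate %g, seed %s",
                       n_clonotypes, nrow(library$sequences),
                       params$base_rate, format(seed)),
                     germline_reference = library$sequences,
                     ground_truth = gt)
}

#' Write the simulation ground truth as TSV
#'
#' @param dataset A simulated `repertoire_dataset`.
#' @param path Output path. Columns: clonotype_id, germline_id, n_mutations,
#'   mutated_positions (comma-separated).
#' @export
write_ground_truth <- function(dataset, path) {
  gt <- dataset$ground_truth
  if (is.null(gt)) stop_contract("dataset carries no ground truth")
  out <- gt
  out$mutated_positions <- vapply(gt$mutated_positions, paste,
                                  character(1), collapse = ",")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Plant a peptide into a subset of repertoire records
#'
#' Overwrites the residues at a fixed position in the chosen records with a
#' given peptide — a test construction that pins a motif's molecule count
#' (and hence its frequency class) exactly. Simulation ground truth is not
#' updated; this is a planting tool for frequency-spectrum checks, not a
#' mutation model.
#'
#' @param dataset A `repertoire_dataset`.
#' @param peptide Residue string to plant.
#' @param at 1-based start position.
#' @param record_ids Ids of the records to modify.
#' @return The modified `repertoire_dataset`.
#' @export
plant_peptide <- function(dataset, peptide, at, record_ids) {
  stopifnot(inherits(dataset, "repertoire_dataset"))
  peptide <- toupper(peptide)
  at <- check_scalar_count(at, "at")
  idx <- match(record_ids, dataset$records$id)
  if (anyNA(idx))
    stop_contract("unknown record id(s): ",
                  paste(record_ids[is.na(idx)], collapse = ", "))
  end <- at + nchar(peptide) - 1L
  if (any(nchar(dataset$records$residues[idx]) < end))
    stop_contract("peptide does not fit at position ", at)
  substr(dataset$records$residues[idx], at, end) <- peptide
  validate_records(dataset$records)
  dataset$provenance <- c(dataset$provenance,
                          sprintf("plant_peptide: '%s' at %d in %d record(s)",
                                  peptide, at, length(idx)))
  dataset
}
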