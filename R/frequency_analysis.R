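#' @import data.table
NULL

# All k-windows of all records, quietly skipping records shorter than k and
# windows containing X. Returns a data.table(id, start, residues).
all_windows <- function(records, k) {
  n_win <- pmax(nchar(records$residues) - k + 1L, 0L)
  id <- rep(records$id, n_win)
  seq_res <- rep(records$residues, n_win)
  start <- unlist(lapply(n_win, seq_len), use.names = FALSE)
  if (is.null(start)) start <- integer(0)
  residues <- substring(seq_res, start, start + k - 1L)
  dt <- data.table::data.table(id = id, start = as.integer(start),
                               residues = residues)
  dt[!grepl("X", residues, fixed = TRUE)]
}

new_motif_frequency_table <- function(register, entries, positions,
                                      total_molecules, total_instances) {
  structure(list(register = register, entries = entries,
                 positions = positions,
                 total_molecules = as.integer(total_molecules),
                 total_instances = as.integer(total_instances)),
            class = "motif_frequency_table")
}

#' Count motif re-use across a repertoire
#'
#' Extracts the register's motif from every non-skipped window of every
#' record and tabulates, per unique motif: `molecule_count` (distinct records
#' containing it at least once), `instance_count` (total window occurrences)
#' and a per-start-position occurrence histogram.
#'
#' @param dataset A `repertoire_dataset` (or bare `tcem_records`).
#' @param register Register name or definition (see [motif_registers()]).
#' @return A `motif_frequency_table` with fields `register`, `entries`
#'   (data.table: motif, molecule_count, instance_count), `positions`
#'   (data.table: motif, start, count), `total_molecules`, `total_instances`.
#' @export
build_frequency_table <- function(dataset, register) {
  records <- if (inherits(dataset, "repertoire_dataset")) dataset$records
             else dataset
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop_contract("empty dataset")
  register <- as_register(register)
  win <- all_windows(records, register$window_length)
  win[, motif := extract_motif_letters(residues, register)]
  entries <- win[, .(molecule_count = data.table::uniqueN(id),
                     instance_count = .N), by = motif]
  data.table::setkey(entries, motif)
  positions <- win[, .(count = .N), by = .(motif, start)]
  new_motif_frequency_table(register = register$name, entries = entries,
                            positions = positions,
                            total_molecules = nrow(records),
                            total_instances = nrow(win))
}

#' @export
print.motif_frequency_table <- function(x, ...) {
  cat(sprintf("<motif_frequency_table> %s: %d unique motifs, %d instances in %d molecules\n",
              x$register, nrow(x$entries), x$total_instances,
              x$total_molecules))
  invisible(x)
}

#' Assign a reciprocal base-2 frequency class
#'
#' A motif found in a fraction `f = molecule_count / total_molecules` of
#' repertoire molecules gets class `ceiling(-log2(f))`, computed exactly in
#' integer arithmetic: exact powers of two keep their exponent (1/4 -> FC2,
#' 1/1024 -> FC10), a motif present in every molecule is FC0, and a singleton
#' among 39,982 molecules is FC16. Equivalently, FC k means the motif is
#' shared by about 1 in 2^k clonotypes.
#'
#' @param molecule_count Number of distinct molecules containing the motif
#'   (vectorized), each >= 1.
#' @param total_molecules Total molecules in the repertoire.
#' @param instance_count,total_instances Optional: supply both to classify on
#'   instance fractions instead of molecule fractions.
#' @return Integer vector of frequency classes.
#' @export
assign_frequency_class <- function(molecule_count, total_molecules,
                                   instance_count = NULL,
                                   total_instances = NULL) {
  if (!is.null(instance_count)) {
    if (is.null(total_instances))
      stop_contract("instance-based classification needs `total_instances`")
    molecule_count <- instance_count
    total_molecules <- total_instances
  }
  total_molecules <- check_scalar_count(total_molecules, "total_molecules")
  m <- as.numeric(molecule_count)
  if (length(m) == 0L) return(integer(0))
  if (anyNA(m) || any(m < 1) || any(m != floor(m)))
    stop_contract("`molecule_count` must be positive integers")
  if (any(m > total_molecules))
    stop_contract("`molecule_count` cannot exceed `total_molecules`")
  fc <- pmax(0, ceiling(log2(total_molecules / m) - 1e-9))
  # integer-exact adjustment of any floating-point boundary cases
  repeat {
    low <- m * 2^fc < total_molecules
    if (!any(low)) break
    fc[low] <- fc[low] + 1
  }
  repeat {
    high <- fc > 0 & m * 2^(fc - 1) >= total_molecules
    if (!any(high)) break
    fc[high] <- fc[high] - 1
  }
  as.integer(fc)
}

#' Frequency-class histogram of a motif table
#'
#' Bins the table's unique motifs by frequency class and reports, per class:
#' the unique-motif count, the frequency-weighted count (total instances),
#' and the cumulative weighted fraction. The `midpoint_fc` attribute is the
#' smallest class at which the cumulative weighted fraction reaches 0.5.
#'
#' @param table A `motif_frequency_table`.
#' @return A data frame (fc, unique_count, weighted_count,
#'   cumulative_fraction) with attribute `midpoint_fc`.
#' @export
fc_histogram <- function(table) {
  stopifnot(inherits(table, "motif_frequency_table"))
  ent <- table$entries
  if (nrow(ent) == 0L) stop_contract("empty motif table")
  fc <- assign_frequency_class(ent$molecule_count, table$total_molecules)
  agg <- data.table::data.table(fc = fc, w = ent$instance_count)[
    , .(unique_count = .N, weighted_count = sum(w)), by = fc]
  data.table::setorder(agg, fc)
  out <- as.data.frame(agg)
  out$cumulative_fraction <- cumsum(out$weighted_count) /
    sum(out$weighted_count)
  attr(out, "midpoint_fc") <- out$fc[which(out$cumulative_fraction >= 0.5)[1]]
  out
}

# Unique motif letters present anywhere in a germline reference, per register.
germline_motif_set <- function(germline_reference, register) {
  register <- as_register(register)
  if (is.null(germline_reference) || nrow(germline_reference) == 0L)
    stop_contract("germline reference is empty")
  win <- all_windows(germline_reference, register$window_length)
  unique(extract_motif_letters(win$residues, register))
}

#' Attribute motifs to germline or somatic-hypermutation origin
#'
#' A motif is germline-origin iff its letters occur (same register, any
#' position) in any germline reference sequence; every other motif is the
#' product of somatic hypermutation (SHM).
#'
#' @param table A `motif_frequency_table`.
#' @param germline_reference `tcem_records` of germline sequences; defaults
#'   to the dataset's own reference when the table was built from a
#'   `repertoire_dataset` carrying one.
#' @return Data frame with columns `motif`, `origin` (factor
#'   germline/SHM).
#' @export
attribute_origin <- function(table, germline_reference) {
  stopifnot(inherits(table, "motif_frequency_table"))
  gl <- germline_motif_set(germline_reference, table$register)
  data.frame(motif = table$entries$motif,
             origin = factor(ifelse(table$entries$motif %in% gl,
                                    "germline", "SHM"),
                             levels = c("germline", "SHM")),
             stringsAsFactors = FALSE)
}

#' Unique motif counts per aligned position
#'
#' For repertoires on a common coordinate system (fixed-length or truncated
#' records), counts the unique motifs whose window center falls at each
#' position; the center of a 15-mer starting at s is s + 7, of a 9-mer
#' s + 4. Optionally restricted to germline- or SHM-origin motifs.
#'
#' @param dataset A `repertoire_dataset`.
#' @param register Register name or definition.
#' @param origin Optional `"germline"` or `"SHM"` filter.
#' @param germline_reference Germline records; defaults to
#'   `dataset$germline_reference`. Required when `origin` is given.
#' @return Data frame (position, unique_count), one row per occupied center
#'   position.
#' @export
per_position_unique_motifs <- function(dataset, register, origin = NULL,
                                       germline_reference = NULL) {
  records <- if (inherits(dataset, "repertoire_dataset")) dataset$records
             else dataset
  register <- as_register(register)
  win <- all_windows(records, register$window_length)
  if (nrow(win) == 0L)
    return(data.frame(position = integer(), unique_count = integer()))
  win[, motif := extract_motif_letters(residues, register)]
  win[, position := start + register$window_length %/% 2L]
  if (!is.null(origin)) {
    origin <- match.arg(origin, c("germline", "SHM"))
    if (is.null(germline_reference) &&
        inherits(dataset, "repertoire_dataset"))
      germline_reference <- dataset$germline_reference
    gl <- germline_motif_set(germline_reference, register)
    keep <- if (origin == "germline") win$motif %in% gl
            else !win$motif %in% gl
    win <- win[keep]
  }
  agg <- win[, .(unique_count = data.table::uniqueN(motif)), by = position]
  data.table::setorder(agg, position)
  as.data.frame(agg)
}

#' Fraction of unique class II motifs co-located with a unique partner motif
#'
#' Each 15-mer window carries both a TCEM IIa and a TCEM IIb; when both are
#' unique in the repertoire the co-located pair forms a hexamer engaging two
#' distinct T-cell populations. "Unique" means found in exactly one molecule
#' of the repertoire.
#'
#' @param dataset A `repertoire_dataset`.
#' @param from,to Register names of the anchor and partner motif
#'   (defaults TCEM_IIA / TCEM_IIB; swap for the symmetric variant).
#' @param count_by `"motif"`: fraction of unique `from` motifs with at least
#'   one window whose `to` motif is also unique; `"window"`: fraction over
#'   window occurrences of unique `from` motifs.
#' @return A fraction in \[0, 1\]; 0 with a warning when the repertoire has
#'   no unique `from` motifs.
#' @export
colocalization_fraction <- function(dataset, from = "TCEM_IIA",
                                    to = "TCEM_IIB",
                                    count_by = c("motif", "window")) {
  count_by <- match.arg(count_by)
  records <- if (inherits(dataset, "repertoire_dataset")) dataset$records
             else dataset
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop_contract("empty dataset")
  from <- as_register(from); to <- as_register(to)
  if (from$window_length != to$window_length)
    stop_contract("`from` and `to` registers must share a window length")
  win <- all_windows(records, from$window_length)
  win[, a := extract_motif_letters(residues, from)]
  win[, b := extract_motif_letters(residues, to)]
  uniq_a <- win[, .(n_mol = data.table::uniqueN(id)), by = a][n_mol == 1L, a]
  uniq_b <- win[, .(n_mol = data.table::uniqueN(id)), by = b][n_mol == 1L, b]
  sel <- win[a %in% uniq_a]
  if (nrow(sel) == 0L) {
    warning("no unique '", from$name, "' motifs in the repertoire; ",
            "co-location fraction undefined, returning 0")
    return(0)
  }
  sel[, partner_unique := b %in% uniq_b]
  if (count_by == "window") return(mean(sel$partner_unique))
  mean(sel[, .(any_unique = any(partner_unique)), by = a]$any_unique)
}

#' Overlap between two motif sets
#'
#' Intersection of the unique motif letters of two tables of the same
#' register (e.g. variable regions vs. constant regions, or an
#' immunoglobulin set vs. a proteome).
#'
#' @param tableA,tableB `motif_frequency_table`s of the same register.
#' @return List with `shared_fraction_of_A`, `shared_fraction_of_B`,
#'   `shared_count`.
#' @export
motif_set_overlap <- function(tableA, tableB) {
  stopifnot(inherits(tableA, "motif_frequency_table"),
            inherits(tableB, "motif_frequency_table"))
  if (tableA$register != tableB$register)
    stop_contract("register mismatch: ", tableA$register, " vs ",
                  tableB$register)
  a <- tableA$entries$motif; b <- tableB$entries$motif
  shared <- length(intersect(a, b))
  list(shared_fraction_of_A = if (length(a)) shared / length(a) else 0,
       shared_fraction_of_B = if (length(b)) shared / length(b) else 0,
       shared_count = shared)
}

#' Look up frequency classes of query motifs in a reference table
#'
#' Assigns each query motif the frequency class it holds in a reference
#' repertoire (e.g. classifying an arbitrary protein's motifs against an
#' immunoglobulin-derived table). Motifs absent from the reference are
#' flagged unclassified.
#'
#' @param query_table,reference_table `motif_frequency_table`s of the same
#'   register.
#' @return Data frame (motif, fc, unclassified) with attribute
#'   `unclassified_fraction`.
#' @export
map_fc_from_reference <- function(query_table, reference_table) {
  stopifnot(inherits(query_table, "motif_frequency_table"),
            inherits(reference_table, "motif_frequency_table"))
  if (query_table$register != reference_table$register)
    stop_contract("register mismatch: ", query_table$register, " vs ",
                  reference_table$register)
  ref <- reference_table$entries
  ref_fc <- assign_frequency_class(ref$molecule_count,
                                   reference_table$total_molecules)
  idx <- match(query_table$entries$motif, ref$motif)
  out <- data.frame(motif = query_table$entries$motif,
                    fc = ref_fc[idx],
                    unclassified = is.na(idx),
                    stringsAsFactors = FALSE)
  attr(out, "unclassified_fraction") <-
    if (nrow(out)) mean(out$unclassified) else 0
  out
}

#' Pearson correlation of germline usage fractions
#'
#' Compares observed germline usage (e.g. from a simulated or curated
#' repertoire) against a reference usage profile over the germline ids both
#' share.
#'
#' @param observed_usage,reference_usage Named numeric vectors of usage
#'   fractions keyed by germline id.
#' @return Pearson correlation coefficient over the shared ids (>= 3
#'   required).
#' @export
usage_correlation <- function(observed_usage, reference_usage) {
  shared <- intersect(names(observed_usage), names(reference_usage))
  if (length(shared) < 3L)
    stop_contract("need at least 3 shared germline ids, got ",
                  length(shared))
  cor(as.numeric(observed_usage[shared]),
      as.numeric(reference_usage[shared]), method = "pearson")
}
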