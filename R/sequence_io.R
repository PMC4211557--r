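IG_CLASSES <- c("IgG", "IgM", "IgE", "IgA", "IgD", "unknown")

#' Construct a set of sequence records
#'
#' The basic sequence container is a data frame with one row per record and
#' columns `id`, `description`, `residues`, `class_label`, `is_germline`.
#' Residues are upper-cased and validated against the 20-letter amino-acid
#' alphabet plus `X` (ambiguous).
#'
#' @param id Character vector of unique accession-like identifiers.
#' @param residues Character vector of amino-acid strings.
#' @param description Free-text descriptions (recycled).
#' @param class_label Immunoglobulin class, one of
#'   `r paste(IG_CLASSES, collapse = ", ")` (recycled).
#' @param is_germline Logical, marks germline reference sequences (recycled).
#' @return A `tcem_records` data frame.
#' @export
sequence_records <- function(id, residues, description = "",
                             class_label = "unknown", is_germline = FALSE) {
  if (length(id) != length(residues))
    stop_contract("`id` and `residues` must have the same length")
  df <- data.frame(id = as.character(id),
                   description = rep_len(as.character(description), length(id)),
                   residues = toupper(as.character(residues)),
                   class_label = rep_len(as.character(class_label), length(id)),
                   is_germline = rep_len(as.logical(is_germline), length(id)),
                   stringsAsFactors = FALSE)
  # raw record sets may carry duplicate ids; curate()/repertoire_dataset()
  # enforce uniqueness at the dataset level
  validate_records(df, allow_duplicate_ids = TRUE)
  class(df) <- c("tcem_records", "data.frame")
  df
}

validate_records <- function(df, allow_duplicate_ids = FALSE) {
  if (nrow(df) == 0L) return(invisible(df))
  if (anyNA(df$id) || any(!nzchar(df$id)))
    stop_contract("record ids must be non-empty strings")
  if (!allow_duplicate_ids && anyDuplicated(df$id))
    stop_contract("duplicate record ids: ",
                  paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  if (any(!nzchar(df$residues)))
    stop_contract("residues must be non-empty")
  bad <- grepl(sprintf("[^%sX]", paste(AA_ALPHABET, collapse = "")),
               df$residues)
  if (any(bad))
    stop_contract("invalid residue characters in record(s): ",
                  paste(head(df$id[bad], 5), collapse = ", "))
  if (any(!df$class_label %in% IG_CLASSES))
    stop_contract("class_label must be one of: ",
                  paste(IG_CLASSES, collapse = ", "))
  invisible(df)
}

# Accept a one-row tcem_records data frame, a list(id=, residues=), or a bare
# residue string, and return list(id, residues).
as_record <- function(record) {
  if (is.character(record) && length(record) == 1L)
    return(list(id = "seq1", residues = toupper(record)))
  if (is.data.frame(record)) {
    if (nrow(record) != 1L)
      stop_contract("expected a single sequence record, got ", nrow(record))
    return(list(id = record$id[[1]], residues = record$residues[[1]]))
  }
  if (is.list(record) && !is.null(record$residues))
    return(list(id = if (is.null(record$id)) "seq1" else record$id,
                residues = toupper(record$residues)))
  stop_contract("cannot interpret `record` as a sequence record")
}

#' Read protein sequences from a FASTA file
#'
#' The header token before the first whitespace becomes the record id, the
#' remainder the description; residues are upper-cased and validated against
#' the amino-acid alphabet (20 letters plus X). A `class=IgG` style token in
#' the description sets the class label; a `germline` token marks germline
#' records.
#'
#' @param path Path to a FASTA file.
#' @return A `tcem_records` data frame, one row per FASTA entry.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_contract("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || all(!nzchar(trimws(lines)))) {
    warning("empty FASTA file: ", path)
    return(sequence_records(character(), character()))
  }
  header_lines <- grep("^>", lines)
  if (length(header_lines) == 0L || header_lines[1] != which(nzchar(trimws(lines)))[1])
    stop_contract("FASTA parse error at line ",
                  which(nzchar(trimws(lines)))[1], ": expected '>' header")
  # validate residue lines up front: readAAStringSet silently drops codes
  # outside its alphabet, which would mask the error contract
  seq_lines <- setdiff(which(nzchar(trimws(lines))), header_lines)
  bad_line <- seq_lines[grepl(sprintf("[^%sXx%s]",
                                      paste(AA_ALPHABET, collapse = ""),
                                      paste(tolower(AA_ALPHABET),
                                            collapse = "")),
                              trimws(lines[seq_lines]))]
  if (length(bad_line))
    stop_contract(sprintf(
      "FASTA parse error at line %d: characters outside the amino-acid alphabet",
      bad_line[1]))
  set <- tryCatch(
    suppressWarnings(Biostrings::readAAStringSet(path)),
    error = function(e) stop_contract("FASTA parse error in ", path, ": ",
                                      conditionMessage(e)))
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- trimws(sub("^\\S+\\s*", "", headers))
  residues <- toupper(as.character(set))
  bad <- grep(sprintf("[^%sX]", paste(AA_ALPHABET, collapse = "")), residues)
  if (length(bad)) {
    i <- bad[1]
    stop_contract(sprintf(
      "FASTA parse error: entry '%s' (starting at line %d) contains characters outside the amino-acid alphabet",
      ids[i], header_lines[i]))
  }
  cls <- rep("unknown", length(ids))
  m <- regmatches(desc, regexpr("class=(Ig[GMEAD])", desc))
  has <- grepl("class=Ig[GMEAD]", desc)
  cls[has] <- sub("class=", "", m)
  sequence_records(id = ids, residues = residues, description = desc,
                   class_label = cls,
                   is_germline = grepl("\\bgermline\\b", desc,
                                       ignore.case = TRUE))
}

#' Write sequence records to FASTA
#'
#' @param records A `tcem_records` data frame.
#' @param path Output path.
#' @param width Line-wrap width for residues (default 60).
#' @export
write_fasta <- function(records, path, width = 60) {
  set <- Biostrings::AAStringSet(setNames(records$residues, records$id))
  hdr <- ifelse(nzchar(records$description),
                paste(records$id, records$description), records$id)
  names(set) <- hdr
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Curate a record set into a repertoire dataset
#'
#' Mirrors the standard preparation of variable-region sets: sequences longer
#' than `max_length` residues are truncated to their first `max_length`
#' (IMGT-style fixed coordinates), and duplicate ids are removed keeping the
#' first occurrence. Counts of truncations and removals are recorded in the
#' dataset provenance.
#'
#' @param records A `tcem_records` data frame.
#' @param max_length Truncation length in residues (default 130); `Inf`
#'   disables truncation.
#' @param deduplicate Remove records with duplicate ids (default TRUE).
#' @param dedup_by_sequence Additionally remove records whose full residue
#'   string duplicates an earlier record (default FALSE; id-level
#'   deduplication is the standard behaviour).
#' @return A `repertoire_dataset`.
#' @export
curate <- function(records, max_length = 130, deduplicate = TRUE,
                   dedup_by_sequence = FALSE) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop_contract("`records` must be a non-empty record set")
  validate_records(records, allow_duplicate_ids = TRUE)
  n_in <- nrow(records)
  removed <- 0L
  if (deduplicate) {
    keep <- !duplicated(records$id)
    if (dedup_by_sequence) keep <- keep & !duplicated(records$residues)
    removed <- sum(!keep)
    records <- records[keep, , drop = FALSE]
  }
  truncated <- 0L
  if (is.finite(max_length)) {
    long <- nchar(records$residues) > max_length
    truncated <- sum(long)
    records$residues[long] <- substr(records$residues[long], 1L, max_length)
  }
  if (nrow(records) == 0L) stop_contract("empty after curation")
  rownames(records) <- NULL
  class(records) <- c("tcem_records", "data.frame")
  repertoire_dataset(
    records,
    max_length_applied = if (is.finite(max_length)) max_length else NA,
    provenance = sprintf(
      "curate: %d records in, %d duplicate id(s) removed, %d truncated to %s residues",
      n_in, removed, truncated, format(max_length)))
}

#' Construct a repertoire dataset
#'
#' @param records A `tcem_records` data frame (unique ids).
#' @param max_length_applied Truncation length that has been applied, or NA.
#' @param provenance Free-text provenance lines.
#' @param germline_reference Optional `tcem_records` of germline sequences.
#' @param ground_truth Optional per-clonotype simulation ground truth (see
#'   [simulate_repertoire()]).
#' @return A `repertoire_dataset` list object.
#' @export
repertoire_dataset <- function(records, max_length_applied = NA,
                               provenance = character(),
                               germline_reference = NULL,
                               ground_truth = NULL) {
  validate_records(records)
  if (!is.na(max_length_applied) &&
      any(nchar(records$residues) > max_length_applied))
    stop_contract("record(s) longer than max_length_applied")
  if (!is.null(germline_reference)) validate_records(germline_reference)
  structure(list(records = records,
                 max_length_applied = max_length_applied,
                 provenance = provenance,
                 germline_reference = germline_reference,
                 ground_truth = ground_truth),
            class = "repertoire_dataset")
}

#' @export
print.repertoire_dataset <- function(x, ...) {
  cat(sprintf("<repertoire_dataset> %d record(s)", nrow(x$records)))
  if (!is.na(x$max_length_applied))
    cat(sprintf(", max length %d", as.integer(x$max_length_applied)))
  if (!is.null(x$germline_reference))
    cat(sprintf(", %d germline reference(s)", nrow(x$germline_reference)))
  cat("\n")
  for (p in x$provenance) cat(" ", p, "\n")
  invisible(x)
}

#' Write a motif frequency table to TSV
#'
#' Writes one row per unique motif with columns `motif`, `register`,
#' `molecule_count`, `instance_count`, `frequency_class`, `origin`, in stable
#' lexicographic motif order. Table totals are preserved in `#`-prefixed
#' header comments so the file round-trips through [read_motif_table()].
#'
#' @param table A `motif_frequency_table` from [build_frequency_table()].
#' @param path Output path.
#' @param origin Optional origin attribution from [attribute_origin()]
#'   (a data frame with columns `motif`, `origin`); defaults to `NA`.
#' @export
write_motif_table <- function(table, path, origin = NULL) {
  stopifnot(inherits(table, "motif_frequency_table"))
  ent <- as.data.frame(table$entries)
  ent <- ent[order(ent$motif), , drop = FALSE]
  out <- data.frame(motif = ent$motif,
                    register = rep(table$register, nrow(ent)),
                    molecule_count = ent$molecule_count,
                    instance_count = ent$instance_count,
                    frequency_class = if (nrow(ent))
                      assign_frequency_class(ent$molecule_count,
                                             table$total_molecules)
                    else integer(),
                    origin = rep(NA_character_, nrow(ent)),
                    stringsAsFactors = FALSE)
  if (!is.null(origin) && nrow(ent))
    out$origin <- origin$origin[match(out$motif, origin$motif)]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# register=%s total_molecules=%d total_instances=%d",
                     table$register, table$total_molecules,
                     table$total_instances), con)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a motif frequency table written by [write_motif_table()]
#'
#' @param path Path to a TSV produced by [write_motif_table()].
#' @return A `motif_frequency_table` (without position histograms, which are
#'   not serialized).
#' @export
read_motif_table <- function(path) {
  if (!file.exists(path)) stop_contract("file not found: ", path)
  hdr <- readLines(path, n = 1L)
  if (!grepl("^# register=", hdr))
    stop_contract("not a motif table (missing '# register=' header): ", path)
  meta <- regmatches(hdr, gregexpr("[a-z_]+=\\S+", hdr))[[1]]
  kv <- setNames(sub("^[a-z_]+=", "", meta), sub("=.*$", "", meta))
  df <- read.delim(path, comment.char = "#", sep = "\t",
                   stringsAsFactors = FALSE,
                   colClasses = c(motif = "character"))
  ent <- data.table::data.table(motif = as.character(df$motif),
                                molecule_count = as.integer(df$molecule_count),
                                instance_count = as.integer(df$instance_count))
  new_motif_frequency_table(register = kv[["register"]], entries = ent,
                            positions = NULL,
                            total_molecules = as.integer(kv[["total_molecules"]]),
                            total_instances = as.integer(kv[["total_instances"]]))
}
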