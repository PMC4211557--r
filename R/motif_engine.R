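#' Enumerate peptide windows of a sequence
#'
#' Breaks a sequence into all k-mers offset by a single residue. Windows
#' containing the ambiguity character `X` are flagged `skip = TRUE` and are
#' excluded from motif extraction and counting downstream.
#'
#' @param record A single sequence record (one-row `tcem_records`, a
#'   `list(id=, residues=)`, or a bare residue string).
#' @param k Window length: 8 (cleavage octamers), 9 (class I) or 15 (class II).
#' @return A `peptide_windows` data frame with columns `parent_id`, `start`
#'   (1-based), `length`, `residues`, `skip`. A record shorter than `k`
#'   yields zero windows with a warning.
#' @export
enumerate_windows <- function(record, k) {
  if (!k %in% c(8L, 9L, 15L))
    stop_contract("`k` must be one of 8, 9, 15")
  rec <- as_record(record)
  L <- nchar(rec$residues)
  if (L < k) {
    warning(sprintf("record '%s' (length %d) shorter than window length %d",
                    rec$id, L, k))
    starts <- integer(0)
  } else {
    starts <- seq_len(L - k + 1L)
  }
  residues <- if (length(starts))
    substring(rec$residues, starts, starts + k - 1L) else character(0)
  out <- data.frame(parent_id = rep(rec$id, length(starts)),
                    start = starts,
                    length = rep(as.integer(k), length(starts)),
                    residues = residues,
                    skip = grepl("X", residues, fixed = TRUE),
                    stringsAsFactors = FALSE)
  class(out) <- c("peptide_windows", "data.frame")
  out
}

# Vectorized extraction of register letters from a character vector of
# windows (all of the register's window length). The motif-counting hot path.
extract_motif_letters <- function(windows, register) {
  register <- as_register(register)
  if (length(windows) == 0L) return(character())
  do.call(paste0, lapply(register$positions, function(p) substr(windows, p, p)))
}

# Gapped display: one "~" for every run of skipped positions between
# consecutive mask positions (so TCEM_IIB renders its leading -1 gap as a
# single tilde, e.g. "N~I~W~RQ").
motif_display <- function(letters, register) {
  register <- as_register(register)
  pos <- register$positions
  chars <- strsplit(letters, "")
  vapply(chars, function(cc) {
    out <- cc[1]
    for (j in seq_along(pos)[-1]) {
      if (pos[j] - pos[j - 1L] > 1L) out <- c(out, "~")
      out <- c(out, cc[j])
    }
    paste(out, collapse = "")
  }, character(1))
}

#' Extract a motif from a peptide window
#'
#' Pulls the register's positions out of the window in N-to-C order. The
#' `display` rendering marks skipped positions with `~`, e.g. the TCEM IIa of
#' `FSNYAIHWVRQAPGQ` is `AIWRQ`, displayed `AI~W~RQ`.
#'
#' @param window A window (one row of [enumerate_windows()] output, or a bare
#'   string of the register's window length).
#' @param register Register name (see [motif_registers()]) or definition.
#' @return A `tcem_motif` list with elements `register`, `letters`, `display`.
#' @export
extract_motif <- function(window, register) {
  register <- as_register(register)
  if (is.data.frame(window)) {
    if (nrow(window) != 1L) stop_contract("expected a single window")
    if (isTRUE(window$skip))
      stop_contract("window is flagged skip (contains X)")
    window <- window$residues
  }
  if (nchar(window) != register$window_length)
    stop_contract(sprintf("window length %d does not match register %s (%d)",
                          nchar(window), register$name,
                          register$window_length))
  letters <- extract_motif_letters(window, register)
  structure(list(register = register$name, letters = letters,
                 display = motif_display(letters, register)),
            class = "tcem_motif")
}

#' @export
print.tcem_motif <- function(x, ...) {
  cat(sprintf("<%s> %s (%s)\n", x$register, x$letters, x$display))
  invisible(x)
}

#' Central 9-mer core of a 15-mer window
#'
#' Class II registers are numbered on the central 9-mer core of a 15-mer
#' (window positions 4--12). This returns that core, with the start index
#' shifted by +3 when a window row is supplied.
#'
#' @param window A length-15 window (row or string).
#' @return The 9-mer core in the same shape as the input.
#' @export
central_core <- function(window) {
  if (is.data.frame(window)) {
    if (nrow(window) != 1L) stop_contract("expected a single window")
    if (window$length != 15L) stop_contract("central_core requires a 15-mer")
    window$start <- window$start + CORE_OFFSET
    window$length <- 9L
    window$residues <- substr(window$residues, 4L, 12L)
    window$skip <- grepl("X", window$residues, fixed = TRUE)
    return(window)
  }
  if (nchar(window) != 15L) stop_contract("central_core requires a 15-mer")
  substr(window, 4L, 12L)
}

#' Cleavage-site octamer around a scissile bond
#'
#' Endosomal cathepsins recognize the octamer spanning four residues either
#' side of a scissile bond (P4..P1 | P1'..P4'). `bond_after = i` denotes the
#' bond between residues `i` and `i + 1`; the octamer is residues
#' `i - 3 .. i + 4`, with the bond between octamer positions 4 and 5.
#'
#' @param record A single sequence record.
#' @param bond_after 1-based index of the residue N-terminal to the bond;
#'   must satisfy `4 <= bond_after <= length - 4`.
#' @return A one-row `peptide_windows` data frame of length 8.
#' @export
cleavage_site_octomer <- function(record, bond_after) {
  rec <- as_record(record)
  L <- nchar(rec$residues)
  bond_after <- check_scalar_count(bond_after, "bond_after")
  if (bond_after < 4 || bond_after > L - 4)
    stop_contract(sprintf(
      "bond_after = %d too close to a terminus (need 4 <= bond <= %d)",
      bond_after, L - 4))
  res <- substr(rec$residues, bond_after - 3L, bond_after + 4L)
  out <- data.frame(parent_id = rec$id, start = as.integer(bond_after - 3L),
                    length = 8L, residues = res,
                    skip = grepl("X", res, fixed = TRUE),
                    stringsAsFactors = FALSE)
  class(out) <- c("peptide_windows", "data.frame")
  out
}

#' Map every residue to its overlapping recognition frames
#'
#' For each binding-peptide window of a sequence, every residue inside the
#' window plays a TCEM or GEM role in each register, and the four residues
#' flanking either end of the window sit in the cathepsin cleavage octamers
#' that excise it (`CSO_position`). The full influence span of one binding
#' peptide is therefore 4 + 15 + 4 = 23 residues for class II, or
#' 4 + 9 + 4 = 17 for class I, and an interior residue participates in 23
#' (resp. 17) distinct overlapping spans: its own plus 22 (resp. 16) more.
#'
#' @param record A single sequence record.
#' @param mhc_class `"II"` (15-mer windows) or `"I"` (9-mer windows).
#' @return A `recognition_frame_map`: list with `parent_id`, `length`,
#'   `mhc_class`, `span`, and `entries` — one data frame per residue with
#'   columns `window_start`, `window_length`, `role`. A record shorter than
#'   the span yields an empty map with a warning.
#' @export
build_frame_map <- function(record, mhc_class = c("II", "I")) {
  mhc_class <- match.arg(as.character(mhc_class), c("II", "I"))
  rec <- as_record(record)
  L <- nchar(rec$residues)
  k <- if (mhc_class == "II") 15L else 9L
  span <- k + 8L
  empty <- structure(list(parent_id = rec$id, length = L,
                          mhc_class = mhc_class, span = span,
                          entries = rep(list(data.frame(
                            window_start = integer(), window_length = integer(),
                            role = character(), stringsAsFactors = FALSE)), L)),
                     class = "recognition_frame_map")
  if (L < span) {
    warning(sprintf("record '%s' (length %d) shorter than the %d-residue span",
                    rec$id, L, span))
    return(empty)
  }
  regs <- Filter(function(r) r$window_length == k, REGISTER_DEFS)
  starts <- seq_len(L - k + 1L)
  res_idx <- integer(0); w_start <- integer(0); role <- character(0)
  for (r in regs) {
    for (p in r$positions) {
      res_idx <- c(res_idx, starts + p - 1L)
      w_start <- c(w_start, starts)
      role <- c(role, rep(r$name, length(starts)))
    }
  }
  # CSO flanks: residues s-4..s-1 and s+k..s+k+3, clipped to the sequence
  for (off in c(-4:-1, k:(k + 3L))) {
    idx <- starts + off
    ok <- idx >= 1L & idx <= L
    res_idx <- c(res_idx, idx[ok])
    w_start <- c(w_start, starts[ok])
    role <- c(role, rep("CSO_position", sum(ok)))
  }
  all <- data.frame(residue = res_idx, window_start = w_start,
                    window_length = k, role = role, stringsAsFactors = FALSE)
  all <- all[order(all$residue, all$window_start, all$role), ]
  entries <- empty$entries
  spl <- split(all[c("window_start", "window_length", "role")],
               factor(all$residue, levels = seq_len(L)))
  for (i in seq_len(L)) {
    rownames(spl[[i]]) <- NULL
    entries[[i]] <- spl[[i]]
  }
  structure(list(parent_id = rec$id, length = L, mhc_class = mhc_class,
                 span = span, entries = entries),
            class = "recognition_frame_map")
}

#' Number of influence spans containing a residue
#'
#' Counts the distinct binding-peptide windows in whose 23-residue (class II)
#' or 17-residue (class I) influence span the residue participates — as a
#' TCEM or GEM position inside the window or as a cleavage-octamer position
#' in its flanks. By default only complete spans count: a peptide whose
#' excision octamers would run past a terminus cannot be fully processed, so
#' the first residue of a record sits in exactly one complete class II span
#' while an interior residue sits in 23 (its own window's span plus 22 more).
#'
#' @param map A `recognition_frame_map` from [build_frame_map()].
#' @param residue 1-based residue index.
#' @param complete_only Count only windows whose full influence span (both
#'   4-residue cleavage flanks) lies within the sequence (default TRUE).
#' @return Integer count of distinct spans.
#' @export
frame_span_count <- function(map, residue, complete_only = TRUE) {
  stopifnot(inherits(map, "recognition_frame_map"))
  residue <- check_scalar_count(residue, "residue")
  if (residue > map$length) stop_contract("residue index out of range")
  starts <- unique(map$entries[[residue]]$window_start)
  if (complete_only) {
    k <- map$span - 8L
    starts <- starts[starts >= 5L & starts <= map$length - k - 3L]
  }
  length(starts)
}

#' @export
print.recognition_frame_map <- function(x, ...) {
  cat(sprintf("<recognition_frame_map> class %s, %d residues, span %d\n",
              x$mhc_class, x$length, x$span))
  invisible(x)
}
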