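# Independent brute-force oracles: plain nested loops over substr(), no use
# of the package's window/counting machinery.

# register position masks restated independently from first principles.
# Core position c of the central 9-mer (window 4-12) sits at window c + 3;
# "-1" denotes the residue immediately N-terminal of the core (no position
# 0 exists in this convention), i.e. window position 3. The mapping is
# confirmed by the printed worked example: TCEM IIb of FSNYAIHWVRQAPGQ is
# N~I~W~RQ, i.e. window positions 3,6,8,10,11.
core_to_window <- function(c) ifelse(c < 0, c + 4, c + 3)
ORACLE_MASKS <- list(
  TCEM_I   = list(k = 9L,  pos = c(4, 5, 6, 7, 8)),
  GEM_I    = list(k = 9L,  pos = c(1, 2, 3, 9)),
  TCEM_IIA = list(k = 15L, pos = core_to_window(c(2, 3, 5, 7, 8))),
  TCEM_IIB = list(k = 15L, pos = core_to_window(c(-1, 3, 5, 7, 8))),
  GEM_IIA  = list(k = 15L,
                  pos = setdiff(1:15, core_to_window(c(2, 3, 5, 7, 8)))),
  GEM_IIB  = list(k = 15L,
                  pos = setdiff(1:15, core_to_window(c(-1, 3, 5, 7, 8))))
)

oracle_extract <- function(window, register) {
  m <- ORACLE_MASKS[[register]]
  paste(vapply(m$pos, function(p) substr(window, p, p), character(1)),
        collapse = "")
}

# motif -> c(molecule_count, instance_count) via double loop
oracle_count_motifs <- function(records, register) {
  m <- ORACLE_MASKS[[register]]
  per_motif_instances <- list()
  per_motif_molecules <- list()
  total_instances <- 0L
  for (r in seq_len(nrow(records))) {
    seqres <- records$residues[r]
    L <- nchar(seqres)
    if (L < m$k) next
    for (s in 1:(L - m$k + 1)) {
      w <- substr(seqres, s, s + m$k - 1)
      if (grepl("X", w, fixed = TRUE)) next
      total_instances <- total_instances + 1L
      mo <- oracle_extract(w, register)
      per_motif_instances[[mo]] <- c(per_motif_instances[[mo]], 1L)
      per_motif_molecules[[mo]] <- union(per_motif_molecules[[mo]],
                                         records$id[r])
    }
  }
  motifs <- sort(names(per_motif_instances))
  data.frame(
    motif = motifs,
    molecule_count = vapply(motifs, function(mo)
      length(per_motif_molecules[[mo]]), integer(1)),
    instance_count = vapply(motifs, function(mo)
      sum(per_motif_instances[[mo]]), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

oracle_fc <- function(molecule_count, total) {
  k <- 0
  while (molecule_count * 2^k < total) k <- k + 1
  k
}

# per-residue role counts and complete-span counts by exhaustive enumeration
oracle_frame <- function(seqres, mhc_class) {
  k <- if (mhc_class == "II") 15L else 9L
  L <- nchar(seqres)
  masks <- Filter(function(m) m$k == k, ORACLE_MASKS)
  roles <- matrix(0L, nrow = L, ncol = length(masks) + 1L,
                  dimnames = list(NULL, c(names(masks), "CSO_position")))
  complete_spans <- integer(L)
  if (L < k) return(list(roles = roles, complete_spans = complete_spans))
  for (s in 1:(L - k + 1)) {
    for (nm in names(masks))
      for (p in masks[[nm]]$pos)
        roles[s + p - 1, nm] <- roles[s + p - 1, nm] + 1L
    for (i in c((s - 4):(s - 1), (s + k):(s + k + 3)))
      if (i >= 1 && i <= L)
        roles[i, "CSO_position"] <- roles[i, "CSO_position"] + 1L
    if (s - 4 >= 1 && s + k + 3 <= L) {
      for (i in (s - 4):(s + k + 3))
        complete_spans[i] <- complete_spans[i] + 1L
    }
  }
  list(roles = roles, complete_spans = complete_spans)
}

random_records <- function(n, len, seed, alphabet = aa_alphabet()) {
  set.seed(seed)
  sequence_records(
    id = sprintf("r%03d", seq_len(n)),
    residues = vapply(seq_len(n), function(i)
      paste(sample(alphabet, len, replace = TRUE), collapse = ""),
      character(1)))
}

sample_skewness <- function(v) mean((v - mean(v))^3) / sd(v)^3

# 15-mer whose TCEM IIa extraction is WWWWW; backgrounds built without W
# make the planted motif provably unique to the planted windows.
PLANT_15MER <- "AAAAWWAWAWWAAAA"
NO_W <- setdiff(aa_alphabet(), "W")
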