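#' Shared TCEM registers between two 15-mer peptides
#'
#' Compares two class II binding peptides register by register: the class I
#' TCEM is taken from the central 9-mer core (the convention used when class
#' I and class II motifs of the same 15-mer are compared), the class II
#' TCEMs from the full window. Two peptides differing only at a position
#' outside every TCEM mask — e.g. `FSNYAIHWVRQAPGQ` and its single-residue
#' variant `FTNYAIHWVRQAPGQ` — share all three TCEM registers while their
#' GEMs differ.
#'
#' @param peptide_a,peptide_b 15-residue peptide strings.
#' @return List with `shared` (named logical over TCEM_I, TCEM_IIA,
#'   TCEM_IIB), `n_shared`, and the two peptides' motifs.
#' @export
shared_tcem_registers <- function(peptide_a, peptide_b) {
  peptide_a <- toupper(peptide_a); peptide_b <- toupper(peptide_b)
  if (nchar(peptide_a) != 15L || nchar(peptide_b) != 15L)
    stop_contract("both peptides must be 15-mers")
  motifs <- function(p) list(
    TCEM_I = extract_motif(central_core(p), "TCEM_I"),
    TCEM_IIA = extract_motif(p, "TCEM_IIA"),
    TCEM_IIB = extract_motif(p, "TCEM_IIB"))
  ma <- motifs(peptide_a); mb <- motifs(peptide_b)
  shared <- vapply(names(ma), function(r)
    ma[[r]]$letters == mb[[r]]$letters, logical(1))
  list(shared = shared, n_shared = sum(shared),
       motifs_a = ma, motifs_b = mb)
}
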