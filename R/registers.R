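# The six motif registers. Positions are 1-based indices into the peptide
# window. Class II registers are defined on a 15-mer whose central 9-mer core
# is window positions 4-12; the field's conventional core numbering (2,3,5,7,8
# and -1,3,5,7,8, where -1 is the residue preceding core position 1) maps onto
# window positions by +3:
#   TCEM IIa: core 2,3,5,7,8   -> window 5,6,8,10,11
#   TCEM IIb: core -1,3,5,7,8  -> window 3,6,8,10,11
# GEM registers are the set complements within the window, so TCEM and GEM
# positions always partition the window.
REGISTER_DEFS <- local({
  defs <- list(
    TCEM_I   = list(window_length = 9L,  positions = c(4L, 5L, 6L, 7L, 8L)),
    GEM_I    = list(window_length = 9L,  positions = c(1L, 2L, 3L, 9L)),
    TCEM_IIA = list(window_length = 15L, positions = c(5L, 6L, 8L, 10L, 11L)),
    TCEM_IIB = list(window_length = 15L, positions = c(3L, 6L, 8L, 10L, 11L))
  )
  defs$GEM_IIA <- list(window_length = 15L,
                       positions = setdiff(1:15, defs$TCEM_IIA$positions))
  defs$GEM_IIB <- list(window_length = 15L,
                       positions = setdiff(1:15, defs$TCEM_IIB$positions))
  for (nm in names(defs)) defs[[nm]]$name <- nm
  defs
})

# Window positions of the central 9-mer core of a 15-mer.
CORE_OFFSET <- 3L
CORE_POSITIONS <- 4:12

#' Motif register definitions
#'
#' The six non-contiguous motif registers used throughout the package: the
#' T-cell exposed motifs (TCEM) of MHC class I 9-mers and class II 15-mers,
#' and their complementary groove-exposed motifs (GEM).
#'
#' \describe{
#'   \item{TCEM_I}{9-mer positions 4--8, the contiguous class I T-cell face.}
#'   \item{GEM_I}{9-mer positions 1,2,3,9, the class I anchor residues.}
#'   \item{TCEM_IIA}{15-mer positions 5,6,8,10,11 (core positions 2,3,5,7,8).}
#'   \item{TCEM_IIB}{15-mer positions 3,6,8,10,11 (core positions -1,3,5,7,8).}
#'   \item{GEM_IIA, GEM_IIB}{the 10-position window complements of the class II
#'     TCEMs, facing into the MHC groove.}
#' }
#'
#' @param name Optional register name; if given, the single definition is
#'   returned instead of the full list.
#' @return A named list of register definitions, each with elements `name`,
#'   `window_length` (9 or 15) and `positions` (1-based window indices).
#' @examples
#' motif_registers("TCEM_IIA")$positions
#' @export
motif_registers <- function(name = NULL) {
  if (is.null(name)) return(REGISTER_DEFS)
  name <- match.arg(toupper(name), names(REGISTER_DEFS))
  REGISTER_DEFS[[name]]
}

register_names <- function() names(REGISTER_DEFS)

as_register <- function(register) {
  if (is.list(register) && !is.null(register$positions)) return(register)
  motif_registers(register)
}

#' Size of the theoretical motif space
#'
#' Number of distinct motifs expressible over an alphabet: for the pentamer
#' TCEM registers this is 20^5 = 3,200,000; for the 10-residue class II GEM,
#' 20^10.
#'
#' @param alphabet_size Number of residue letters (20 for standard proteins).
#' @param motif_length Number of positions in the register.
#' @return The exact count, as a double (exact for all values below 2^53).
#' @examples
#' theoretical_motif_space(20, 5) # 3.2e6
#' @export
theoretical_motif_space <- function(alphabet_size, motif_length) {
  alphabet_size <- check_scalar_count(alphabet_size, "alphabet_size")
  motif_length <- check_scalar_count(motif_length, "motif_length")
  out <- alphabet_size^motif_length
  if (out >= 2^53)
    warning("motif space exceeds exact double-precision integer range")
  out
}
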