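#' @importFrom stats rnorm runif sd quantile cor setNames plogis
#' @importFrom utils head tail write.table read.delim
NULL

# The 20 standard amino acids, alphabetical one-letter codes.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Standard amino-acid alphabet
#'
#' @return Character vector of the 20 standard one-letter amino-acid codes.
#' @export
aa_alphabet <- function() AA_ALPHABET

# Physicochemical indices per residue, used by the surrogate predictors:
# Kyte-Doolittle hydropathy, van der Waals volume (A^3), Grantham polarity,
# net charge at pH 7, and normalized flexibility. Values are standard
# published scales; each column is z-scaled at load so surrogate weights act
# on comparable units.
aa_property_matrix <- local({
  hydropathy <- c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4,
                  H = -3.2, I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5,
                  P = -1.6, Q = -3.5, R = -4.5, S = -0.8, T = -0.7, V = 4.2,
                  W = -0.9, Y = -1.3)
  volume <- c(A = 88.6, C = 108.5, D = 111.1, E = 138.4, F = 189.9, G = 60.1,
              H = 153.2, I = 166.7, K = 168.6, L = 166.7, M = 162.9,
              N = 114.1, P = 112.7, Q = 143.8, R = 173.4, S = 89.0,
              T = 116.1, V = 140.0, W = 227.8, Y = 193.6)
  polarity <- c(A = 8.1, C = 5.5, D = 13.0, E = 12.3, F = 5.2, G = 9.0,
                H = 10.4, I = 5.2, K = 11.3, L = 4.9, M = 5.7, N = 11.6,
                P = 8.0, Q = 10.5, R = 10.5, S = 9.2, T = 8.6, V = 5.9,
                W = 5.4, Y = 6.2)
  charge <- c(A = 0, C = 0, D = -1, E = -1, F = 0, G = 0, H = 0.1, I = 0,
              K = 1, L = 0, M = 0, N = 0, P = 0, Q = 0, R = 1, S = 0,
              T = 0, V = 0, W = 0, Y = 0)
  flexibility <- c(A = 0.36, C = 0.35, D = 0.51, E = 0.50, F = 0.31,
                   G = 0.54, H = 0.32, I = 0.46, K = 0.47, L = 0.37,
                   M = 0.30, N = 0.46, P = 0.51, Q = 0.49, R = 0.53,
                   S = 0.51, T = 0.44, V = 0.39, W = 0.31, Y = 0.42)
  m <- cbind(hydropathy, volume, polarity, charge, flexibility)
  m <- m[AA_ALPHABET, ]
  scale(m)[, ]
})

# Deterministic 32-bit FNV-1a hash of the character representation of the
# arguments, folded into [1, 2^31 - 2]. Used to split one user seed into
# independent sub-streams (per clonotype, per ensemble member, ...) so
# generation order never matters.
derive_seed <- function(seed, ...) {
  txt <- paste(c(format(seed), vapply(list(...), format, character(1))),
               collapse = "\r")
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    # bitwXor needs < 2^31; folding the top bit keeps determinism
    h <- bitwXor(h %% 2147483648, b)
    # 32-bit overflow-safe multiply by the FNV prime 16777619 = 403 * 41623
    h <- (h * 403) %% 4294967296
    h <- (h * 41623) %% 4294967296
  }
  as.integer(h %% 2147483646) + 1L
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards, so library code never perturbs user
# randomness.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# shared argument checkers ---------------------------------------------------

stop_contract <- function(...) stop(..., call. = FALSE)

check_scalar_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x))
    stop_contract(sprintf("`%s` must be a single integer >= %d", name, min))
  as.numeric(x)
}
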