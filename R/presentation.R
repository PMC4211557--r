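# Default allele roster: the HLA class I and class II alleles scored in the
# analyses this package supports. DR/DP/DQ alleles bind 15-mers, A/B alleles
# 9-mers.
HLA_ROSTER <- local({
  dr <- c("DRB1*01:01", "DRB1*03:01", "DRB1*04:01", "DRB1*04:04",
          "DRB1*04:05", "DRB1*07:01", "DRB1*08:02", "DRB1*09:01",
          "DRB1*11:01", "DRB1*12:01", "DRB1*13:02", "DRB1*15:01",
          "DRB3*01:01", "DRB3*02:02", "DRB4*01:01", "DRB5*01:01")
  dp <- c("DPA1*01:03-DPB1*02:01", "DPA1*01:03-DPB1*04:02",
          "DPA1*01:03-DPB1*04:01", "DPA1*02:01-DPB1*01:01",
          "DPA1*02:01-DPB1*05:01", "DPA1*03:01-DPB1*04:02")
  dq <- c("DQA1*01:01-DQB1*05:01", "DQA1*01:02-DQB1*06:02",
          "DQA1*03:01-DQB1*03:02", "DQA1*04:01-DQB1*04:02",
          "DQA1*05:01-DQB1*02:01", "DQA1*05:01-DQB1*03:01")
  a <- c("A*01:01", "A*02:01", "A*02:02", "A*02:03", "A*02:06", "A*03:01",
         "A*11:01", "A*23:01", "A*24:02", "A*24:03", "A*26:01", "A*29:02",
         "A*30:01", "A*30:02", "A*31:01", "A*32:01", "A*33:01", "A*68:01",
         "A*68:02", "A*69:01")
  b <- c("B*07:02", "B*08:01", "B*15:01", "B*15:03", "B*18:01", "B*27:05",
         "B*35:01", "B*40:01", "B*40:02", "B*44:02", "B*44:01", "B*51:01",
         "B*53:01", "B*54:01", "B*57:01", "B*58:01")
  data.frame(
    allele = c(dr, dp, dq, a, b),
    mhc_class = rep(c("II", "I"), c(length(dr) + length(dp) + length(dq),
                                    length(a) + length(b))),
    locus = c(rep("DR", length(dr)), rep("DP", length(dp)),
              rep("DQ", length(dq)), rep("A", length(a)),
              rep("B", length(b))),
    stringsAsFactors = FALSE)
})

#' Default HLA allele roster
#'
#' The class I (HLA-A, -B; 9-mer) and class II (DR, DP, DQ; 15-mer) alleles
#' configured by default, with their locus. The DR locus has 16 entries.
#'
#' @param locus Optional locus filter (`"DR"`, `"DP"`, `"DQ"`, `"A"`, `"B"`).
#' @param mhc_class Optional class filter (`"I"` or `"II"`).
#' @return Data frame with columns `allele`, `mhc_class`, `locus`.
#' @export
hla_allele_roster <- function(locus = NULL, mhc_class = NULL) {
  out <- HLA_ROSTER
  if (!is.null(locus)) out <- out[out$locus %in% locus, , drop = FALSE]
  if (!is.null(mhc_class))
    out <- out[out$mhc_class %in% mhc_class, , drop = FALSE]
  rownames(out) <- NULL
  out
}

allele_window_length <- function(allele_id) {
  if (grepl("^(DR|DP|DQ)", allele_id)) 15L else 9L
}

# score a character vector of windows with one weight matrix (k x 5).
# X (ambiguous) contributes the column means of the property matrix, i.e. 0
# on the z-scale.
score_windows <- function(windows, weights, intercept, scale_factor) {
  k <- nrow(weights)
  props <- rbind(aa_property_matrix, X = 0)
  s <- numeric(length(windows))
  for (p in seq_len(k)) {
    res <- substr(windows, p, p)
    s <- s + as.numeric(props[res, , drop = FALSE] %*% weights[p, ])
  }
  intercept + scale_factor * s / sqrt(5 * k)
}

#' Deterministic surrogate MHC binding-affinity predictor
#'
#' Stands in for trained per-allele regression ensembles: each ensemble
#' member scores a window as a fixed linear function of residue
#' physicochemical indices (hydropathy, volume, polarity, charge,
#' flexibility) with allele- and member-specific weights, returning ln IC50
#' in natural-log nanomolar units. Fully determined by `(allele_id, seed)`;
#' distinct alleles give distinct score landscapes; members differ by small
#' weight perturbations so the ensemble has a non-trivial spread.
#'
#' @param allele_id HLA-style identifier; DR/DP/DQ alleles score 15-mers,
#'   others 9-mers unless `window_length` overrides.
#' @param seed Integer seed for the surrogate's weight draws.
#' @param members Number of ensemble members (default 10).
#' @param window_length 9 or 15; default inferred from `allele_id`.
#' @return An `affinity_predictor` with fields `allele_id`, `window_length`,
#'   `members` (list of vectorized scoring functions window -> ln IC50).
#' @export
make_surrogate_affinity_predictor <- function(allele_id, seed = 1,
                                              members = 10,
                                              window_length = NULL) {
  members <- check_scalar_count(members, "members")
  if (is.null(window_length)) window_length <- allele_window_length(allele_id)
  if (!window_length %in% c(9L, 15L))
    stop_contract("`window_length` must be 9 or 15")
  k <- as.integer(window_length)
  base_w <- with_seed(derive_seed(seed, "affinity", allele_id),
                      matrix(rnorm(k * 5), nrow = k))
  member_fns <- lapply(seq_len(members), function(m) {
    pert <- with_seed(derive_seed(seed, "affinity", allele_id, m),
                      matrix(rnorm(k * 5, sd = 0.15), nrow = k))
    w <- base_w + pert
    # typical ln IC50 around ln(500 nM) ~ 6.2, spread ~1.5 ln units
    function(windows) score_windows(windows, w, intercept = 6.2,
                                    scale_factor = 1.5)
  })
  structure(list(allele_id = allele_id, window_length = k,
                 members = member_fns),
            class = "affinity_predictor")
}

# member x window score matrix
predictor_scores <- function(predictor, windows) {
  bad <- nchar(windows) != predictor$window_length
  if (any(bad))
    stop_contract(sprintf("window length mismatch: predictor %s expects %d-mers",
                          predictor$allele_id, predictor$window_length))
  do.call(rbind, lapply(predictor$members, function(f) f(windows)))
}

#' Ensemble mean and spread of a predictor on one window
#'
#' Aggregates the predictor's members into the ensemble mean ln IC50 and the
#' sample (n-1) standard deviation across members, the reliability metric
#' reported alongside every prediction.
#'
#' @param predictor An `affinity_predictor`.
#' @param window A window string or one-row `peptide_windows` data frame of
#'   the predictor's window length.
#' @return List with `mean_ln_ic50` and `ensemble_sd` (0 when all members
#'   agree, including the single-member case).
#' @export
ensemble_predict <- function(predictor, window) {
  stopifnot(inherits(predictor, "affinity_predictor"))
  if (is.data.frame(window)) window <- window$residues
  if (length(window) != 1L) stop_contract("expected a single window")
  scores <- predictor_scores(predictor, window)[, 1]
  list(mean_ln_ic50 = mean(scores),
       ensemble_sd = if (length(scores) > 1L) sd(scores) else 0)
}

#' Johnson Sb standardization of within-protein affinities
#'
#' Transforms one allele's raw ln IC50 values within one protein to an
#' approximately Gaussian scale with zero mean and unit variance via a
#' bounded Johnson Sb transform `z = gamma + delta *
#' ln((x - xi)/(xi + lambda - x))`. The bounds `(xi, xi + lambda)` start
#' just beyond the sample range (1% inflation per side) and are then fitted
#' by minimizing the squared deviation of the transformed sample's skewness
#' and excess kurtosis from the Gaussian targets; `(gamma, delta)` are the
#' least-squares shape parameters, which pin the sample mean and SD to
#' exactly (0, 1). The transform is strictly monotone, so within-allele
#' peptide ranking is preserved exactly; near-Gaussian inputs come out
#' nearly unchanged (bounds recede, the transform approaches linearity) and
#' skewed inputs are symmetrized. Samples with fewer than 20 values fall
#' back to plain z-scoring with a warning.
#'
#' @param values Numeric vector of ln IC50 values (one allele, one protein).
#' @return Numeric z-scores with attributes `method` (`"johnson_sb"` or
#'   `"zscore"`) and the fit parameters `gamma`, `delta`, `xi`, `lambda`.
#' @export
johnson_sb_standardize <- function(values) {
  values <- as.numeric(values)
  if (anyNA(values)) stop_contract("`values` must not contain NA")
  rng <- range(values)
  if (length(values) < 2L || rng[1] == rng[2])
    stop_contract("degenerate input: constant or near-empty sample")
  if (length(values) < 20L) {
    warning("fewer than 20 values; falling back to plain z-scoring")
    z <- (values - mean(values)) / sd(values)
    attributes(z) <- list(method = "zscore", gamma = NA_real_,
                          delta = NA_real_, xi = NA_real_, lambda = NA_real_)
    return(z)
  }
  span <- diff(rng)
  transform <- function(pads) {
    xi <- rng[1] - span * exp(pads[1])
    lambda <- span + span * (exp(pads[1]) + exp(pads[2]))
    list(xi = xi, lambda = lambda,
         y = log((values - xi) / (xi + lambda - values)))
  }
  gauss_dev <- function(pads) {
    y <- transform(pads)$y
    yc <- (y - mean(y)) / sd(y)
    skew <- mean(yc^3)
    exkurt <- mean(yc^4) - 3
    skew^2 + exkurt^2
  }
  # pads on log scale relative to the sample range; start at the 1%-inflated
  # bounds and let the moment fit widen or tighten each side independently
  fit <- stats::optim(c(log(0.01), log(0.01)), gauss_dev,
                      method = "Nelder-Mead",
                      control = list(maxit = 300, reltol = 1e-8))
  tr <- transform(fit$par)
  delta <- 1 / sd(tr$y)
  gamma <- -mean(tr$y) * delta
  z <- gamma + delta * tr$y
  attributes(z) <- list(method = "johnson_sb", gamma = gamma, delta = delta,
                        xi = tr$xi, lambda = tr$lambda)
  z
}

#' Affinity matrix of one protein across an allele panel
#'
#' Scores every non-skipped window of the record with each predictor's
#' ensemble, then standardizes each allele's mean ln IC50 values to zero
#' mean and unit variance within the protein so alleles are comparable.
#'
#' @param record A single sequence record.
#' @param predictors List of `affinity_predictor`s, all of one window
#'   length.
#' @param standardize Apply [johnson_sb_standardize()] per allele (default
#'   TRUE).
#' @return An `affinity_matrix`: list with `parent_id`, `starts`,
#'   `window_length`, `alleles`, and windows-by-alleles matrices `mean`
#'   (ensemble mean ln IC50), `sd` (ensemble SD) and `z` (standardized; NULL
#'   if `standardize = FALSE`).
#' @export
build_affinity_matrix <- function(record, predictors, standardize = TRUE) {
  if (inherits(predictors, "affinity_predictor")) predictors <- list(predictors)
  if (length(predictors) == 0L) stop_contract("no predictors supplied")
  k <- unique(vapply(predictors, `[[`, integer(1), "window_length"))
  if (length(k) != 1L)
    stop_contract("all predictors must share one window length")
  rec <- as_record(record)
  win <- enumerate_windows(rec, k)
  win <- win[!win$skip, , drop = FALSE]
  if (nrow(win) == 0L) stop_contract("record has no scorable windows")
  alleles <- vapply(predictors, `[[`, character(1), "allele_id")
  mu <- s <- matrix(NA_real_, nrow(win), length(predictors),
                    dimnames = list(NULL, alleles))
  for (j in seq_along(predictors)) {
    sc <- predictor_scores(predictors[[j]], win$residues)
    mu[, j] <- colMeans(sc)
    s[, j] <- if (nrow(sc) > 1L) apply(sc, 2, sd) else 0
  }
  z <- NULL
  if (standardize) {
    z <- mu
    for (j in seq_len(ncol(mu))) z[, j] <- johnson_sb_standardize(mu[, j])
  }
  structure(list(parent_id = rec$id, starts = win$start,
                 window_length = k, alleles = alleles,
                 mean = mu, sd = s, z = z),
            class = "affinity_matrix")
}

#' @export
print.affinity_matrix <- function(x, ...) {
  cat(sprintf("<affinity_matrix> %s: %d windows (%d-mer) x %d alleles%s\n",
              x$parent_id, length(x$starts), x$window_length,
              length(x$alleles),
              if (is.null(x$z)) "" else ", standardized"))
  invisible(x)
}

#' Binding-fraction profile of one protein
#'
#' For each window, the fraction of panel alleles predicting the peptide's
#' standardized affinity more than `threshold_sd` standard deviations below
#' that allele's within-protein mean — i.e. unusually strong binding (lower
#' ln IC50 = higher affinity).
#'
#' @param matrix A standardized `affinity_matrix`.
#' @param alleles Optional subset of allele ids (default: all columns).
#' @param threshold_sd Threshold in SD units (default 1).
#' @return Data frame (start, position, fraction) where `position` is the
#'   window center.
#' @export
binding_fraction_profile <- function(matrix, alleles = NULL,
                                     threshold_sd = 1) {
  stopifnot(inherits(matrix, "affinity_matrix"))
  if (is.null(matrix$z)) stop_contract("matrix is not standardized")
  if (is.null(alleles)) alleles <- matrix$alleles
  if (length(alleles) == 0L) stop_contract("empty allele group")
  missing <- setdiff(alleles, matrix$alleles)
  if (length(missing))
    stop_contract("alleles not in matrix: ", paste(missing, collapse = ", "))
  zz <- matrix$z[, alleles, drop = FALSE]
  data.frame(start = matrix$starts,
             position = matrix$starts + matrix$window_length %/% 2L,
             fraction = rowMeans(zz < -threshold_sd))
}

#' Repertoire-level binding profile
#'
#' Computes the per-record binding-fraction profile for every record of a
#' repertoire on a common coordinate and aggregates per aligned window
#' center: the mean fraction and the 10th/90th percentiles across records.
#'
#' @param dataset A `repertoire_dataset`.
#' @param predictors List of `affinity_predictor`s (one window length).
#' @param alleles,threshold_sd Passed to [binding_fraction_profile()].
#' @return Data frame (position, mean_fraction, p10, p90).
#' @export
repertoire_binding_profile <- function(dataset, predictors, alleles = NULL,
                                       threshold_sd = 1) {
  records <- if (inherits(dataset, "repertoire_dataset")) dataset$records
             else dataset
  profs <- lapply(seq_len(nrow(records)), function(i) {
    m <- build_affinity_matrix(records[i, ], predictors)
    binding_fraction_profile(m, alleles = alleles,
                             threshold_sd = threshold_sd)
  })
  long <- data.table::rbindlist(profs)
  agg <- long[, .(mean_fraction = mean(fraction),
                  p10 = as.numeric(quantile(fraction, 0.10)),
                  p90 = as.numeric(quantile(fraction, 0.90))),
              by = position]
  data.table::setorder(agg, position)
  as.data.frame(agg)
}

CATHEPSINS <- c("cathepsin_B", "cathepsin_L", "cathepsin_S")

#' Deterministic surrogate cathepsin cleavage predictor
#'
#' Stands in for trained cleavage models: for each P1P1' dipeptide (the
#' central pair of the octamer, across the scissile bond) a fixed linear
#' function of the octamer's residue physicochemical indices is squashed
#' through a logistic link to a cleavage probability in \[0, 1\]. Weights are
#' determined by `(enzyme, seed, dipeptide)`, so the predictor is
#' bit-reproducible and enzyme-specific.
#'
#' @param enzyme One of `"cathepsin_B"`, `"cathepsin_L"`, `"cathepsin_S"`.
#' @param seed Integer seed.
#' @return A `cleavage_predictor` with a vectorized `$score(octamers)`
#'   function.
#' @export
make_surrogate_cleavage_predictor <- function(enzyme = CATHEPSINS,
                                              seed = 1) {
  enzyme <- match.arg(enzyme)
  cache <- new.env(parent = emptyenv())
  dipeptide_weights <- function(dp) {
    if (!is.null(cache[[dp]])) return(cache[[dp]])
    w <- with_seed(derive_seed(seed, "cleavage", enzyme, dp), list(
      weights = matrix(rnorm(8 * 5), nrow = 8),
      intercept = rnorm(1, mean = -0.5, sd = 1)))
    cache[[dp]] <- w
    w
  }
  score <- function(octamers) {
    if (any(nchar(octamers) != 8L))
      stop_contract("cleavage scoring requires 8-mers")
    dp <- substr(octamers, 4L, 5L)
    out <- numeric(length(octamers))
    for (d in unique(dp)) {
      w <- dipeptide_weights(d)
      i <- dp == d
      out[i] <- plogis(score_windows(octamers[i], w$weights,
                                     intercept = w$intercept,
                                     scale_factor = 2))
    }
    out
  }
  structure(list(enzyme = enzyme, seed = seed, score = score),
            class = "cleavage_predictor")
}

#' Cleavage-probability profile of a protein
#'
#' Scores every interior scissile bond (bonds `4 .. L - 4`) from the octamer
#' centered on it; bonds nearer the termini have no full octamer and are
#' reported absent.
#'
#' @param predictor A `cleavage_predictor`.
#' @param record A single sequence record (length >= 8).
#' @return Data frame (bond_after, enzyme, probability).
#' @export
cleavage_profile <- function(predictor, record) {
  stopifnot(inherits(predictor, "cleavage_predictor"))
  rec <- as_record(record)
  L <- nchar(rec$residues)
  if (L < 8L) {
    warning(sprintf("record '%s' shorter than 8 residues; empty profile",
                    rec$id))
    return(data.frame(bond_after = integer(), enzyme = character(),
                      probability = numeric()))
  }
  bonds <- 4:(L - 4L)
  oct <- substring(rec$residues, bonds - 3L, bonds + 4L)
  data.frame(bond_after = bonds, enzyme = predictor$enzyme,
             probability = predictor$score(oct),
             stringsAsFactors = FALSE)
}

#' Standardized affinity distributions of all windows carrying a motif
#'
#' Collects every window in the repertoire whose register extraction equals
#' the motif (a fixed TCEM combined, across occurrences, with varying GEMs)
#' and returns the per-allele standardized affinities of those windows —
#' the spread shows how the same T-cell exposed motif is presented with
#' widely different binding strengths.
#'
#' @param dataset A `repertoire_dataset`.
#' @param motif A `tcem_motif` (from [extract_motif()]) or motif letter
#'   string; must be a TCEM register.
#' @param predictors List of `affinity_predictor`s matching the register's
#'   window length.
#' @param register Register name, required when `motif` is a bare string.
#' @return List with `windows` (data frame id, start), `values` (windows x
#'   alleles matrix of standardized affinities) and `summary` (per allele:
#'   10/50/90% quantiles). Empty, with a warning, when the motif is absent.
#' @export
affinity_distribution_by_motif <- function(dataset, motif, predictors,
                                           register = NULL) {
  if (inherits(motif, "tcem_motif")) {
    register <- motif$register
    letters <- motif$letters
  } else {
    if (is.null(register))
      stop_contract("supply `register` with a bare motif string")
    letters <- toupper(as.character(motif))
  }
  reg <- as_register(register)
  if (!startsWith(reg$name, "TCEM"))
    stop_contract("motif must be a TCEM register, got ", reg$name)
  records <- if (inherits(dataset, "repertoire_dataset")) dataset$records
             else dataset
  win <- all_windows(records, reg$window_length)
  win <- win[extract_motif_letters(win$residues, reg) == letters]
  if (nrow(win) == 0L) {
    warning("motif ", letters, " not found in dataset")
    return(list(windows = data.frame(id = character(), start = integer()),
                values = NULL, summary = NULL))
  }
  mats <- lapply(unique(win$id), function(rid) {
    rec <- records[records$id == rid, , drop = FALSE]
    m <- build_affinity_matrix(rec, predictors)
    sel <- win[win$id == rid]
    m$z[match(sel$start, m$starts), , drop = FALSE]
  })
  values <- do.call(rbind, mats)
  summ <- apply(values, 2, quantile, probs = c(0.1, 0.5, 0.9))
  list(windows = data.frame(id = win$id, start = win$start,
                            stringsAsFactors = FALSE),
       values = values, summary = summ)
}
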