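constant_predictor <- function(vals, k = 9L) {
  structure(list(allele_id = "toy", window_length = k,
                 members = lapply(vals, function(v)
                   function(w) rep(v, length(w)))),
            class = "affinity_predictor")
}

test_that("ensemble aggregation is mean and sample SD over members", {
  p <- constant_predictor(c(1, 2, 3))
  e <- ensemble_predict(p, strrep("A", 9))
  expect_equal(e$mean_ln_ic50, 2)
  expect_equal(e$ensemble_sd, 1)
  same <- constant_predictor(c(5, 5, 5))
  expect_equal(ensemble_predict(same, strrep("A", 9))$ensemble_sd, 0)
  expect_error(ensemble_predict(p, strrep("A", 15)), "length mismatch")
})

test_that("surrogate predictors are deterministic and allele-specific", {
  w <- "FSNYAIHWVRQAPGQ"
  p1 <- make_surrogate_affinity_predictor("DRB1*01:01", seed = 4)
  p2 <- make_surrogate_affinity_predictor("DRB1*01:01", seed = 4)
  expect_identical(unlist(ensemble_predict(p1, w)),
                   unlist(ensemble_predict(p2, w)))
  expect_equal(p1$window_length, 15L)
  expect_equal(make_surrogate_affinity_predictor("A*02:01")$window_length, 9L)
  # ensemble matches an independent recomputation from the members
  scores <- vapply(p1$members, function(f) f(w), numeric(1))
  e <- ensemble_predict(p1, w)
  expect_equal(e$mean_ln_ic50, sum(scores) / length(scores))
  expect_equal(e$ensemble_sd,
               sqrt(sum((scores - mean(scores))^2) / (length(scores) - 1)))
  expect_gt(e$ensemble_sd, 0)
  # distinct alleles give distinct landscapes (collision check)
  set.seed(6)
  peps <- vapply(1:20, function(i)
    paste(sample(aa_alphabet(), 15, TRUE), collapse = ""), character(1))
  other <- make_surrogate_affinity_predictor("DRB1*15:01", seed = 4)
  m1 <- vapply(peps, function(p) ensemble_predict(p1, p)$mean_ln_ic50,
               numeric(1))
  m2 <- vapply(peps, function(p) ensemble_predict(other, p)$mean_ln_ic50,
               numeric(1))
  expect_true(all(m1 != m2))
})

test_that("Johnson Sb standardization meets its contract", {
  set.seed(2)
  x <- rnorm(500)
  z <- johnson_sb_standardize(x)
  expect_gt(cor(x, z), 0.99)                 # near-identity on normal input
  expect_lt(abs(mean(z)), 0.01)
  expect_lt(abs(sd(z) - 1), 0.02)
  y <- exp(rnorm(300))
  zy <- johnson_sb_standardize(y)
  expect_lt(abs(sample_skewness(zy)), abs(sample_skewness(y)))
  expect_equal(rank(zy), rank(y))            # strictly monotone
  expect_equal(attr(zy, "method"), "johnson_sb")
  expect_true(is.finite(attr(zy, "xi")) && is.finite(attr(zy, "lambda")))
  expect_error(johnson_sb_standardize(rep(1, 30)), "degenerate")
  expect_warning(z_small <- johnson_sb_standardize(rnorm(10)), "z-scoring")
  expect_equal(attr(z_small, "method"), "zscore")
})

test_that("binding fraction counts alleles more than 1 SD below their mean", {
  m <- structure(list(parent_id = "p", starts = 1:3, window_length = 15L,
                      alleles = sprintf("a%02d", 1:16),
                      mean = matrix(0, 3, 16), sd = matrix(0, 3, 16),
                      z = matrix(rbind(c(rep(-1.5, 10), rep(0, 6)),
                                       rep(0, 16),
                                       rep(-2, 16)), nrow = 3,
                                 dimnames = list(NULL,
                                                 sprintf("a%02d", 1:16)))),
                 class = "affinity_matrix")
  prof <- binding_fraction_profile(m)
  expect_equal(prof$fraction, c(10 / 16, 0, 1))  # 0.625 as in a 16-DR panel
  expect_equal(prof$position, 1:3 + 7L)
  expect_error(binding_fraction_profile(m, alleles = character()), "empty")
  expect_error(binding_fraction_profile(m, alleles = "nope"), "not in matrix")
})

test_that("binding fraction is invariant to affine rescaling of one allele", {
  rec <- random_records(1, 60, seed = 8)
  preds <- lapply(c("DRB1*01:01", "DRB1*03:01", "DRB1*04:01"),
                  make_surrogate_affinity_predictor, seed = 2)
  base <- binding_fraction_profile(build_affinity_matrix(rec, preds))
  rescaled <- preds
  f0 <- rescaled[[2]]$members
  rescaled[[2]]$members <- lapply(f0, function(f) function(w) 3 * f(w) - 5)
  again <- binding_fraction_profile(build_affinity_matrix(rec, rescaled))
  expect_equal(again$fraction, base$fraction)
})

test_that("identical records give a zero-variance repertoire profile", {
  rec <- random_records(1, 50, seed = 12)
  ds <- repertoire_dataset(sequence_records(
    c("a", "b", "c"), rep(rec$residues, 3)))
  preds <- lapply(c("DRB1*01:01", "DRB1*07:01"),
                  make_surrogate_affinity_predictor, seed = 3)
  prof <- repertoire_binding_profile(ds, preds)
  expect_equal(prof$p10, prof$p90)
  expect_equal(prof$p10, prof$mean_fraction)
})

test_that("cleavage profiles score interior bonds with probabilities", {
  pred <- make_surrogate_cleavage_predictor("cathepsin_L", seed = 5)
  rec8 <- list(id = "r", residues = "ACDEFGHI")
  prof8 <- cleavage_profile(pred, rec8)
  expect_equal(nrow(prof8), 1L)
  expect_equal(prof8$bond_after, 4L)
  rec <- random_records(1, 40, seed = 19)
  prof <- cleavage_profile(pred, rec)
  expect_equal(prof$bond_after, 4:36)
  expect_true(all(prof$probability >= 0 & prof$probability <= 1))
  # bit-reproducible across a fresh predictor
  pred2 <- make_surrogate_cleavage_predictor("cathepsin_L", seed = 5)
  expect_identical(cleavage_profile(pred2, rec)$probability,
                   prof$probability)
  # enzymes differ
  predB <- make_surrogate_cleavage_predictor("cathepsin_B", seed = 5)
  expect_false(identical(cleavage_profile(predB, rec)$probability,
                         prof$probability))
  expect_warning(empty <- cleavage_profile(pred, list(id = "s", residues = "ACDEF")),
                 "shorter")
  expect_equal(nrow(empty), 0L)
})

test_that("affinity distributions collect exactly the motif's windows", {
  ds <- repertoire_dataset(random_records(4, 40, seed = 51))
  preds <- lapply(c("DRB1*01:01", "DRB1*03:01"),
                  make_surrogate_affinity_predictor, seed = 1)
  tab <- build_frequency_table(ds, "TCEM_IIA")
  motif <- as.data.frame(tab$entries)$motif[1]
  out <- affinity_distribution_by_motif(ds, motif, preds,
                                        register = "TCEM_IIA")
  # brute-force scan of matching windows
  hits <- 0L
  for (i in 1:4) {
    s <- ds$records$residues[i]
    for (st in 1:(nchar(s) - 14))
      if (oracle_extract(substr(s, st, st + 14), "TCEM_IIA") == motif)
        hits <- hits + 1L
  }
  expect_equal(nrow(out$windows), hits)
  expect_equal(nrow(out$values), hits)
  expect_equal(colnames(out$values), c("DRB1*01:01", "DRB1*03:01"))
  if (hits == 1L) expect_equal(dim(out$summary), c(3L, 2L))
  expect_warning(none <- affinity_distribution_by_motif(
    ds, "WWWWW", preds, register = "TCEM_IIA"), "not found")
  expect_equal(nrow(none$windows), 0L)
  expect_error(affinity_distribution_by_motif(ds, "AAAAA", preds,
                                              register = "GEM_IIA"),
               "TCEM")
})

test_that("the default allele roster has the expected structure", {
  roster <- hla_allele_roster()
  expect_equal(nrow(hla_allele_roster("DR")), 16L)
  expect_true(all(roster$mhc_class[roster$locus %in% c("DR", "DP", "DQ")] == "II"))
  expect_true(all(roster$mhc_class[roster$locus %in% c("A", "B")] == "I"))
  expect_false(anyDuplicated(roster$allele) > 0)
})
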