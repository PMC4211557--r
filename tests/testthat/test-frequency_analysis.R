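test_that("frequency tables equal the nested-loop oracle on random repertoires", {
  for (seed in c(11, 12)) {
    ds <- curate(random_records(n = 15 + seed %% 5, len = 38, seed = seed),
                 max_length = 40)
    for (reg in c("TCEM_I", "TCEM_IIA", "GEM_I")) {
      tab <- build_frequency_table(ds, reg)
      oracle <- oracle_count_motifs(ds$records, reg)
      got <- as.data.frame(tab$entries)[order(tab$entries$motif), ]
      rownames(got) <- NULL
      expect_equal(got$motif, oracle$motif)
      expect_equal(got$molecule_count, oracle$molecule_count)
      expect_equal(got$instance_count, oracle$instance_count)
      expect_equal(tab$total_instances, sum(oracle$instance_count))
      expect_equal(tab$total_molecules, nrow(ds$records))
      # invariants
      expect_true(all(got$molecule_count >= 1 &
                        got$molecule_count <= tab$total_molecules))
      expect_true(all(got$molecule_count <= got$instance_count))
    }
  }
})

test_that("molecule vs instance counting distinguishes re-use within a record", {
  # two records each containing motif once
  ds <- repertoire_dataset(sequence_records(
    c("a", "b"), c("ACDEFGHIK", "ACDEFGHIK")))
  tab <- build_frequency_table(ds, "TCEM_I")
  expect_equal(tab$entries$molecule_count, 2L)
  expect_equal(tab$entries$instance_count, 2L)
  # one record containing the motif twice
  ds2 <- repertoire_dataset(sequence_records("a", "ACDEFGHIKACDEFGHIK"))
  tab2 <- build_frequency_table(ds2, "TCEM_I")
  m <- as.data.frame(tab2$entries)
  expect_equal(m$molecule_count[m$motif == "EFGHI"], 1L)
  expect_equal(m$instance_count[m$motif == "EFGHI"], 2L)
  # windows containing X contribute nothing
  dsx <- repertoire_dataset(sequence_records("a", "ACDEFGHIKX"))
  expect_equal(build_frequency_table(dsx, "TCEM_I")$total_instances, 1L)
  expect_error(build_frequency_table(sequence_records(character(), character()),
                                     "TCEM_I"), "empty")
})

test_that("frequency classes reproduce the definitional identities", {
  expect_identical(assign_frequency_class(1, 4), 2L)       # 1/4  -> FC2
  expect_identical(assign_frequency_class(1, 1024), 10L)   # 1/1024 -> FC10
  expect_identical(assign_frequency_class(1, 32), 5L)      # 1/32 -> FC5
  expect_identical(assign_frequency_class(1, 39982), 16L)  # singleton in 40K
  expect_identical(assign_frequency_class(39982, 39982), 0L)
  expect_error(assign_frequency_class(0, 10), "positive")
  expect_error(assign_frequency_class(11, 10), "exceed")
})

test_that("FC is exact on powers of two and monotone in molecule count", {
  for (k in 0:20) expect_identical(assign_frequency_class(1, 2^k), k,
                                   info = paste("k =", k))
  for (total in c(100, 1000, 39982)) {
    fc <- assign_frequency_class(seq_len(total %/% 2), total)
    expect_true(all(diff(fc) <= 0))          # non-increasing in count
    expect_equal(oracle_fc(1, total), assign_frequency_class(1, total))
    counts <- sample(seq_len(total), 50)
    expect_equal(assign_frequency_class(counts, total),
                 vapply(counts, oracle_fc, numeric(1), total = total))
  }
})

test_that("fc_histogram conserves counts and finds the weighted midpoint", {
  ds <- curate(random_records(12, 40, seed = 33), max_length = 40)
  tab <- build_frequency_table(ds, "TCEM_IIA")
  h <- fc_histogram(tab)
  expect_equal(sum(h$unique_count), nrow(tab$entries))
  expect_equal(sum(h$weighted_count), tab$total_instances)
  expect_equal(tail(h$cumulative_fraction, 1), 1)
  # brute-force binning oracle
  fc <- vapply(tab$entries$molecule_count, oracle_fc, numeric(1),
               total = tab$total_molecules)
  expect_equal(h$unique_count,
               as.integer(table(fc)[as.character(h$fc)]))
  expect_equal(attr(h, "midpoint_fc"),
               h$fc[which(cumsum(h$weighted_count) >=
                            0.5 * sum(h$weighted_count))[1]])
  # degenerate single-bin cases
  every <- repertoire_dataset(sequence_records(
    c("a", "b"), rep("ACDEFGHIK", 2)))
  h0 <- fc_histogram(build_frequency_table(every, "TCEM_I"))
  expect_equal(h0$fc, 0L)
  # singletons among 2^k molecules land in the single bin FC k
  k <- 3
  sing <- repertoire_dataset(random_records(2^k, 24, seed = 9))
  tab_s <- build_frequency_table(sing, "TCEM_IIA")
  if (all(tab_s$entries$molecule_count == 1L))
    expect_equal(fc_histogram(tab_s)$fc, k)
})

test_that("origin attribution labels germline motifs and partitions", {
  germ <- sequence_records("gl1", "ACDEFGHIKLMNPQR", is_germline = TRUE)
  ds <- repertoire_dataset(sequence_records(
    c("c1", "c2"), c("ACDEFGHIKLMNPQR", "YYYYYYYYYYYYYYY")))
  tab <- build_frequency_table(ds, "TCEM_IIA")
  org <- attribute_origin(tab, germ)
  expect_setequal(levels(org$origin), c("germline", "SHM"))
  # window positions 5,6,8,10,11 of ACDEFGHIKLMNPQR -> FGILM
  expect_equal(as.character(org$origin[org$motif == "FGILM"]), "germline")
  expect_equal(as.character(org$origin[org$motif == "YYYYY"]), "SHM")
  expect_equal(nrow(org), nrow(tab$entries))     # exactly one label each
  expect_error(attribute_origin(tab, NULL), "empty")
})

test_that("per-position unique counts respond to repertoire diversity", {
  ds <- repertoire_dataset(sequence_records(
    c("a", "b", "c"), rep(strrep("ACDEFGHIKL", 3), 3)))
  pp <- per_position_unique_motifs(ds, "TCEM_IIA")
  expect_true(all(pp$unique_count == 1L))
  expect_equal(pp$position, (1:16) + 7L)   # center = start + 7
  distinct <- repertoire_dataset(random_records(4, 15, seed = 5))
  pp2 <- per_position_unique_motifs(distinct, "TCEM_IIA")
  expect_equal(pp2$unique_count, 4L)
  expect_equal(pp2$position, 8L)
  pp9 <- per_position_unique_motifs(distinct, "TCEM_I")
  expect_equal(pp9$position, (1:7) + 4L)   # 9-mer center = start + 4
})

test_that("co-location fraction matches exhaustive pairing on toy sets", {
  # all-singleton repertoire: every unique IIa window carries a unique IIb
  singles <- repertoire_dataset(random_records(5, 15, seed = 21))
  expect_equal(colocalization_fraction(singles), 1.0)
  expect_equal(colocalization_fraction(singles, from = "TCEM_IIB",
                                       to = "TCEM_IIA"), 1.0)
  # identical records: no unique motifs at all
  same <- repertoire_dataset(sequence_records(
    c("a", "b"), rep(strrep("ACDEFGHIKLMNPQR", 1), 2)))
  expect_warning(z <- colocalization_fraction(same), "undefined")
  expect_equal(z, 0)
  # toy 3-record set vs exhaustive enumeration
  ds <- repertoire_dataset(random_records(3, 20, seed = 77))
  win <- do.call(rbind, lapply(seq_len(3), function(i) {
    s <- ds$records$residues[i]
    data.frame(id = ds$records$id[i], start = 1:(nchar(s) - 14),
               w = substring(s, 1:(nchar(s) - 14), 15:nchar(s)))
  }))
  win$a <- vapply(win$w, oracle_extract, character(1), "TCEM_IIA")
  win$b <- vapply(win$w, oracle_extract, character(1), "TCEM_IIB")
  uniq <- function(v) names(which(vapply(split(win$id, v), function(x)
    length(unique(x)), integer(1)) == 1L))
  ua <- uniq(win$a); ub <- uniq(win$b)
  expected <- mean(vapply(ua, function(m)
    any(win$b[win$a == m] %in% ub), logical(1)))
  expect_equal(colocalization_fraction(ds), expected)
})

test_that("motif set overlap and reference FC mapping behave as set ops", {
  ds <- curate(random_records(8, 30, seed = 41), max_length = 40)
  tab <- build_frequency_table(ds, "TCEM_I")
  self <- motif_set_overlap(tab, tab)
  expect_equal(self$shared_fraction_of_A, 1.0)
  expect_equal(self$shared_fraction_of_B, 1.0)
  expect_equal(self$shared_count, nrow(tab$entries))
  other <- build_frequency_table(
    repertoire_dataset(random_records(8, 30, seed = 42,
                                      alphabet = c("A", "C", "D"))), "TCEM_I")
  dis <- motif_set_overlap(tab, other)
  expect_equal(dis$shared_count, length(intersect(tab$entries$motif,
                                                  other$entries$motif)))
  tab15 <- build_frequency_table(ds, "TCEM_IIA")
  expect_error(motif_set_overlap(tab, tab15), "register mismatch")
  # FC mapping: query against itself -> zero unclassified, own FCs
  self_map <- map_fc_from_reference(tab, tab)
  expect_equal(attr(self_map, "unclassified_fraction"), 0)
  expect_equal(self_map$fc,
               assign_frequency_class(tab$entries$molecule_count,
                                      tab$total_molecules))
  dis_map <- map_fc_from_reference(other, tab)
  expect_equal(mean(dis_map$unclassified),
               1 - dis$shared_count / nrow(other$entries))
})

test_that("usage correlation is Pearson over shared germline ids", {
  u <- c(g1 = 0.5, g2 = 0.3, g3 = 0.2)
  expect_equal(usage_correlation(u, u), 1.0)
  rev3 <- c(g1 = 0.2, g2 = 0.4, g3 = 0.5)  # 0.7 - u: anti-collinear
  expect_equal(usage_correlation(u, rev3), -1.0)
  v <- c(g1 = 0.45, g2 = 0.35, g3 = 0.2, g9 = 99)
  expect_equal(usage_correlation(u, v),
               cor(c(0.5, 0.3, 0.2), c(0.45, 0.35, 0.2)))
  expect_error(usage_correlation(u, c(g1 = 1, g2 = 2)), "3 shared")
})
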