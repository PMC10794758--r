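toy_di_table <- function(values = NULL) {
  kmers <- lncsig:::all_kmers(2)
  if (is.null(values)) {
    set.seed(1)
    values <- matrix(rnorm(48), 16, 3)
  }
  dimnames(values) <- list(kmers, c("solvation", "stacking", "hbond"))
  energy_table(2, values)
}

test_that("energy tables load with case-insensitive keys and strict validation", {
  tab <- example_energy_table(2)
  expect_equal(tab$k, 2)
  expect_equal(nrow(tab$energies), 16)
  tri <- example_energy_table(3)
  expect_equal(nrow(tri$energies), 64)

  f <- withr::local_tempfile(fileext = ".tsv")
  d <- data.frame(kmer = tolower(lncsig:::all_kmers(2)),
                  solvation = 1:16, stacking = 1:16, hbond = 1:16)
  write.table(d, f, sep = "\t", quote = FALSE, row.names = FALSE)
  tab2 <- load_energy_table(f, 2) # lowercase keys accepted
  expect_equal(rownames(tab2$energies), lncsig:::all_kmers(2))

  write.table(d[-3, ], f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_energy_table(f, 2), "AG") # names the missing dinucleotide
  write.table(rbind(d, d[1, ]), f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_energy_table(f, 2), "duplicate")
  d_bad <- d; d_bad$stacking <- as.character(d_bad$stacking); d_bad$stacking[2] <- "x"
  write.table(d_bad, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_energy_table(f, 2), "non-numeric")
})

test_that("lower-order derivation equals the brute-force positional average", {
  # constant table stays constant
  const <- energy_table(3, matrix(2.5, 64, 3,
    dimnames = list(lncsig:::all_kmers(3), c("solvation", "stacking", "hbond"))))
  expect_true(all(derive_lower_order_table(const)$energies == 2.5))

  # E(AA) averages the eight containing trinucleotides, AAA counted twice
  tri <- example_energy_table(3)
  d2 <- derive_lower_order_table(tri)
  containing <- c(paste0("AA", c("A", "C", "G", "T")), paste0(c("A", "C", "G", "T"), "AA"))
  expect_equal(d2$energies["AA", "stacking"],
               mean(tri$energies[containing, "stacking"]))
  expect_equal(sum(containing == "AAA"), 2)

  # random order-4 table: 4 -> 3 matches brute-force substring enumeration
  set.seed(8)
  tet <- energy_table(4, matrix(rnorm(256 * 3), 256, 3,
    dimnames = list(lncsig:::all_kmers(4), c("solvation", "stacking", "hbond"))))
  expect_equal(derive_lower_order_table(tet)$energies,
               oracle_lower_order(tet)$energies, tolerance = 1e-12)
})

test_that("transition matrices match hand enumeration and are row-stochastic", {
  tm <- transition_matrix("ATGAT", 2)
  expect_equal(sum(tm$counts), 3)
  expect_equal(tm$counts["AT", "TG"], 1)
  expect_equal(tm$counts["TG", "GA"], 1)
  expect_equal(tm$counts["GA", "AT"], 1)
  expect_equal(tm$probs["AT", "TG"], 1)

  tm2 <- transition_matrix(strrep("AT", 50), 2)
  nz <- which(tm2$counts > 0, arr.ind = TRUE)
  expect_setequal(paste(rownames(tm2$counts)[nz[, 1]],
                        colnames(tm2$counts)[nz[, 2]]),
                  c("AT TA", "TA AT"))
  expect_equal(tm2$probs["AT", "TA"], 1)
  expect_equal(tm2$probs["TA", "AT"], 1)

  set.seed(21)
  for (i in 1:5) {
    tm3 <- transition_matrix(random_seq(sample(50:400, 1)), sample(1:3, 1))
    rs <- rowSums(tm3$probs)
    occupied <- rowSums(tm3$counts) > 0
    expect_equal(unname(rs[occupied]), rep(1, sum(occupied)), tolerance = 1e-12)
    expect_true(all(rs[!occupied] == 0))
    # transitions only between k-mers overlapping in k-1 bases
    k <- tm3$k
    if (k > 1) {
      nz <- which(tm3$counts > 0, arr.ind = TRUE)
      froms <- rownames(tm3$counts)[nz[, 1]]; tos <- colnames(tm3$counts)[nz[, 2]]
      expect_true(all(substr(froms, 2, k) == substr(tos, 1, k - 1)))
    }
  }
  expect_error(transition_matrix("AC", 2), "shorter")
  expect_error(transition_matrix("ANNNA", 2), "no N-free")
})

test_that("energy features are frequency-weighted means with unit total weight", {
  # homopolymer: single-support distribution returns that k-mer's energies
  tab <- toy_di_table()
  h <- energy_features(strrep("A", 100), tab)
  expect_equal(unname(h), unname(tab$energies["AA", ]))

  # constant table gives the constant whatever the sequence
  const <- toy_di_table(matrix(7, 16, 3))
  set.seed(4)
  expect_equal(unname(energy_features(random_seq(150), const)), rep(7, 3))

  # hand-counted weights for ATGATG: AT 2/5, TG 2/5, GA 1/5
  e <- energy_features("ATGATG", tab)
  manual <- (2 / 5) * tab$energies["AT", ] + (2 / 5) * tab$energies["TG", ] +
    (1 / 5) * tab$energies["GA", ]
  expect_equal(unname(e), unname(manual))

  expect_error(energy_features("ANANAN", tab), "no N-free")
})

test_that("long-sequence energy features converge to the analytic expectation", {
  # i.i.d. uniform bases: every dinucleotide equally likely, f* = 1/16, so
  # the feature expectation is the plain mean energy. The standard error
  # accounts for the lag-1 dependence of overlapping windows, computed by
  # exact enumeration over trinucleotides.
  tab <- example_energy_table(2)
  expected <- colMeans(tab$energies)
  n <- 30000
  m <- n - 1 # number of windows
  set.seed(12)
  feats <- energy_features(random_seq(n), tab)
  tri <- lncsig:::all_kmers(3)
  for (col in c("solvation", "stacking", "hbond")) {
    e <- tab$energies[, col]
    mu <- mean(e)
    var_x <- mean(e^2) - mu^2
    cov1 <- mean(vapply(tri, function(w) {
      e[substr(w, 1, 2)] * e[substr(w, 2, 3)]
    }, numeric(1))) - mu^2
    se <- sqrt((var_x + 2 * cov1) / m)
    expect_lt(abs(feats[[col]] - expected[[col]]), 3 * se)
  }
})

test_that("stationary weighting agrees with empirical weighting on long chains", {
  set.seed(31)
  s <- random_seq(20000)
  tab <- example_energy_table(2)
  emp <- energy_features(s, tab, weighting = "empirical")
  stat <- energy_features(s, tab, weighting = "stationary")
  expect_equal(unname(emp), unname(stat), tolerance = 0.05)
})

test_that("physchem_features emits six named columns per record", {
  ds <- make_toy_dataset(n = 5)
  pc <- physchem_features(rbind(ds$lnc, ds$mrna),
                          example_energy_table(2), example_energy_table(3))
  expect_equal(nrow(pc), 10)
  expect_named(pc, c("id", "label", "dp_solvation", "dp_stacking", "dp_hbond",
                     "tp_solvation", "tp_stacking", "tp_hbond"))
  expect_true(all(is.finite(as.matrix(pc[, -(1:2)]))))
})
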