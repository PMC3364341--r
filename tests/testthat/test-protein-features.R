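# Protein descriptor families: worked examples, edge cases and oracle spot
# checks (the full 100-sequence oracle suite runs in test-acceptance.R).

test_that("amino-acid and dipeptide composition count correctly", {
  v <- composition_features("AAAA")
  expect_equal(unname(v["AAC.A"]), 1.0)
  expect_equal(sum(v[paste0("AAC.", setdiff(AA20, "A"))]), 0)
  expect_equal(unname(v["DPC.AA"]), 1.0)

  v <- composition_features("ACDA")
  expect_equal(unname(v[c("AAC.A", "AAC.C", "AAC.D")]), c(0.5, 0.25, 0.25))

  v <- composition_features("ARAR")
  expect_equal(unname(v["DPC.AR"]), 2 / 3)
  expect_equal(unname(v["DPC.RA"]), 1 / 3)
})

test_that("composition blocks each sum to one on random sequences", {
  set.seed(1)
  for (i in 1:20) {
    v <- composition_features(rand_seq(sample(2:200, 1)))
    expect_equal(sum(v[1:20]), 1, tolerance = 1e-9)
    expect_equal(sum(v[21:420]), 1, tolerance = 1e-9)
  }
})

test_that("nonstandard residues are rejected with position, or stripped", {
  expect_error(composition_features("ACDXE"), "X.*position 4|position 4")
  expect_warning(s <- check_protein_sequence("ACDXE", sanitize = TRUE),
                 "stripped")
  expect_equal(s, "ACDE")
})

test_that("autocorrelation matches hand-computed toy cases", {
  toy <- list(pm = c(A = 1, R = -1)[c("A", "R")])
  names(toy$pm) <- c("A", "R")
  # alternating ARARARARAR, lag 1: every product is -1
  v <- autocorrelation_features("ARARARARAR", properties = toy, maxlag = 1,
                                kind = "moreau_broto")
  expect_equal(unname(v), -1)
  # homopolymer has zero variance: centered forms return 0
  long_a <- strrep("A", 40)
  p8 <- aa_scales("hydropathy")
  expect_true(all(autocorrelation_features(long_a, p8, maxlag = 5,
                                           kind = "moran") == 0))
  expect_true(all(autocorrelation_features(long_a, p8, maxlag = 5,
                                           kind = "geary") == 0))
  # dimensionality: 1 property x 30 lags
  expect_length(autocorrelation_features(rand_seq(60), p8, maxlag = 30),
                30)
})

test_that("autocorrelation rejects sequences shorter than maxlag + 1", {
  expect_error(
    autocorrelation_features(rand_seq(20), aa_scales("hydropathy"),
                             maxlag = 30),
    "minimum 31")
})

test_that("CTD matches the hand-counted toy attribute", {
  toy <- list(tg = list(g1 = "A", g2 = "R",
                        g3 = setdiff(AA20, c("A", "R"))))
  v <- ctd_features("AAARRR", groups = toy)
  expect_equal(unname(v[paste0("CTD.C.tg.g", 1:3)]), c(0.5, 0.5, 0))
  expect_equal(unname(v["CTD.T.tg.g1g2"]), 1 / 5)
  expect_equal(unname(v[paste0("CTD.D.tg.g1.",
                               c("first", "p25", "p50", "p75", "p100"))]),
               100 * c(1, 1, 2, 3, 3) / 6)
  # homogroup sequence: all transitions zero
  v <- ctd_features("AAAA", groups = toy)
  expect_true(all(v[grep("^CTD\\.T", names(v))] == 0))
})

test_that("sequence-order coupling numbers match the toy distance matrix", {
  dm <- matrix(0, 20, 20, dimnames = list(AA20, AA20))
  dm["A", "R"] <- dm["R", "A"] <- 1
  v <- order_features("ARAR", maxlag = 2, weight = 0.1,
                      dist_mats = list(toy = dm))
  expect_equal(unname(v["SOC.toy.lag1"]), 3)
  expect_equal(unname(v["SOC.toy.lag2"]), 0)
  # homopolymer: all coupling numbers and order-type values are 0
  v <- order_features(strrep("A", 40), maxlag = 5)
  expect_true(all(v[grep("^SOC", names(v))] == 0))
  expect_true(all(v[grep("order", names(v))] == 0))
  # default dimensionality: 2*30 SOC + 2*(20+30) QSO
  expect_length(order_features(rand_seq(60)), 160)
})

test_that("amphiphilic pseudo-composition has the documented structure", {
  s <- rand_seq(80)
  v <- apaac_features(s, lam = 30, weight = 0.05)
  expect_length(v, 80)
  # weight zero: first 20 equal plain composition, the rest vanish
  v0 <- apaac_features(s, lam = 30, weight = 0)
  expect_equal(unname(v0[1:20]),
               unname(composition_features(s)[1:20]), tolerance = 1e-12)
  expect_true(all(v0[21:80] == 0))
  # denominator identity via independent recomputation
  expect_equal(unname(v), unname(oracle_apaac(s, 30, 0.05)),
               tolerance = 1e-9)
  expect_equal(sum(v[1:20]) * (1 + 0.05 * sum(oracle_apaac_tau(s, 30))), 1,
               tolerance = 1e-9)
})

test_that("averaged property descriptors are sequence means", {
  toy <- list(pm = structure(c(1, -1), names = c("A", "R")))
  expect_equal(unname(aaprop_features("AAA", toy)), 1)
  expect_equal(unname(aaprop_features("AR", toy)), 0)
  expect_length(aaprop_features(rand_seq(10)), 33)
  expect_error(aaprop_features("AR", list()), "nonempty")
})

test_that("the default profile yields 1080 finite dimensions", {
  for (len in c(31, 100, 500)) {
    v <- featurize_protein(rand_seq(len))
    expect_length(v, 1080)
    expect_true(all(is.finite(v)))
    expect_false(anyDuplicated(names(v)) > 0)
  }
  # determinism
  s <- rand_seq(120)
  expect_identical(featurize_protein(s), featurize_protein(s))
  # composition-only profile
  prof <- structure(list(version = "c", total = 420L,
                         families = list(list(family = "composition"))),
                    class = "protein_profile")
  expect_length(featurize_protein(rand_seq(50), prof), 420)
  # too-short sequences are rejected, naming the minimum
  expect_error(featurize_protein(rand_seq(30)), "31")
})

test_that("family errors are propagated with the family named", {
  prof <- default_protein_profile()
  prof$families <- c(prof$families, list(list(family = "nope")))
  expect_error(featurize_protein(rand_seq(40), prof), "nope")
})

test_that("featurize_proteins builds a named matrix and honors sanitize", {
  seqs <- c(p1 = rand_seq(40), p2 = rand_seq(60))
  m <- featurize_proteins(seqs)
  expect_equal(dim(m), c(2L, 1080L))
  expect_equal(rownames(m), c("p1", "p2"))
  # a too-short sequence is dropped (with a warning) under sanitize
  seqs2 <- c(seqs, bad = rand_seq(10))
  expect_warning(m2 <- featurize_proteins(seqs2, sanitize = TRUE),
                 "dropping")
  expect_equal(rownames(m2), c("p1", "p2"))
  expect_error(featurize_proteins(seqs2), "bad")
})

test_that("property scales standardize to zero mean and unit variance", {
  for (sc in aa_scales()) {
    expect_equal(mean(sc), 0, tolerance = 1e-9)
    expect_equal(mean(sc^2), 1, tolerance = 1e-9)
  }
  expect_length(aa_scales(), 33)
  dms <- residue_distance_matrices()
  for (dm in dms) {
    expect_true(isSymmetric(dm))
    expect_true(all(diag(dm) == 0))
    expect_equal(max(dm), 1)
  }
})

test_that("FASTA round trip preserves ids and sequences", {
  path <- withr::local_tempfile(fileext = ".fasta")
  seqs <- c(protA = rand_seq(45), protB = rand_seq(52))
  writeLines(paste0(">", names(seqs), " some description\n", seqs), path)
  got <- read_protein_fasta(path)
  expect_equal(got, seqs)
})
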