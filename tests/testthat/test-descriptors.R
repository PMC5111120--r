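# Primary-structure descriptor blocks

test_that("amino-acid composition matches hand counts and sums to one", {
  v <- aac("AAAA")
  expect_equal(unname(v[["aac.A"]]), 1)
  expect_equal(sum(v), 1)

  v <- aac("ACDEFGHIKLMNPQRSTVWY")
  expect_equal(unname(v), rep(0.05, 20))

  v <- aac("AAC")
  expect_equal(unname(v[["aac.A"]]), 2 / 3)
  expect_equal(unname(v[["aac.C"]]), 1 / 3)
  expect_equal(sum(v[!names(v) %in% c("aac.A", "aac.C")]), 0)
})

test_that("dipeptide composition counts adjacent ordered pairs over N-1", {
  v <- dipeptide("AA")
  expect_equal(unname(v[["dipep.AA"]]), 1)
  expect_equal(sum(v), 1)

  v <- dipeptide("ACA")
  expect_equal(unname(v[["dipep.AC"]]), 0.5)
  expect_equal(unname(v[["dipep.CA"]]), 0.5)

  set.seed(42)
  seq <- paste(sample(AA_ALPHABET, 80, replace = TRUE), collapse = "")
  expect_equal(sum(dipeptide(seq)), 1)
  expect_error(dipeptide("A"), "at least 2")
})

test_that("autocorrelations match a direct-formula evaluation", {
  # 4-residue toy sequence, every kind, checked lag by lag
  toy <- c("A", "W", "C", "G")
  for (kind in c("moreau_broto", "moran", "geary")) {
    got <- autocorrelation(toy, kind)
    for (prop in names(AA_PROPERTY_SCALES)) {
      want <- oracle_autocorr(toy, AA_PROPERTY_SCALES[[prop]], kind)
      idx <- grep(paste0("\\.", prop, "_lag"), names(got))
      expect_equal(unname(got[idx]), want,
                   info = paste(kind, prop))
    }
  }
  # random longer sequences against the naive implementation
  set.seed(1)
  for (rep in 1:3) {
    chars <- sample(AA_ALPHABET, sample(20:60, 1), replace = TRUE)
    for (kind in c("moreau_broto", "moran", "geary")) {
      got <- autocorrelation(chars, kind)
      prop <- sample(names(AA_PROPERTY_SCALES), 1)
      want <- oracle_autocorr(chars, AA_PROPERTY_SCALES[[prop]], kind)
      idx <- grep(paste0("\\.", prop, "_lag"), names(got))
      expect_equal(unname(got[idx]), want)
    }
  }
})

test_that("homopolymers and overlong lags fall back to zero", {
  homo <- strrep("A", 30)
  expect_true(all(autocorrelation(homo, "moran") == 0))
  expect_true(all(autocorrelation(homo, "geary") == 0))
  short <- c("A", "W", "C")  # N = 3: lags >= 3 must be 0
  for (kind in c("moreau_broto", "moran", "geary")) {
    v <- autocorrelation(short, kind)
    lag_no <- as.integer(sub(".*_lag", "", names(v)))
    expect_true(all(v[lag_no >= 3] == 0))
  }
})

test_that("CTD composition/transition follow the class-index encoding", {
  # charge attribute: K,R -> 1; D,E -> 3; everything else -> 2
  v <- ctd_composition("KKKK")
  expect_equal(unname(v[["ctdc.charge_1"]]), 1)
  expect_equal(unname(v[["ctdc.charge_2"]]), 0)
  # every attribute triple partitions the sequence
  set.seed(5)
  seq <- paste(sample(AA_ALPHABET, 50, replace = TRUE), collapse = "")
  v <- ctd_composition(seq)
  for (a in names(AA_CTD_GROUPS))
    expect_equal(sum(v[grep(paste0("^ctdc\\.", a, "_"), names(v))]), 1)

  # "1122" under charge: K K A A -> T12 = 1/3
  v <- ctd_composition("KKAA")
  expect_equal(unname(v[["ctdc.charge_1"]]), 0.5)
  expect_equal(unname(v[["ctdc.charge_2"]]), 0.5)
  t <- ctd_transition("KKAA")
  expect_equal(unname(t[["ctdt.charge_12"]]), 1 / 3)

  # "1212" (KAKA): all 3 adjacent pairs are 1<->2 transitions
  t <- ctd_transition("KAKA")
  expect_equal(unname(t[["ctdt.charge_12"]]), 1)
  expect_equal(unname(t[["ctdt.charge_13"]]), 0)
  # "123" (KAD): one 12, one 23
  t <- ctd_transition("KAD")
  expect_equal(unname(t[["ctdt.charge_12"]]), 0.5)
  expect_equal(unname(t[["ctdt.charge_23"]]), 0.5)
  expect_equal(unname(t[["ctdt.charge_13"]]), 0)
  # no class change
  t <- ctd_transition("KKKK")
  expect_true(all(t[grep("charge", names(t))] == 0))
})

test_that("CTD distribution uses the ceiling landmark rule", {
  # "KKK" => class 1 at positions 1,2,3 of N=3: (1/3, 1/3, 2/3, 1, 1)
  v <- ctd_distribution("KKK")
  got <- unname(v[grep("^ctdd\\.charge_1_", names(v))])
  expect_equal(got, c(1 / 3, 1 / 3, 2 / 3, 1, 1))
  # absent class -> all zero
  expect_true(all(v[grep("^ctdd\\.charge_3_", names(v))] == 0))
  # first landmark never exceeds the last
  set.seed(9)
  seq <- paste(sample(AA_ALPHABET, 40, replace = TRUE), collapse = "")
  v <- ctd_distribution(seq)
  m <- matrix(v, ncol = 5, byrow = TRUE)
  expect_true(all(m[, 1] <= m[, 5]))
  expect_true(all(v >= 0 & v <= 1))
})

test_that("full descriptor has the fixed 1767 layout and is deterministic", {
  set.seed(3)
  seq <- paste(sample(AA_ALPHABET, 120, replace = TRUE), collapse = "")
  v <- full_descriptor(seq)
  expect_length(v, 1767)
  expect_identical(v, full_descriptor(seq))
  blocks <- c(aac = 20, dipep = 400, mb = 400, mr = 400, ge = 400,
              ctdc = 21, ctdt = 21, ctdd = 105)
  prefix <- sub("\\..*", "", names(v))
  expect_equal(as.integer(table(prefix)[names(blocks)]),
               as.integer(blocks))
  expect_equal(sum(v[prefix == "aac"]), 1, tolerance = 1e-9)
  expect_equal(sum(v[prefix == "dipep"]), 1, tolerance = 1e-9)
})

test_that("permuting residues keeps AAC but changes order-sensitive blocks", {
  a <- sanitize_sequence("ACDKWYACDKWY")
  b <- rev(a)
  expect_equal(aac(a), aac(b))
  expect_false(isTRUE(all.equal(dipeptide(a), dipeptide(b))))
})

test_that("non-canonical residues are dropped with a warning", {
  expect_warning(chars <- sanitize_sequence("ACXDB"), "non-canonical")
  expect_equal(chars, c("A", "C", "D"))
  expect_equal(sanitize_sequence("acd"), c("A", "C", "D"))
  expect_error(suppressWarnings(sanitize_sequence("XXB")), "no canonical")
})

test_that("FASTA round trip preserves sequences and first-token IDs", {
  tmp <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">sp|P1|NAME first protein", "ACDEF", "GHIKL",
               ">P2 another", "MNPQR"), tmp)
  seqs <- read_fasta(tmp)
  expect_equal(names(seqs), c("sp|P1|NAME", "P2"))
  expect_equal(unname(seqs[1]), "ACDEFGHIKL")
  M <- descriptor_matrix(seqs)
  expect_equal(dim(M), c(2, 1767))
  expect_equal(rownames(M), c("sp|P1|NAME", "P2"))
})
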